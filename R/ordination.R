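#' Drop rare seed-category columns from a count matrix
#'
#' @param mat trees x categories count matrix (or data frame).
#' @param min_count minimum column total for a category to be kept
#'   (boundary inclusive; default 4).
#' @return the matrix restricted to abundant columns, row order preserved.
#' @export
filter_abundant_categories <- function(mat, min_count = 4) {
  mat <- as.matrix(mat)
  if (any(mat < 0)) stop("count matrix must be non-negative", call. = FALSE)
  mat[, colSums(mat) >= min_count, drop = FALSE]
}

#' Percent-maximum column transform
#'
#' Each column is divided by its maximum, so every column maximum becomes
#' exactly 1 and all entries lie in [0, 1].
#'
#' @param mat non-negative matrix; every column must contain a positive
#'   entry (filter first).
#' @return transformed matrix.
#' @export
percent_max_transform <- function(mat) {
  mat <- as.matrix(mat)
  if (any(mat < 0)) stop("matrix must be non-negative", call. = FALSE)
  cm <- apply(mat, 2, max)
  if (any(cm == 0)) {
    stop("all-zero column(s): ",
         paste(colnames(mat)[cm == 0], collapse = ", "),
         " (filter rare categories first)", call. = FALSE)
  }
  sweep(mat, 2, cm, "/")
}

#' Bray-Curtis dissimilarity between rows
#'
#' d(i, j) = sum |x_ik - x_jk| / sum (x_ik + x_jk); symmetric, zero
#' diagonal, bounded by [0, 1] for non-negative data. Two all-zero rows are
#' assigned dissimilarity 0.
#'
#' @param mat non-negative matrix, rows = objects.
#' @return a `stats::dist` object.
#' @export
bray_curtis <- function(mat) {
  mat <- as.matrix(mat)
  if (any(mat < 0)) stop("matrix must be non-negative", call. = FALSE)
  n <- nrow(mat)
  d <- matrix(0, n, n, dimnames = list(rownames(mat), rownames(mat)))
  for (i in seq_len(n - 1L)) {
    xi <- mat[i, ]
    for (j in (i + 1L):n) {
      den <- sum(xi + mat[j, ])
      d[i, j] <- d[j, i] <- if (den > 0) sum(abs(xi - mat[j, ])) / den else 0
    }
  }
  stats::as.dist(d)
}

#' Ward hierarchical clustering via the Lance-Williams update
#'
#' Agglomerative clustering under Ward's minimum-variance criterion in its
#' "ward.D2" form: the Lance-Williams recurrence is applied to squared
#' dissimilarities and merge heights are square-rooted back to the input
#' scale. Ties are broken deterministically by the smallest pair of current
#' cluster indices.
#'
#' @param d a `stats::dist` object (e.g. from [bray_curtis()]).
#' @param k number of groups to cut (default 2).
#' @return object of class `fcss_clust`: list with `hclust` (a standard
#'   `stats::hclust` tree built by this implementation), `height`, `groups`
#'   (k-cut labels) and `k`.
#' @export
ward_cluster <- function(d, k = 2) {
  if (!inherits(d, "dist")) d <- stats::as.dist(d)
  n <- attr(d, "Size")
  if (is.null(n) || n < 2L) stop("need at least 2 objects", call. = FALSE)
  labels <- attr(d, "Labels")
  if (is.null(labels)) labels <- as.character(seq_len(n))
  S <- as.matrix(d)^2
  diag(S) <- Inf
  active <- seq_len(n)           # positions into S still in play
  code <- -seq_len(n)            # hclust merge codes
  size <- rep(1L, n)
  merge <- matrix(0L, n - 1L, 2L)
  height <- numeric(n - 1L)
  for (step in seq_len(n - 1L)) {
    m <- length(active)
    sub <- S[active, active, drop = FALSE]
    best <- which(sub == min(sub), arr.ind = TRUE)
    # deterministic tie-break: smallest row index, then column
    best <- best[best[, 1] < best[, 2], , drop = FALSE]
    best <- best[order(best[, 1], best[, 2])[1L], ]
    i <- active[best[[1L]]]
    j <- active[best[[2L]]]
    height[step] <- sqrt(S[i, j])
    a <- code[i]; b <- code[j]
    merge[step, ] <- if (a < b) c(a, b) else c(b, a)
    ni <- size[i]; nj <- size[j]
    others <- setdiff(active, c(i, j))
    if (length(others)) {
      nk <- size[others]
      S[i, others] <- S[others, i] <-
        ((ni + nk) * S[i, others] + (nj + nk) * S[j, others] -
           nk * S[i, j]) / (ni + nj + nk)
    }
    size[i] <- ni + nj
    code[i] <- step
    active <- setdiff(active, j)
  }
  order_ <- .dendro_order(merge, n)
  hc <- structure(list(merge = merge, height = height, order = order_,
                       labels = labels, method = "ward.D2",
                       call = match.call(), dist.method = "user"),
                  class = "hclust")
  groups <- stats::cutree(hc, k = k)
  structure(list(hclust = hc, height = height, groups = groups, k = k),
            class = "fcss_clust")
}

# leaf order for plotting, standard recursion on the merge matrix
.dendro_order <- function(merge, n) {
  expand <- function(node) {
    if (node < 0) return(-node)
    c(expand(merge[node, 1L]), expand(merge[node, 2L]))
  }
  expand(nrow(merge))
}

#' @export
print.fcss_clust <- function(x, ...) {
  cat(sprintf("Ward clustering (ward.D2) of %d objects; k = %d groups: %s\n",
              length(x$groups), x$k,
              paste(table(x$groups), collapse = "/")))
  invisible(x)
}

# weighted helpers for correspondence analysis
.wmean <- function(x, w) sum(w * x) / sum(w)
.wsd <- function(x, w) sqrt(sum(w * (x - .wmean(x, w))^2) / sum(w))

# subtract segment-wise weighted means of x along a previous axis
.detrend_segments <- function(x, prev, w, n_segments) {
  rng <- range(prev)
  if (diff(rng) == 0) return(x - .wmean(x, w))
  breaks <- seq(rng[1], rng[2], length.out = n_segments + 1L)
  seg <- findInterval(prev, breaks, rightmost.closed = TRUE, all.inside = TRUE)
  for (s in unique(seg)) {
    idx <- seg == s
    x[idx] <- x[idx] - .wmean(x[idx], w[idx])
  }
  x
}

#' Detrended correspondence analysis
#'
#' Hill-style DCA implemented from the algorithm: reciprocal averaging
#' extracts each axis by power iteration, axes beyond the first are
#' detrended against all previous axes by subtracting segment-wise means
#' (default 26 segments), and axes are optionally rescaled to standard
#' deviation (sd) units of species turnover. The first axis is exactly the
#' first correspondence-analysis axis. The rescaling implemented here is a
#' single global scaling (mean within-site dispersion of species scores set
#' to 1) rather than Hill's iterative per-segment rescaling; axis ordering
#' and within-axis ranking are unaffected. Axis scores are defined up to
#' sign; axis 1 is oriented so the first row's score is non-negative.
#'
#' @param mat non-negative matrix (rows = sites/trees, columns = species/
#'   seed categories) with at least 3 non-empty rows and columns and rank
#'   at least 2.
#' @param n_segments number of detrending segments (default 26).
#' @param rescale rescale axes to sd units (default TRUE).
#' @param n_axes number of axes to extract (default 4, truncated by the
#'   matrix rank).
#' @return object of class `fcss_dca`: list with `row_scores`,
#'   `col_scores`, `eigenvalues` and `axis_lengths` (range of row scores
#'   per axis, in sd units when rescaled).
#' @export
dca <- function(mat, n_segments = 26, rescale = TRUE, n_axes = 4) {
  mat <- as.matrix(mat)
  if (any(mat < 0) || any(!is.finite(mat))) {
    stop("matrix must be finite and non-negative", call. = FALSE)
  }
  if (any(rowSums(mat) == 0) || any(colSums(mat) == 0)) {
    stop("remove empty rows/columns before ordination", call. = FALSE)
  }
  if (nrow(mat) < 3 || ncol(mat) < 3) {
    stop("need at least 3 rows and 3 columns after filtering", call. = FALSE)
  }
  rw <- rowSums(mat)
  cw <- colSums(mat)
  tot <- sum(mat)
  # rank check on the standardized residual matrix
  Sres <- diag(1 / sqrt(rw)) %*%
    (mat - outer(rw, cw) / tot) %*% diag(1 / sqrt(cw))
  sv <- svd(Sres, nu = 0, nv = 0)$d
  rank_ <- sum(sv > max(sv) * 1e-9)
  if (rank_ < 2) {
    stop("degenerate matrix: rank < 2, no meaningful second axis",
         call. = FALSE)
  }
  n_axes <- min(n_axes, rank_, nrow(mat) - 1L, ncol(mat) - 1L)
  axes <- matrix(0, nrow(mat), n_axes)
  eig <- numeric(n_axes)
  set_start <- function(k) {
    # deterministic start: k-th pattern of alternating signs along rows
    x <- seq_len(nrow(mat)) %% (k + 1L) - k / 2
    if (.wsd(x, rw) == 0) x <- seq_len(nrow(mat))
    x
  }
  for (ax in seq_len(n_axes)) {
    x <- set_start(ax)
    x <- (x - .wmean(x, rw)) / .wsd(x, rw)
    lambda <- 0
    for (it in 1:999) {
      u <- as.vector(crossprod(mat, x)) / cw
      xn <- as.vector(mat %*% u) / rw
      if (ax > 1L) {
        for (p in seq_len(ax - 1L)) {
          xn <- .detrend_segments(xn, axes[, p], rw, n_segments)
        }
      }
      xn <- xn - .wmean(xn, rw)
      s <- .wsd(xn, rw)
      if (s < 1e-12) break
      lambda_new <- s
      xn <- xn / s
      if (max(abs(xn - x)) < 1e-10 || max(abs(xn + x)) < 1e-10) {
        x <- xn
        lambda <- lambda_new
        break
      }
      x <- xn
      lambda <- lambda_new
    }
    axes[, ax] <- x
    eig[ax] <- lambda
  }
  col_scores <- matrix(0, ncol(mat), n_axes)
  axis_lengths <- numeric(n_axes)
  for (ax in seq_len(n_axes)) {
    x <- axes[, ax]
    v <- as.vector(crossprod(mat, x)) / cw
    if (rescale) {
      disp <- sum(rw * vapply(seq_len(nrow(mat)), function(i) {
        sum(mat[i, ] * (v - x[i])^2) / rw[i]
      }, numeric(1))) / tot
      if (disp > 1e-12) {
        x <- x / sqrt(disp)
        v <- as.vector(crossprod(mat, x)) / cw
      }
    }
    if (x[1L] < 0) {
      x <- -x
      v <- -v
    }
    axes[, ax] <- x
    col_scores[, ax] <- v
    axis_lengths[ax] <- diff(range(x))
  }
  dimnames(axes) <- list(rownames(mat), paste0("DCA", seq_len(n_axes)))
  dimnames(col_scores) <- list(colnames(mat), paste0("DCA", seq_len(n_axes)))
  structure(list(row_scores = axes, col_scores = col_scores,
                 eigenvalues = eig, axis_lengths = axis_lengths,
                 n_segments = n_segments, rescaled = rescale),
            class = "fcss_dca")
}

#' @export
print.fcss_dca <- function(x, ...) {
  cat(sprintf("DCA: %d axes, eigenvalues %s; axis lengths %s\n",
              ncol(x$row_scores),
              paste(sprintf("%.3f", x$eigenvalues), collapse = ", "),
              paste(sprintf("%.2f", x$axis_lengths), collapse = ", ")))
  invisible(x)
}
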