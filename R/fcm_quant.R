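#' Built-in and user-defined internal reference standards
#'
#' Flow-cytometric genome size estimation is anchored to an internal
#' reference standard (IRS) co-processed with the sample. Two standards
#' widely used for hawthorn work are built in: *Pisum sativum* cv. Ctirad
#' (2C = 9.09 pg) and *Solanum pseudocapsicum* (2C = 2.59 pg).
#'
#' @param name `"pisum"`, `"solanum"`, or a free-text name for a custom
#'   standard.
#' @param twoC_pg 2C DNA amount of the standard in picograms. Required for
#'   custom standards, ignored (taken from the built-in table) otherwise.
#' @return An object of class `fcss_standard`: a list with `name` and
#'   `twoC_pg`.
#' @examples
#' reference_standard("pisum")
#' reference_standard("maize", twoC_pg = 5.43)
#' @export
reference_standard <- function(name = c("pisum", "solanum"), twoC_pg = NULL) {
  builtin <- c(pisum = 9.09, solanum = 2.59)
  if (length(name) > 1L) name <- name[[1L]]
  if (name %in% names(builtin)) {
    twoC_pg <- unname(builtin[[name]])
  } else {
    if (is.null(twoC_pg)) {
      stop("custom reference standard '", name, "' needs an explicit twoC_pg",
           call. = FALSE)
    }
    if (!is.numeric(twoC_pg) || length(twoC_pg) != 1L || !is.finite(twoC_pg) ||
        twoC_pg <= 0) {
      stop("twoC_pg must be a single positive number", call. = FALSE)
    }
  }
  structure(list(name = name, twoC_pg = twoC_pg), class = "fcss_standard")
}

#' @export
print.fcss_standard <- function(x, ...) {
  cat(sprintf("FCSS reference standard: %s (2C = %.2f pg)\n", x$name, x$twoC_pg))
  invisible(x)
}

#' Quality-control thresholds for FCSS peak measurements
#'
#' Peak CV thresholds are strict ("above" fails, the boundary passes):
#' embryo and standard peaks fail above 6% CV, endosperm peaks above the
#' more relaxed 9%, and embryo peaks additionally require a minimum number
#' of collected nuclei (default 1300).
#'
#' @param max_cv_embryo_standard maximum CV (percent) for embryo, maternal
#'   and standard peaks.
#' @param max_cv_endosperm maximum CV (percent) for endosperm peaks; must be
#'   at least `max_cv_embryo_standard`.
#' @param min_nuclei_embryo minimum nuclei count for embryo peaks.
#' @return An object of class `fcss_qc_thresholds`.
#' @export
qc_thresholds <- function(max_cv_embryo_standard = 6,
                          max_cv_endosperm = 9,
                          min_nuclei_embryo = 1300) {
  stopifnot(is.numeric(max_cv_embryo_standard), max_cv_embryo_standard >= 0,
            is.numeric(max_cv_endosperm), is.numeric(min_nuclei_embryo))
  if (max_cv_endosperm < max_cv_embryo_standard) {
    stop("max_cv_endosperm must be >= max_cv_embryo_standard", call. = FALSE)
  }
  structure(list(max_cv_embryo_standard = max_cv_embryo_standard,
                 max_cv_endosperm = max_cv_endosperm,
                 min_nuclei_embryo = min_nuclei_embryo),
            class = "fcss_qc_thresholds")
}

.tissue_levels <- c("embryo", "endosperm", "maternal", "standard")

#' Absolute DNA amount from sample and standard peak means
#'
#' 2C value of the sample = 2C of the internal standard times the ratio of
#' the sample and standard G0/G1 peak means. The result is invariant to a
#' common rescaling of both peak means (channel gain cancels).
#'
#' @param sample_peak_mean,standard_peak_mean G0/G1 peak means in channel
#'   units; both must be positive. `sample_peak_mean` may be a vector.
#' @param standard an [reference_standard()] object.
#' @param tissue tissue role of the sample peak(s), recycled as needed.
#' @return A data frame with columns `value_pg`, `tissue`, `qc_pass`,
#'   `qc_reason` (QC columns are filled by [qc_filter()]; here `qc_pass` is
#'   `TRUE` with empty reason).
#' @examples
#' compute_2c(50, 100, reference_standard("pisum"))  # 4.545 pg
#' @export
compute_2c <- function(sample_peak_mean, standard_peak_mean, standard,
                       tissue = "embryo") {
  if (!inherits(standard, "fcss_standard")) {
    stop("standard must be a reference_standard() object", call. = FALSE)
  }
  if (!is.numeric(sample_peak_mean) || !is.numeric(standard_peak_mean)) {
    stop("invalid measurement: peak means must be numeric", call. = FALSE)
  }
  if (any(!is.finite(sample_peak_mean)) || any(!is.finite(standard_peak_mean)) ||
      any(sample_peak_mean <= 0) || any(standard_peak_mean <= 0)) {
    stop("invalid measurement: non-positive peak mean", call. = FALSE)
  }
  tissue <- match.arg(tissue, .tissue_levels, several.ok = TRUE)
  data.frame(
    value_pg = standard$twoC_pg * (sample_peak_mean / standard_peak_mean),
    tissue = rep_len(tissue, length(sample_peak_mean)),
    qc_pass = TRUE,
    qc_reason = "",
    stringsAsFactors = FALSE
  )
}

#' Annotate peak measurements with QC verdicts
#'
#' QC never raises an error: every peak receives a verdict and a
#' machine-readable reason. Thresholds are strict inequalities, so a CV
#' exactly at the threshold passes.
#'
#' @param peaks data frame with columns `tissue`, `peak_mean`, `cv` and
#'   optionally `n_nuclei`.
#' @param thresholds a [qc_thresholds()] object.
#' @return `peaks` with added logical `qc_pass` and character `qc_reason`
#'   (`""` when passing, otherwise a semicolon-separated reason list).
#' @export
qc_filter <- function(peaks, thresholds = qc_thresholds()) {
  stopifnot(is.data.frame(peaks))
  need <- c("tissue", "peak_mean", "cv")
  miss <- setdiff(need, names(peaks))
  if (length(miss)) {
    stop("peaks is missing required columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  bad_tissue <- !peaks$tissue %in% .tissue_levels
  if (any(bad_tissue)) {
    stop("unknown tissue role(s): ",
         paste(unique(peaks$tissue[bad_tissue]), collapse = ", "),
         call. = FALSE)
  }
  reasons <- character(nrow(peaks))
  strict_cv <- peaks$tissue %in% c("embryo", "standard", "maternal")
  fail_cv_strict <- strict_cv & peaks$cv > thresholds$max_cv_embryo_standard
  fail_cv_end <- peaks$tissue == "endosperm" &
    peaks$cv > thresholds$max_cv_endosperm
  reasons[fail_cv_strict] <- paste0("cv_above_",
                                    thresholds$max_cv_embryo_standard)
  reasons[fail_cv_end] <- paste0("cv_above_", thresholds$max_cv_endosperm)
  if ("n_nuclei" %in% names(peaks)) {
    fail_n <- peaks$tissue == "embryo" & !is.na(peaks$n_nuclei) &
      peaks$n_nuclei < thresholds$min_nuclei_embryo
    reasons[fail_n] <- ifelse(nzchar(reasons[fail_n]),
                              paste0(reasons[fail_n], ";too_few_nuclei"),
                              "too_few_nuclei")
  }
  peaks$qc_pass <- !nzchar(reasons)
  peaks$qc_reason <- reasons
  peaks
}

#' Fit G0/G1 peaks to a raw fluorescence event list
#'
#' Artifact plumbing around the measurement step: a kernel-density mode
#' finder seeds a one-dimensional k-means refinement, so synthetic event
#' lists can be pushed through the same pipeline as instrument peak tables.
#' Not a cell-cycle model; G2 populations simply surface as extra peaks.
#'
#' @param events numeric vector of per-event fluorescence values (>= 200).
#' @param expected_peaks hint for the number of G0/G1 populations present;
#'   at most `expected_peaks + 2` peaks are returned (room for G2 peaks).
#' @return data frame of peaks sorted by mean, with columns `peak_mean`,
#'   `cv` (percent, 100 * sd/mean) and `n_nuclei`.
#' @export
fit_peaks <- function(events, expected_peaks = 3) {
  if (!is.numeric(events)) stop("events must be numeric", call. = FALSE)
  events <- events[is.finite(events)]
  if (length(events) < 200) {
    stop("insufficient data: need at least 200 events, got ", length(events),
         call. = FALSE)
  }
  max_peaks <- expected_peaks + 2L
  if (stats::sd(events) == 0) {
    return(data.frame(peak_mean = events[[1L]], cv = 0,
                      n_nuclei = length(events)))
  }
  dens <- stats::density(events, n = 1024)
  y <- dens$y
  is_mode <- which(diff(sign(diff(y))) == -2) + 1L
  # ignore modes carrying almost no density
  is_mode <- is_mode[y[is_mode] > 0.01 * max(y)]
  if (!length(is_mode)) is_mode <- which.max(y)
  if (length(is_mode) > max_peaks) {
    is_mode <- is_mode[order(y[is_mode], decreasing = TRUE)[seq_len(max_peaks)]]
    is_mode <- sort(is_mode)
  }
  centers <- dens$x[is_mode]
  # 1-D k-means refinement with fixed number of centers
  for (i in 1:25) {
    assign <- max.col(-abs(outer(events, centers, "-")), ties.method = "first")
    new_centers <- vapply(seq_along(centers), function(k) {
      v <- events[assign == k]
      if (length(v)) mean(v) else NA_real_
    }, numeric(1))
    keep <- !is.na(new_centers)
    new_centers <- sort(new_centers[keep])
    if (length(new_centers) == length(centers) &&
        max(abs(new_centers - centers)) < 1e-8) {
      centers <- new_centers
      break
    }
    centers <- new_centers
  }
  assign <- max.col(-abs(outer(events, centers, "-")), ties.method = "first")
  out <- do.call(rbind, lapply(seq_along(centers), function(k) {
    v <- events[assign == k]
    m <- mean(v)
    data.frame(peak_mean = m,
               cv = if (length(v) > 1L) 100 * stats::sd(v) / m else 0,
               n_nuclei = length(v))
  }))
  out <- out[order(out$peak_mean), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Label probable G2 peaks of the internal standard
#'
#' Endosperm peaks can sit on top of the G2 peak of the IRS; any peak whose
#' mean lies within `tol` (relative) of twice the standard peak mean is
#' labeled so it can be excluded from tissue assignment.
#'
#' @param peaks data frame with a `peak_mean` column.
#' @param standard_peak_mean G0/G1 peak mean of the internal standard.
#' @param tol relative tolerance (default 0.05, i.e. +/- 5%).
#' @return `peaks` with an added logical column `standard_g2`.
#' @export
flag_standard_g2 <- function(peaks, standard_peak_mean, tol = 0.05) {
  stopifnot(is.data.frame(peaks), "peak_mean" %in% names(peaks),
            standard_peak_mean > 0)
  peaks$standard_g2 <-
    abs(peaks$peak_mean / (2 * standard_peak_mean) - 1) <= tol
  peaks
}
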