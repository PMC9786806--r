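# Questionable classes excluded from meiosis/fertilization evidence; the
# >12x class only lowers sperm-reconstruction confidence and stays counted.
.meiosis_excluding <- c("near_unreduced_endosperm",
                        "aneuploid_embryo_high_endosperm")

#' Mother-tree x seed-category count and percentage matrices
#'
#' @param classified output of [classify_seeds()] with `mother_id` and
#'   `maternal_level` columns.
#' @return list with `counts` (trees x categories integer matrix),
#'   `percentages` (per row, denominator = the tree's successfully screened
#'   seeds), and `cytotype` (long data frame pooling trees of equal maternal
#'   ploidy, with percentages over the cytotype's successes).
#' @export
tabulate_categories <- function(classified) {
  stopifnot(is.data.frame(classified))
  need <- c("mother_id", "maternal_level", "status", "label")
  miss <- setdiff(need, names(classified))
  if (length(miss)) {
    stop("classified is missing required columns: ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  ok <- classified[classified$status == "ok", , drop = FALSE]
  if (!nrow(ok)) {
    m <- matrix(integer(0), nrow = 0, ncol = 0)
    return(list(counts = m, percentages = m,
                cytotype = data.frame(maternal_level = numeric(0),
                                      label = character(0),
                                      count = integer(0), pct = numeric(0))))
  }
  trees <- unique(ok$mother_id)
  labels <- unique(ok$label)
  counts <- table(factor(ok$mother_id, levels = trees),
                  factor(ok$label, levels = labels))
  counts <- matrix(as.integer(counts), nrow = length(trees),
                   dimnames = list(trees, labels))
  pct <- 100 * counts / rowSums(counts)
  agg <- stats::aggregate(list(count = rep(1L, nrow(ok))),
                          by = list(maternal_level = ok$maternal_level,
                                    label = ok$label), FUN = sum)
  tot <- stats::aggregate(list(n = rep(1L, nrow(ok))),
                          by = list(maternal_level = ok$maternal_level),
                          FUN = sum)
  agg$pct <- 100 * agg$count /
    tot$n[match(agg$maternal_level, tot$maternal_level)]
  agg <- agg[order(agg$maternal_level, -agg$count, agg$label), , drop = FALSE]
  rownames(agg) <- NULL
  list(counts = counts, percentages = pct, cytotype = agg)
}

#' Headline reproduction-pathway rates per maternal cytotype
#'
#' Computes, per maternal ploidy, the quantitative summary of seed origins:
#' screening success, embryo-sac reduction, egg fate (parthenogenesis,
#' fertilization, B-III hybrid formation), central-cell fate (pseudogamy vs
#' autonomous endosperm) and the share of seeds with the canonical 2m:1p
#' maternal-to-paternal endosperm genome dose.
#'
#' Denominators: `success_pct` uses all analyzed seeds; every other rate
#' uses successfully screened seeds. Questionable seeds (see
#' [flag_questionable()]) are handled the way the screen's interpretation
#' rules prescribe: near-unreduced endosperm seeds are dropped from the
#' meiosis, egg-fertilization and central-cell numerators (reported in
#' `questionable_pct`); aneuploid-embryo seeds are treated as mismeasured
#' unreduced parthenogenetic seeds for the sac and egg-fate rates and are
#' excluded from the balanced-endosperm numerator.
#'
#' @param classified output of [classify_seeds()].
#' @param balanced_band when `TRUE` (default) the 2m:1p share counts
#'   endosperm within half a grid step of three times the maternal level
#'   (e.g. ~8.5x-~9.5x for a triploid); when `FALSE` only the exact 3m
#'   level counts.
#' @return data frame, one row per maternal cytotype.
#' @export
summarize_pathways <- function(classified, balanced_band = TRUE) {
  stopifnot(is.data.frame(classified))
  res <- lapply(sort(unique(classified$maternal_level)), function(m) {
    cc <- classified[classified$maternal_level == m, , drop = FALSE]
    n_analyzed <- nrow(cc)
    ok <- cc[cc$status == "ok", , drop = FALSE]
    n <- nrow(ok)
    if (!n) {
      return(NULL)
    }
    excl <- ok$questionable %in% .meiosis_excluding
    near6 <- ok$questionable == "near_unreduced_endosperm"
    aneu <- ok$questionable == "aneuploid_embryo_high_endosperm"
    # effective sac / egg fate after the measurement-error reassignment
    sac_eff <- ifelse(aneu, "unreduced", ok$sac)
    fate_eff <- ifelse(aneu, "parthenogenetic", ok$egg_fate)
    pc <- function(k) 100 * k / n
    data.frame(
      maternal_level = m,
      n_analyzed = n_analyzed,
      n_success = n,
      success_pct = 100 * n / n_analyzed,
      unreduced_sac_pct = pc(sum(sac_eff == "unreduced", na.rm = TRUE)),
      reduced_sac_pct = pc(sum(sac_eff == "reduced", na.rm = TRUE)),
      meiosis_evidence_pct = pc(sum(sac_eff == "reduced" & !excl,
                                    na.rm = TRUE)),
      parthenogenesis_pct = pc(sum(fate_eff == "parthenogenetic" & !near6,
                                   na.rm = TRUE)),
      egg_fertilization_pct = pc(sum(fate_eff == "fertilized" & !excl,
                                     na.rm = TRUE)),
      b3_hybrid_pct = pc(sum(ok$embryo_mode == "B_III" & !excl,
                             na.rm = TRUE)),
      central_fertilized_pct = pc(sum(ok$endosperm_mode == "pseudogamous" &
                                        !near6, na.rm = TRUE)),
      autonomous_pct = pc(sum(ok$endosperm_mode %in%
                                c("autonomous",
                                  "autonomous_plus_endoreplication") &
                                !near6, na.rm = TRUE)),
      questionable_pct = pc(sum(near6)),
      balanced_2m1p_pct = pc(sum(
        (if (balanced_band) abs(ok$endosperm_level - 3 * m) <= 0.5 + 1e-9
         else abs(ok$endosperm_level - 3 * m) < 1e-9) & !excl)),
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Per-tree fruit and seed-set statistics
#'
#' @param fruits data frame with columns `mother_id`, `n_pyrenes` (1-4) and
#'   `n_seeds` (0 to `n_pyrenes`).
#' @param sterile_threshold trees whose share of seedless fruits exceeds
#'   this percentage are flagged as putatively seed-sterile.
#' @return data frame, one row per tree: fruit counts, percentage of fruits
#'   with 0/1/2+ seeds, pyrene-count distribution, and the sterility flag.
#' @export
fruit_statistics <- function(fruits, sterile_threshold = 50) {
  stopifnot(is.data.frame(fruits))
  need <- c("mother_id", "n_pyrenes", "n_seeds")
  miss <- setdiff(need, names(fruits))
  if (length(miss)) {
    stop("fruits is missing required columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  bad <- fruits$n_pyrenes < 1 | fruits$n_pyrenes > 4 |
    fruits$n_seeds < 0 | fruits$n_seeds > fruits$n_pyrenes
  if (any(bad)) {
    stop("invalid fruit records (need 0 <= n_seeds <= n_pyrenes <= 4) at rows: ",
         paste(utils::head(which(bad), 10), collapse = ", "), call. = FALSE)
  }
  res <- lapply(unique(fruits$mother_id), function(id) {
    f <- fruits[fruits$mother_id == id, , drop = FALSE]
    n <- nrow(f)
    pyr <- vapply(1:4, function(k) 100 * sum(f$n_pyrenes == k) / n, numeric(1))
    zero <- 100 * sum(f$n_seeds == 0) / n
    data.frame(mother_id = id, n_fruits = n,
               pct_zero_seed = zero,
               pct_one_seed = 100 * sum(f$n_seeds == 1) / n,
               pct_two_plus_seed = 100 * sum(f$n_seeds >= 2) / n,
               pct_pyrenes_1 = pyr[1], pct_pyrenes_2 = pyr[2],
               pct_pyrenes_3 = pyr[3], pct_pyrenes_4 = pyr[4],
               putatively_seed_sterile = zero > sterile_threshold,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}
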