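# Talent-Dickinson 2C ranges used to draw maternal genome sizes
.td_ranges <- function() cytotype_ranges()

#' Default reproduction-pathway templates per maternal cytotype
#'
#' The generator's stated world: scenario templates and frequencies mirror
#' the published per-cytotype seed-category spectrum (diploids n = 247,
#' triploids n = 1162 pathway-resolvable seeds, tetraploids n = 110). Each
#' template is one concrete scenario in the engine's parameterisation; the
#' two measurement-error-only classes (aneuploid embryo near the maternal
#' level, endosperm half a step under twice the maternal level) are not
#' templates — in this model they arise from noise, not from a pathway.
#'
#' @param maternal_level 2, 3 or 4.
#' @return data frame of templates with a `prob` column summing to 1.
#' @export
default_pathway_templates <- function(maternal_level) {
  t_ <- function(sac, sac_ep, egg, se, cn, ep, s1, s2, w) {
    data.frame(sac = sac, sac_ep = sac_ep, egg_fate = egg,
               sperm_to_egg = se, central_nuclei = cn, end_ep = ep,
               s1 = s1, s2 = s2, weight = w, stringsAsFactors = FALSE)
  }
  tpl <- switch(as.character(maternal_level),
    "2" = rbind(
      t_("reduced", FALSE, "fertilized", 1, 2L, FALSE, 1, NA, 240),
      t_("reduced", FALSE, "fertilized", 2, 2L, FALSE, 2, NA, 5),
      t_("reduced", FALSE, "fertilized", 1, 2L, TRUE, 1, NA, 2)),
    "3" = rbind(
      t_("unreduced", FALSE, "parthenogenetic", NA, 2L, FALSE, 1, 1, 457),
      t_("unreduced", FALSE, "parthenogenetic", NA, 2L, FALSE, 1.5, 1.5, 289),
      t_("unreduced", FALSE, "parthenogenetic", NA, 2L, FALSE, 2, 2, 136),
      t_("unreduced", FALSE, "parthenogenetic", NA, 2L, FALSE, 1, NA, 83),
      t_("unreduced", FALSE, "parthenogenetic", NA, 2L, FALSE, 1.5, NA, 54),
      t_("unreduced", FALSE, "parthenogenetic", NA, 2L, FALSE, NA, NA, 4),
      t_("unreduced", FALSE, "parthenogenetic", NA, 3L, FALSE, 2, NA, 61),
      t_("reduced", FALSE, "fertilized", 2, 2L, FALSE, 2, NA, 1),
      t_("unreduced", FALSE, "fertilized", 1, 2L, FALSE, 1, NA, 31),
      t_("unreduced", FALSE, "fertilized", 1.5, 2L, FALSE, 1.5, NA, 8),
      t_("unreduced", FALSE, "fertilized", 2, 2L, FALSE, 2, NA, 5),
      t_("unreduced", FALSE, "fertilized", 1, 2L, FALSE, 1, 1, 27),
      t_("unreduced", TRUE, "parthenogenetic", NA, 2L, FALSE, 1, 1, 6)),
    "4" = rbind(
      t_("unreduced", FALSE, "parthenogenetic", NA, 2L, FALSE, 2, 2, 56),
      t_("unreduced", FALSE, "parthenogenetic", NA, 2L, FALSE, 1.5, 2, 17),
      t_("unreduced", FALSE, "parthenogenetic", NA, 2L, FALSE, 2, NA, 9),
      t_("unreduced", FALSE, "parthenogenetic", NA, 3L, FALSE, 2, NA, 14),
      t_("unreduced", FALSE, "parthenogenetic", NA, 2L, FALSE, 1, 2, 2),
      t_("reduced", FALSE, "parthenogenetic", NA, 2L, FALSE, 2, 2, 6),
      t_("reduced", FALSE, "fertilized", 2, 2L, FALSE, 2, NA, 4),
      t_("unreduced", FALSE, "fertilized", 2, 2L, FALSE, 2, NA, 2)),
    stop("no default templates for maternal level ", maternal_level,
         call. = FALSE)
  )
  tpl$prob <- tpl$weight / sum(tpl$weight)
  tpl$weight <- NULL
  tpl
}

#' Profile of one mother tree for the synthetic seed-family generator
#'
#' @param mother_id tree identifier.
#' @param maternal_level maternal ploidy (grid level).
#' @param maternal_2c maternal 2C in pg; default is the midpoint of the
#'   published cytotype range.
#' @param templates scenario templates with `prob` column; default
#'   [default_pathway_templates()] for the cytotype.
#' @param cv measurement CV (percent) per tissue, named vector with
#'   entries `embryo`, `endosperm`, `standard`. Default 3% throughout, a
#'   typical good seed-screen histogram.
#' @param p_missing_endosperm,p_multiple_signals failure-mode
#'   probabilities; defaults (0.03, 0.005) approximate the observed rates
#'   of missing and multiple endosperm signals.
#' @return object of class `fcss_tree_profile`.
#' @export
tree_profile <- function(mother_id, maternal_level, maternal_2c = NULL,
                         templates = NULL,
                         cv = c(embryo = 3, endosperm = 3, standard = 3),
                         p_missing_endosperm = 0.03,
                         p_multiple_signals = 0.005) {
  if (is.null(templates)) templates <- default_pathway_templates(maternal_level)
  if (abs(sum(templates$prob) - 1) > 1e-6) {
    stop("template probabilities must sum to 1", call. = FALSE)
  }
  if (any(cv <= 0)) stop("cv must be positive", call. = FALSE)
  if (is.null(maternal_2c)) {
    rg <- .td_ranges()
    hit <- which(rg$level_x == maternal_level)
    maternal_2c <- if (length(hit)) {
      (rg$low_pg[hit] + rg$high_pg[hit]) / 2
    } else {
      0.76 * maternal_level  # extrapolated monoploid size
    }
  }
  structure(list(mother_id = mother_id, maternal_level = maternal_level,
                 maternal_2c = maternal_2c, templates = templates,
                 cv = cv, p_missing_endosperm = p_missing_endosperm,
                 p_multiple_signals = p_multiple_signals),
            class = "fcss_tree_profile")
}

#' Generate a synthetic population of mother trees
#'
#' @param cytotype_proportions named numeric vector of percentages per
#'   ploidy level (names are levels, e.g. `c("2" = 35.71, "3" = 46.43,
#'   "4" = 17.86)`); must sum to 100.
#' @param n_trees number of trees.
#' @param seed RNG seed (reproducible populations).
#' @param rounding `"multinomial"` draws counts, `"deterministic"` uses
#'   largest-remainder apportionment of the expected counts.
#' @param ... further arguments passed to [tree_profile()].
#' @return list of `fcss_tree_profile` objects. Maternal 2C values are
#'   drawn uniformly within the published cytotype range.
#' @export
make_population <- function(cytotype_proportions, n_trees, seed = 1,
                            rounding = c("multinomial", "deterministic"),
                            ...) {
  rounding <- match.arg(rounding)
  p <- cytotype_proportions
  if (abs(sum(p) - 100) > 1e-6) {
    stop("cytotype proportions must sum to 100", call. = FALSE)
  }
  levels <- as.numeric(names(p))
  if (any(is.na(levels))) {
    stop("cytotype_proportions must be named by ploidy level", call. = FALSE)
  }
  set.seed(seed)
  counts <- if (rounding == "multinomial") {
    as.vector(stats::rmultinom(1, n_trees, p / 100))
  } else {
    exp_ <- n_trees * p / 100
    base <- floor(exp_)
    rem <- n_trees - sum(base)
    if (rem > 0) {
      extra <- order(exp_ - base, decreasing = TRUE)[seq_len(rem)]
      base[extra] <- base[extra] + 1
    }
    as.integer(base)
  }
  rg <- .td_ranges()
  profiles <- list()
  idx <- 0L
  for (ci in seq_along(levels)) {
    lev <- levels[ci]
    hit <- which(rg$level_x == lev)
    for (t in seq_len(counts[ci])) {
      idx <- idx + 1L
      twoc <- if (length(hit)) {
        stats::runif(1, rg$low_pg[hit], rg$high_pg[hit])
      } else NULL
      profiles[[idx]] <- tree_profile(
        mother_id = sprintf("T%02d_%sx", idx, format(lev)),
        maternal_level = lev, maternal_2c = twoc, ...)
    }
  }
  profiles
}

.STANDARD_CHANNEL <- 200  # channel position of the IRS G0/G1 peak

#' Simulate a seed family with known ground truth
#'
#' Scenarios are drawn from the tree's template distribution, true embryo
#' and endosperm levels follow the same conservation equations as the
#' pathway engine ([scenario_levels()]), and G0/G1 peak means are emitted
#' with multiplicative Gaussian noise at the profile's CV. Failure modes
#' (missing endosperm signal, multiple endosperm signals) are injected at
#' the profile's rates.
#'
#' @param profile a [tree_profile()].
#' @param n_seeds number of seeds.
#' @param seed RNG seed.
#' @param standard internal reference standard co-chopped with every seed.
#' @return list with `truth` (per-seed hidden scenario and exact levels)
#'   and `peaks` (emitted peak table: `sample_id`, `tissue`, `peak_mean`,
#'   `cv`, `n_nuclei`).
#' @export
simulate_seed_family <- function(profile, n_seeds, seed = 1,
                                 standard = reference_standard("pisum")) {
  stopifnot(inherits(profile, "fcss_tree_profile"))
  set.seed(seed)
  tpl <- profile$templates
  pick <- sample.int(nrow(tpl), n_seeds, replace = TRUE, prob = tpl$prob)
  sc <- tpl[pick, , drop = FALSE]
  lv <- scenario_levels(profile$maternal_level, sc$sac, sc$sac_ep,
                        sc$sperm_to_egg, sc$central_nuclei, sc$end_ep,
                        sc$s1, sc$s2)
  monoploid_pg <- profile$maternal_2c / profile$maternal_level
  seed_ids <- sprintf("%s_s%04d", profile$mother_id, seq_len(n_seeds))
  truth <- data.frame(seed_id = seed_ids, mother_id = profile$mother_id,
                      maternal_level = profile$maternal_level,
                      sc, lv, row.names = NULL)
  truth$category <- format_category_label(lv$embryo_level, lv$endosperm_level)
  truth$missing_endosperm <-
    stats::runif(n_seeds) < profile$p_missing_endosperm
  truth$multiple_signals <- !truth$missing_endosperm &
    stats::runif(n_seeds) < profile$p_multiple_signals

  noisy <- function(level, cv) {
    ideal <- .STANDARD_CHANNEL * (level * monoploid_pg) / standard$twoC_pg
    ideal * pmax(0.01, 1 + stats::rnorm(length(level), 0, cv / 100))
  }
  cv <- profile$cv
  peak_rows <- list(
    data.frame(sample_id = seed_ids, tissue = "embryo",
               peak_mean = noisy(lv$embryo_level, cv[["embryo"]]),
               cv = cv[["embryo"]], n_nuclei = 1500L),
    data.frame(sample_id = seed_ids, tissue = "standard",
               peak_mean = .STANDARD_CHANNEL *
                 pmax(0.01, 1 + stats::rnorm(n_seeds, 0, cv[["standard"]] / 100)),
               cv = cv[["standard"]], n_nuclei = 1200L)
  )
  keep_end <- !truth$missing_endosperm
  if (any(keep_end)) {
    peak_rows[[3L]] <- data.frame(
      sample_id = seed_ids[keep_end], tissue = "endosperm",
      peak_mean = noisy(lv$endosperm_level[keep_end], cv[["endosperm"]]),
      cv = cv[["endosperm"]], n_nuclei = 400L)
  }
  dup <- truth$multiple_signals
  if (any(dup)) {
    # spurious second endosperm population one level up
    peak_rows[[length(peak_rows) + 1L]] <- data.frame(
      sample_id = seed_ids[dup], tissue = "endosperm",
      peak_mean = noisy(lv$endosperm_level[dup] + 1, cv[["endosperm"]]),
      cv = cv[["endosperm"]], n_nuclei = 300L)
  }
  peaks <- do.call(rbind, peak_rows)
  peaks <- peaks[order(peaks$sample_id, peaks$tissue), , drop = FALSE]
  rownames(peaks) <- NULL
  list(truth = truth, peaks = peaks)
}

#' Screen emitted peak tables back into seed records
#'
#' The analysis-side counterpart of [simulate_seed_family()]: applies QC,
#' resolves the embryo ploidy through the internal standard and the
#' maternal 2C value, resolves the endosperm ploidy against the embryo
#' peak, and assigns exclusion statuses for missing/multiple signals and QC
#' failures.
#'
#' @param peaks peak table (`sample_id`, `tissue`, `peak_mean`, `cv`,
#'   `n_nuclei`).
#' @param mother_id,maternal_level,maternal_2c maternal context.
#' @param standard the internal reference standard used.
#' @param thresholds QC thresholds ([qc_thresholds()]).
#' @param tolerance snapping tolerance, see [snap_level()].
#' @return data frame of seed-screen records suitable for
#'   [classify_seeds()].
#' @export
screen_seed_family <- function(peaks, mother_id, maternal_level, maternal_2c,
                               standard = reference_standard("pisum"),
                               thresholds = qc_thresholds(),
                               tolerance = 0.25) {
  peaks <- qc_filter(peaks, thresholds)
  ids <- unique(peaks$sample_id)
  count_tissue <- function(tis) {
    as.integer(table(factor(peaks$sample_id[peaks$tissue == tis],
                            levels = ids)))
  }
  pick <- function(tis, col) {
    sel <- peaks[peaks$tissue == tis, , drop = FALSE]
    sel[[col]][match(ids, sel$sample_id)]
  }
  n_emb <- count_tissue("embryo")
  n_end <- count_tissue("endosperm")
  n_std <- count_tissue("standard")
  status <- rep("ok", length(ids))
  status[n_emb == 0L | n_end == 0L | n_std == 0L] <- "excluded_missing_signal"
  status[status == "ok" & (n_emb > 1L | n_end > 1L)] <-
    "excluded_multiple_signals"
  emb_peak <- pick("embryo", "peak_mean")
  std_peak <- pick("standard", "peak_mean")
  end_peak <- pick("endosperm", "peak_mean")
  qc_ok <- pick("embryo", "qc_pass") & pick("standard", "qc_pass") &
    pick("endosperm", "qc_pass")
  status[status == "ok" & !qc_ok] <- "excluded_qc"
  ok <- status == "ok"
  emb_level <- rep(NA_real_, length(ids))
  end_level <- rep(NA_real_, length(ids))
  if (any(ok)) {
    emb_2c <- compute_2c(emb_peak[ok], std_peak[ok], standard)$value_pg
    emb_call <- snap_level(maternal_level * emb_2c / maternal_2c,
                           tolerance = tolerance)
    end_call <- call_seed_tissue_ploidy(end_peak[ok], emb_peak[ok],
                                        emb_call$level_x,
                                        tolerance = tolerance)
    resolved <- emb_call$resolved & end_call$resolved
    emb_level[ok] <- ifelse(resolved, emb_call$level_x, NA_real_)
    end_level[ok] <- ifelse(resolved, end_call$level_x, NA_real_)
    status[ok][!resolved] <- "excluded_qc"
  }
  data.frame(seed_id = ids, mother_id = mother_id,
             maternal_level = maternal_level,
             embryo_level = emb_level, endosperm_level = end_level,
             status = status, stringsAsFactors = FALSE)
}

#' In-paper fixture tables shipped with the package
#'
#' Machine-readable copies of the published per-tree sample sizes (fruits,
#' seeds analyzed, seeds successfully screened) and the per-cytotype
#' seed-category counts, for acceptance testing without any download.
#'
#' @return list with data frames `trees` and `seed_categories`.
#' @export
fixture_tables <- function() {
  trees <- utils::read.csv(system.file("extdata", "table2_trees.csv",
                                       package = "seedscreen"),
                           stringsAsFactors = FALSE)
  cats <- utils::read.csv(system.file("extdata",
                                      "table3_seed_categories.csv",
                                      package = "seedscreen"),
                          stringsAsFactors = FALSE)
  list(trees = trees, seed_categories = cats)
}

#' Expand the fixture category counts into seed-level records
#'
#' One record per seed, with per-cytotype pooled mother ids; optionally
#' appends the excluded seeds (missing or multiple signals) so that
#' screening success rates can be recomputed from the records themselves.
#' Exclusion counts per cytotype: diploids 11 missing; triploids 27 missing
#' and 7 with multiple signals; tetraploids 4 missing.
#'
#' @param include_excluded append excluded records (default TRUE).
#' @return data frame of seed-screen records.
#' @export
fixture_seed_records <- function(include_excluded = TRUE) {
  cats <- fixture_tables()$seed_categories
  rows <- cats[rep(seq_len(nrow(cats)), cats$count), , drop = FALSE]
  rec <- data.frame(
    mother_id = sprintf("%sx_pool", rows$maternal_level),
    maternal_level = rows$maternal_level,
    embryo_level = rows$embryo_level,
    endosperm_level = rows$endosperm_level,
    status = "ok", stringsAsFactors = FALSE)
  if (include_excluded) {
    excl <- rbind(
      data.frame(maternal_level = 2, status = rep("excluded_missing_signal", 11)),
      data.frame(maternal_level = 3, status = rep("excluded_missing_signal", 27)),
      data.frame(maternal_level = 3, status = rep("excluded_multiple_signals", 7)),
      data.frame(maternal_level = 4, status = rep("excluded_missing_signal", 4)))
    rec <- rbind(rec, data.frame(
      mother_id = sprintf("%sx_pool", excl$maternal_level),
      maternal_level = excl$maternal_level,
      embryo_level = NA_real_, endosperm_level = NA_real_,
      status = excl$status, stringsAsFactors = FALSE))
  }
  rec$seed_id <- sprintf("fx%04d", seq_len(nrow(rec)))
  rec[, c("seed_id", "mother_id", "maternal_level", "embryo_level",
          "endosperm_level", "status")]
}
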