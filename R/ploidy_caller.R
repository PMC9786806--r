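#' Ploidy categories on the 0.5x grid
#'
#' Seed-screen ploidy categories live on a half-integer grid: integral
#' levels (2x, 3x, ...) are euploid, half levels (~3.5x, ~9.5x, ...) are
#' aneuploid "approximate" categories. Categories above 12x are only
#' putatively identified (measurement error grows with ploidy) and carry an
#' `uncertain` flag; they are kept in tabulations but excluded from
#' sperm-ploidy reconstruction confidence.
#'
#' @param level_x ploidy level as a multiple of the monoploid genome; must
#'   be a positive multiple of 0.5.
#' @return data frame with columns `level_x`, `euploid`, `approximate`,
#'   `uncertain`.
#' @export
ploidy_category <- function(level_x) {
  if (any(!is.finite(level_x)) || any(level_x <= 0) ||
      any(abs(level_x * 2 - round(level_x * 2)) > 1e-8)) {
    stop("level_x must be positive multiples of 0.5", call. = FALSE)
  }
  eu <- abs(level_x - round(level_x)) < 1e-8
  data.frame(level_x = level_x, euploid = eu, approximate = !eu,
             uncertain = level_x > 12)
}

#' Format a ploidy level the way seed categories are written
#'
#' Euploid levels print as `"3x"`, aneuploid half levels with a leading
#' tilde, `"~9.5x"`.
#'
#' @param level_x numeric vector of grid levels.
#' @return character vector.
#' @export
format_ploidy <- function(level_x) {
  eu <- abs(level_x - round(level_x)) < 1e-8
  ifelse(eu, sprintf("%dx", as.integer(round(level_x))),
         sprintf("~%.1fx", level_x))
}

#' Snap a raw ploidy estimate to the 0.5x grid
#'
#' @param raw numeric vector of raw (unsnapped) levels.
#' @param tolerance maximal distance to the nearest grid point for the call
#'   to be considered resolved; with the default 0.25 (half the grid step)
#'   every value inside the grid span resolves.
#' @param grid_min,grid_max span of the grid (defaults 1x-20x).
#' @return data frame with `raw`, `level_x` (snapped), `resolved`.
#' @export
snap_level <- function(raw, tolerance = 0.25, grid_min = 1, grid_max = 20) {
  snapped <- round(raw * 2) / 2
  snapped <- pmin(pmax(snapped, grid_min), grid_max)
  data.frame(raw = raw, level_x = snapped,
             resolved = abs(raw - snapped) <= tolerance + 1e-9)
}

#' Published 2C ranges per cytotype
#'
#' Default ranges are the empirical Crataegus cytotype intervals:
#' 1.37-1.67 pg (2x), 2.05-2.51 pg (3x), 2.74-3.34 pg (4x),
#' 3.42-4.18 pg (5x). Intervals must be disjoint and increasing; gaps
#' between intervals are legitimate (the ranges are empirical, not
#' exhaustive) and values falling in a gap are reported as unclassified.
#'
#' @param ranges data frame with columns `level_x`, `low_pg`, `high_pg`.
#' @return object of class `fcss_cytotype_ranges`.
#' @export
cytotype_ranges <- function(ranges = NULL) {
  if (is.null(ranges)) {
    ranges <- data.frame(level_x = c(2, 3, 4, 5),
                         low_pg = c(1.37, 2.05, 2.74, 3.42),
                         high_pg = c(1.67, 2.51, 3.34, 4.18))
  }
  stopifnot(is.data.frame(ranges),
            all(c("level_x", "low_pg", "high_pg") %in% names(ranges)))
  ranges <- ranges[order(ranges$level_x), , drop = FALSE]
  if (any(ranges$low_pg >= ranges$high_pg)) {
    stop("each cytotype interval needs low_pg < high_pg", call. = FALSE)
  }
  if (nrow(ranges) > 1L &&
      any(ranges$low_pg[-1L] <= ranges$high_pg[-nrow(ranges)])) {
    stop("cytotype intervals must be disjoint and increasing", call. = FALSE)
  }
  structure(ranges, class = c("fcss_cytotype_ranges", "data.frame"))
}

#' Call the ploidy of a mature plant from its 2C value
#'
#' @param value_pg 2C DNA amount(s) in picograms (QC-passed).
#' @param ranges a [cytotype_ranges()] object.
#' @return data frame with `value_pg`, `level_x` (NA when unclassified),
#'   `status` (`"ok"` or `"unclassified"`) and `candidates` (for
#'   unclassified values, the two nearest cytotypes as `"2x|3x"`).
#' @examples
#' call_mature_ploidy(c(1.50, 2.30, 1.90))
#' @export
call_mature_ploidy <- function(value_pg, ranges = cytotype_ranges()) {
  stopifnot(is.numeric(value_pg), all(value_pg > 0))
  res <- lapply(value_pg, function(v) {
    hit <- which(v >= ranges$low_pg & v <= ranges$high_pg)
    if (length(hit) == 1L) {
      data.frame(value_pg = v, level_x = ranges$level_x[hit], status = "ok",
                 candidates = "")
    } else {
      mid <- (ranges$low_pg + ranges$high_pg) / 2
      near <- order(abs(mid - v))[seq_len(min(2L, nrow(ranges)))]
      data.frame(value_pg = v, level_x = NA_real_, status = "unclassified",
                 candidates = paste(format_ploidy(sort(ranges$level_x[near])),
                                    collapse = "|"))
    }
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Call seed-tissue ploidy from a peak ratio against a reference tissue
#'
#' The ploidy of a seed tissue is computed relative to a reference tissue of
#' known ploidy (the maternal exocarp for the embryo, the embryo for the
#' endosperm): raw level = reference level x (tissue peak / reference peak),
#' snapped to the 0.5x grid. Working on within-sample ratios cancels
#' accession-level genome-size variation; an absolute pg route is available
#' via [compute_2c()] + [call_mature_ploidy()].
#'
#' @param tissue_peak_mean,reference_peak_mean positive G0/G1 peak means.
#' @param reference_level ploidy of the reference tissue (grid level).
#' @param tolerance passed to [snap_level()].
#' @return data frame with `raw_level`, `level_x`, `euploid`, `approximate`,
#'   `uncertain`, `resolved`.
#' @examples
#' call_seed_tissue_ploidy(266.7, 100, 3)  # endosperm 8x from a 3x embryo
#' @export
call_seed_tissue_ploidy <- function(tissue_peak_mean, reference_peak_mean,
                                    reference_level, tolerance = 0.25) {
  if (any(!is.finite(tissue_peak_mean)) || any(tissue_peak_mean <= 0) ||
      any(!is.finite(reference_peak_mean)) || any(reference_peak_mean <= 0)) {
    stop("invalid measurement: non-positive peak mean", call. = FALSE)
  }
  raw <- reference_level * (tissue_peak_mean / reference_peak_mean)
  sn <- snap_level(raw, tolerance = tolerance)
  cat_ <- ploidy_category(sn$level_x)
  data.frame(raw_level = raw, level_x = sn$level_x, euploid = cat_$euploid,
             approximate = cat_$approximate, uncertain = cat_$uncertain,
             resolved = sn$resolved)
}
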