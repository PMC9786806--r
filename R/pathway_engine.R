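#' Candidate sperm-cell ploidies for pathway enumeration
#'
#' The default universe covers reduced euploid pollen of diploid and
#' tetraploid donors (1x, 2x), unbalanced aneuploid reduced pollen (~1.5x,
#' ~2.5x; the former typically shed by triploids) and unreduced pollen (3x,
#' 4x), which the enumeration treats as the least plausible contribution.
#'
#' @param levels sperm ploidies on the 0.5x grid.
#' @param unreduced subset of `levels` to be penalized as unreduced gametes.
#' @return object of class `fcss_sperm_set`.
#' @export
sperm_candidates <- function(levels = c(1, 1.5, 2, 2.5, 3, 4),
                             unreduced = c(3, 4)) {
  if (!length(levels) || any(!is.finite(levels)) || any(levels <= 0) ||
      any(abs(levels * 2 - round(levels * 2)) > 1e-8)) {
    stop("sperm levels must be a non-empty set of positive 0.5x-grid values",
         call. = FALSE)
  }
  levels <- sort(unique(levels))
  structure(list(levels = levels,
                 unreduced = intersect(unreduced, levels)),
            class = "fcss_sperm_set")
}

#' @export
print.fcss_sperm_set <- function(x, ...) {
  cat("FCSS sperm candidate set:", paste(format_ploidy(x$levels), collapse = ", "),
      "\n  unreduced:", paste(format_ploidy(x$unreduced), collapse = ", "), "\n")
  invisible(x)
}

.on_grid <- function(x) {
  is.finite(x) & x > 0 & abs(x * 2 - round(x * 2)) < 1e-8
}

#' Embryo and endosperm levels implied by a reproduction scenario
#'
#' The conservation equations shared by the pathway engine and the
#' synthetic-data generator: egg ploidy is half the maternal level for a
#' reduced sac, the full level for an unreduced one, doubled again by
#' sac-level endoreplication; the central cell carries `central_nuclei`
#' polar nuclei of egg ploidy; the embryo is egg plus (at most one) sperm,
#' the endosperm is central cell plus 0-2 sperm, doubled by endosperm
#' endoreplication.
#'
#' @param maternal maternal ploidy level(s).
#' @param sac `"reduced"` or `"unreduced"`.
#' @param sac_ep,end_ep logical: sac-level / endosperm endoreplication.
#' @param sperm_to_egg sperm ploidy fertilizing the egg, `NA` for
#'   parthenogenesis.
#' @param central_nuclei 2 (binucleate) or 3 (trinucleate central cell).
#' @param s1,s2 sperm ploidies contributing to the central cell (`NA` for
#'   absent).
#' @return data frame with `egg_ploidy`, `central_ploidy`, `embryo_level`,
#'   `endosperm_level`.
#' @export
scenario_levels <- function(maternal, sac, sac_ep = FALSE,
                            sperm_to_egg = NA_real_, central_nuclei = 2L,
                            end_ep = FALSE, s1 = NA_real_, s2 = NA_real_) {
  egg <- ifelse(sac == "reduced", maternal / 2, maternal) *
    ifelse(sac_ep, 2, 1)
  central <- central_nuclei * egg
  sperm_sum <- ifelse(is.na(s1), 0, s1) + ifelse(is.na(s2), 0, s2)
  data.frame(
    egg_ploidy = egg,
    central_ploidy = central,
    embryo_level = egg + ifelse(is.na(sperm_to_egg), 0, sperm_to_egg),
    endosperm_level = (central + sperm_sum) * ifelse(end_ep, 2, 1)
  )
}

# Full scenario universe for one maternal ploidy and sperm set. Cached: the
# universe does not depend on the observed embryo/endosperm levels.
.scenario_cache <- new.env(parent = emptyenv())

.scenario_universe <- function(maternal, sperm_set) {
  key <- paste0("m", maternal, "|", paste(sperm_set$levels, collapse = ","),
                "|u", paste(sperm_set$unreduced, collapse = ","))
  if (!is.null(.scenario_cache[[key]])) return(.scenario_cache[[key]])
  sl <- sperm_set$levels
  # multisets of size 0-2 drawn from the sperm set (canonical s1 <= s2)
  pairs <- expand.grid(s1 = sl, s2 = sl)
  pairs <- pairs[pairs$s1 <= pairs$s2, , drop = FALSE]
  central_sperm <- rbind(data.frame(s1 = NA_real_, s2 = NA_real_),
                         data.frame(s1 = sl, s2 = NA_real_),
                         pairs)
  g <- expand.grid(sac = c("reduced", "unreduced"),
                   sac_ep = c(FALSE, TRUE),
                   egg_fate = c("parthenogenetic", "fertilized"),
                   sperm_to_egg = c(NA_real_, sl),
                   central_nuclei = c(2L, 3L),
                   end_ep = c(FALSE, TRUE),
                   cs = seq_len(nrow(central_sperm)),
                   stringsAsFactors = FALSE)
  # egg fertilization needs exactly one sperm; parthenogenesis none
  g <- g[(g$egg_fate == "fertilized") == !is.na(g$sperm_to_egg), , drop = FALSE]
  g$s1 <- central_sperm$s1[g$cs]
  g$s2 <- central_sperm$s2[g$cs]
  g$cs <- NULL
  # double fertilization: a pollen tube that fertilized the egg also
  # delivered its sibling sperm, so a fertilized egg with a completely
  # unfertilized central cell is not an admissible scenario
  g <- g[!(g$egg_fate == "fertilized" & is.na(g$s1)), , drop = FALSE]

  lv <- scenario_levels(maternal, g$sac, g$sac_ep, g$sperm_to_egg,
                        g$central_nuclei, g$end_ep, g$s1, g$s2)
  g$egg_ploidy <- lv$egg_ploidy
  g$central_ploidy <- lv$central_ploidy
  g$embryo_level <- lv$embryo_level
  g$endosperm_level <- lv$endosperm_level
  sperm_sum <- ifelse(is.na(g$s1), 0, g$s1) + ifelse(is.na(g$s2), 0, g$s2)
  g$n_sperm_central <- (!is.na(g$s1)) + (!is.na(g$s2))

  g$label <- ifelse(g$sac == "unreduced",
                    ifelse(g$egg_fate == "fertilized", "B_III",
                           "parthenogenetic"),
                    ifelse(g$egg_fate == "fertilized", "sexual",
                           "reduced_parthenogenesis"))
  g$endosperm_mode <- ifelse(g$n_sperm_central == 0,
                             ifelse(g$end_ep | g$sac_ep,
                                    "autonomous_plus_endoreplication",
                                    "autonomous"),
                             "pseudogamous")
  g$endoreplication <- g$end_ep | g$sac_ep
  g$polyspermy <- g$n_sperm_central +
    (g$egg_fate == "fertilized") > 2
  # maternal:paternal genome dose in the endosperm
  g$mp_maternal <- g$central_ploidy * ifelse(g$end_ep, 2, 1)
  g$mp_paternal <- sperm_sum * ifelse(g$end_ep, 2, 1)
  g$mp_ratio <- ifelse(g$mp_paternal > 0,
                       sprintf("%gm:%gp", g$mp_maternal, g$mp_paternal),
                       sprintf("%gm:0p", g$mp_maternal))
  g$mp_balanced <- g$mp_paternal > 0 &
    abs(g$mp_maternal - 2 * g$mp_paternal) < 1e-8

  # ---- plausibility cost ------------------------------------------------
  # Rank components, most significant first:
  #   1. apomictic components in a diploid mother (gametophytic apomixis is
  #      effectively absent from diploid hawthorns),
  #   2. number of unreduced(-like) sperm cells: a sperm is implausible if
  #      it is in the declared unreduced set or at/above the maternal level
  #      (for the mother's own pollen pool it would have to be unreduced),
  #   3. number of aneuploid sperm cells,
  #   4. endoreplication events (sac- or endosperm-level),
  #   5. trinucleate central cell.
  # |n_sperm_to_central - 2| orders presentation within a rank only (two-
  # sperm fertilization of the central cell is the more frequent route) so
  # that Table-style alternative sperm compositions stay tied.
  all_sperm <- cbind(ifelse(is.na(g$sperm_to_egg), NA, g$sperm_to_egg),
                     g$s1, g$s2)
  is_unred <- matrix(!is.na(all_sperm) &
                       (all_sperm %in% sperm_set$unreduced |
                          all_sperm >= maternal - 1e-8),
                     nrow = nrow(g))
  is_aneu <- matrix(!is.na(all_sperm) &
                      abs(all_sperm - round(all_sperm)) > 1e-8,
                    nrow = nrow(g))
  g$cost_apo_diploid <- if (maternal <= 2) {
    (g$sac == "unreduced") + (g$egg_fate == "parthenogenetic")
  } else 0L
  g$cost_unreduced_sperm <- rowSums(is_unred)
  g$cost_aneuploid_sperm <- rowSums(is_aneu)
  g$cost_trinucleate <- as.integer(g$central_nuclei == 3L)
  g$cost_endoreplication <- as.integer(g$sac_ep) + as.integer(g$end_ep)
  g$presentation <- abs(g$n_sperm_central - 2L)
  g$encoding <- sprintf("%s|sacep%d|%s|e%s|cn%d|ep%d|c%s+%s",
                        g$sac, g$sac_ep, g$egg_fate,
                        ifelse(is.na(g$sperm_to_egg), "-", g$sperm_to_egg),
                        g$central_nuclei, g$end_ep,
                        ifelse(is.na(g$s1), "-", g$s1),
                        ifelse(is.na(g$s2), "-", g$s2))
  rownames(g) <- NULL
  .scenario_cache[[key]] <- g
  g
}

#' Enumerate reproduction-pathway explanations for a ploidy triple
#'
#' Exhaustively enumerates embryo-sac reduction (reduced/unreduced, with or
#' without sac-level endoreplication), egg fate (parthenogenesis vs
#' fertilization by one sperm), central-cell constitution (binucleate or
#' trinucleate), 0-2 sperm contributions to the central cell, and endosperm
#' endoreplication, keeping every scenario whose embryo and endosperm
#' conservation equations match the observed levels within `tolerance`.
#' Scenarios are ranked by a lexicographic plausibility cost (see
#' [sperm_candidates()] and the package vignette); all co-optimal scenarios
#' are returned as ties.
#'
#' @param maternal,embryo,endosperm ploidy levels on the 0.5x grid.
#' @param sperm_set a [sperm_candidates()] object.
#' @param tolerance maximal |observed - scenario| level difference; the
#'   default 0.25 (half a grid step) makes grid inputs match exactly.
#' @return object of class `fcss_explanations`: a data frame of admissible
#'   scenarios ordered best-first, with logical column `is_top` marking the
#'   co-optimal set. Zero rows mean the triple is unresolved.
#' @examples
#' enumerate_explanations(2, 2, 3)   # sexual, 1x sperm to egg and central
#' enumerate_explanations(3, 3, 8)   # parthenogenetic; 1x+1x or 2x tie
#' @export
enumerate_explanations <- function(maternal, embryo, endosperm,
                                   sperm_set = sperm_candidates(),
                                   tolerance = 0.25) {
  if (!.on_grid(maternal) || !.on_grid(embryo) || !.on_grid(endosperm)) {
    stop("maternal, embryo and endosperm levels must lie on the 0.5x grid",
         call. = FALSE)
  }
  if (!inherits(sperm_set, "fcss_sperm_set")) {
    stop("sperm_set must be a sperm_candidates() object", call. = FALSE)
  }
  g <- .scenario_universe(maternal, sperm_set)
  keep <- abs(g$embryo_level - embryo) <= tolerance + 1e-9 &
    abs(g$endosperm_level - endosperm) <= tolerance + 1e-9
  g <- g[keep, , drop = FALSE]
  if (nrow(g)) {
    ord <- order(g$cost_apo_diploid, g$cost_unreduced_sperm,
                 g$cost_aneuploid_sperm, g$cost_endoreplication,
                 g$cost_trinucleate, g$presentation, g$encoding)
    g <- g[ord, , drop = FALSE]
    key <- paste(g$cost_apo_diploid, g$cost_unreduced_sperm,
                 g$cost_aneuploid_sperm, g$cost_endoreplication,
                 g$cost_trinucleate)
    g$is_top <- key == key[[1L]]
    rownames(g) <- NULL
  } else {
    g$is_top <- logical(0)
  }
  attr(g, "triple") <- c(maternal = maternal, embryo = embryo,
                         endosperm = endosperm)
  class(g) <- c("fcss_explanations", "data.frame")
  g
}

#' @export
print.fcss_explanations <- function(x, ...) {
  tr <- attr(x, "triple")
  cat(sprintf("Explanations for maternal %s, %s_emb/%s_end: %d admissible, %d top\n",
              format_ploidy(tr[["maternal"]]),
              format_ploidy(tr[["embryo"]]), format_ploidy(tr[["endosperm"]]),
              nrow(x), sum(x$is_top)))
  if (nrow(x)) {
    top <- x[x$is_top, c("label", "sac", "egg_fate", "sperm_to_egg",
                         "central_nuclei", "s1", "s2", "endoreplication",
                         "endosperm_mode", "mp_ratio", "polyspermy")]
    print.data.frame(top, row.names = FALSE)
  }
  invisible(x)
}

#' Seed-category label in the field's notation
#'
#' @param embryo,endosperm grid ploidy levels.
#' @return e.g. `"3x_emb/~9.5x_end"`.
#' @export
format_category_label <- function(embryo, endosperm) {
  paste0(format_ploidy(embryo), "_emb/", format_ploidy(endosperm), "_end")
}

#' Flag the questionable seed classes excluded from meiosis evidence
#'
#' Three classes of classified seeds are flagged because measurement error
#' cannot be excluded: (i) endosperm one half-step below twice the maternal
#' level with a maternal-level embryo (e.g. 3x_emb/~5.5x_end, nearly 6x) —
#' would otherwise count as reduced-sac evidence; (ii) an aneuploid embryo
#' one half-step above the maternal level with endosperm at or above three
#' times the maternal level (e.g. ~3.5x_emb/9x-12x_end) — the embryo is
#' treated as a mismeasured maternal-level (unreduced) embryo; (iii)
#' endosperm above 12x, where category identification is only putative (this
#' class stays in all rate numerators and only reduces sperm-reconstruction
#' confidence).
#'
#' @param maternal,embryo,endosperm vectors of grid levels (recycled).
#' @return character vector: `"near_unreduced_endosperm"`,
#'   `"aneuploid_embryo_high_endosperm"`, `"high_endosperm_uncertain"` or
#'   `"none"`.
#' @export
flag_questionable <- function(maternal, embryo, endosperm) {
  n <- max(length(maternal), length(embryo), length(endosperm))
  maternal <- rep_len(maternal, n)
  embryo <- rep_len(embryo, n)
  endosperm <- rep_len(endosperm, n)
  out <- rep("none", n)
  out[endosperm > 12] <- "high_endosperm_uncertain"
  aneu_emb <- abs(embryo - (maternal + 0.5)) < 1e-8 &
    endosperm >= 3 * maternal - 1e-8
  out[aneu_emb] <- "aneuploid_embryo_high_endosperm"
  near6 <- abs(embryo - maternal) < 1e-8 &
    abs(endosperm - (2 * maternal - 0.5)) < 1e-8
  out[near6] <- "near_unreduced_endosperm"
  out
}

#' Classify one seed-screen record
#'
#' @param record a one-row data frame (or list) with fields `maternal_level`,
#'   `embryo_level`, `endosperm_level` and `status` (one of `"ok"`,
#'   `"excluded_missing_signal"`, `"excluded_multiple_signals"`,
#'   `"excluded_qc"`).
#' @param sperm_set,tolerance passed to [enumerate_explanations()].
#' @return list with `status`, and for `"ok"` records `label`, the ranked
#'   `explanations`, the `top` co-optimal subset and the `questionable`
#'   class.
#' @export
classify_seed <- function(record, sperm_set = sperm_candidates(),
                          tolerance = 0.25) {
  if (record$status != "ok") {
    return(list(status = record$status, label = NA_character_,
                explanations = NULL, top = NULL, questionable = NA_character_))
  }
  ex <- enumerate_explanations(record$maternal_level, record$embryo_level,
                               record$endosperm_level, sperm_set, tolerance)
  list(status = "ok",
       label = format_category_label(record$embryo_level,
                                     record$endosperm_level),
       explanations = ex,
       top = ex[ex$is_top, , drop = FALSE],
       questionable = flag_questionable(record$maternal_level,
                                        record$embryo_level,
                                        record$endosperm_level))
}

#' Classify a table of seed-screen records
#'
#' Vectorized, memoized front end to [enumerate_explanations()]: distinct
#' (maternal, embryo, endosperm) triples are enumerated once and the
#' top-ranked interpretation is joined back onto the records.
#'
#' @param records data frame with columns `seed_id`, `mother_id`,
#'   `maternal_level`, `embryo_level`, `endosperm_level`, `status`.
#' @param sperm_set,tolerance passed to [enumerate_explanations()].
#' @return `records` with appended columns: `label`, `embryo_mode`
#'   (S/P/B_III/rP of the top explanation), `endosperm_mode`,
#'   `endoreplication`, `trinucleate`, `polyspermy` (TRUE if any co-optimal
#'   scenario involves >2 sperm), `mp_balanced` (all co-optimal scenarios
#'   carry a 2m:1p dose), `sac`, `egg_fate`, `tie_count`, `unresolved`,
#'   `questionable`.
#' @export
classify_seeds <- function(records, sperm_set = sperm_candidates(),
                           tolerance = 0.25) {
  stopifnot(is.data.frame(records))
  need <- c("maternal_level", "embryo_level", "endosperm_level", "status")
  miss <- setdiff(need, names(records))
  if (length(miss)) {
    stop("records is missing required columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  ok <- records$status == "ok"
  n <- nrow(records)
  out <- records
  out$label <- NA_character_
  out$embryo_mode <- NA_character_
  out$endosperm_mode <- NA_character_
  out$endoreplication <- NA
  out$trinucleate <- NA
  out$polyspermy <- NA
  out$mp_balanced <- NA
  out$sac <- NA_character_
  out$egg_fate <- NA_character_
  out$tie_count <- NA_integer_
  out$unresolved <- NA
  out$questionable <- NA_character_
  if (!any(ok)) return(out)

  key <- paste(records$maternal_level, records$embryo_level,
               records$endosperm_level)[ok]
  uniq <- !duplicated(key)
  ukey <- key[uniq]
  um <- records$maternal_level[ok][uniq]
  ue <- records$embryo_level[ok][uniq]
  ud <- records$endosperm_level[ok][uniq]
  mode_map <- c(sexual = "S", parthenogenetic = "P", B_III = "B_III",
                reduced_parthenogenesis = "rP")
  res <- lapply(seq_along(ukey), function(i) {
    ex <- enumerate_explanations(um[i], ue[i], ud[i], sperm_set, tolerance)
    top <- ex[ex$is_top, , drop = FALSE]
    if (!nrow(top)) {
      return(data.frame(embryo_mode = NA_character_,
                        endosperm_mode = NA_character_, endoreplication = NA,
                        trinucleate = NA, polyspermy = NA, mp_balanced = NA,
                        sac = NA_character_, egg_fate = NA_character_,
                        tie_count = 0L, unresolved = TRUE))
    }
    b <- top[1L, ]
    data.frame(embryo_mode = unname(mode_map[[b$label]]),
               endosperm_mode = b$endosperm_mode,
               endoreplication = b$endoreplication,
               trinucleate = b$central_nuclei == 3L,
               polyspermy = any(top$polyspermy),
               mp_balanced = all(top$mp_balanced),
               sac = b$sac, egg_fate = b$egg_fate,
               tie_count = nrow(top), unresolved = FALSE)
  })
  res <- do.call(rbind, res)
  idx <- match(key, ukey)
  fill <- res[idx, , drop = FALSE]
  out$label[ok] <- format_category_label(records$embryo_level[ok],
                                         records$endosperm_level[ok])
  for (col in names(res)) out[[col]][ok] <- fill[[col]]
  out$questionable[ok] <- flag_questionable(records$maternal_level[ok],
                                            records$embryo_level[ok],
                                            records$endosperm_level[ok])
  out
}
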