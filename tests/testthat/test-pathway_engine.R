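top_of <- function(m, e, d) {
  ex <- enumerate_explanations(m, e, d)
  ex[ex$is_top, , drop = FALSE]
}

test_that("canonical triples resolve to the expected pathway", {
  # (maternal, embryo, endosperm) -> label / endosperm mode / extras
  t1 <- top_of(2, 2, 3)
  expect_equal(unique(t1$label), "sexual")
  expect_equal(unique(t1$endosperm_mode), "pseudogamous")
  expect_equal(t1$mp_ratio, "2m:1p")
  expect_true(all(t1$mp_balanced))

  t2 <- top_of(3, 3, 8)   # parthenogenetic; 1x+1x or 2x tie
  expect_equal(unique(t2$label), "parthenogenetic")
  expect_equal(nrow(t2), 2L)
  comps <- sort(unname(apply(t2[, c("s1", "s2")], 1, function(r)
    paste(r[!is.na(r)], collapse = "+"))))
  expect_equal(comps, c("1+1", "2"))

  t3 <- top_of(3, 4, 7)   # B_III: 3x egg + 1x sperm, 6x central + 1x
  expect_equal(unique(t3$label), "B_III")
  expect_equal(t3$sperm_to_egg, 1)

  t4 <- top_of(3, 3, 6)   # autonomous endosperm
  expect_equal(unique(t4$label), "parthenogenetic")
  expect_equal(unique(t4$endosperm_mode), "autonomous")

  t5 <- top_of(2, 2, 6)   # sexual + endosperm endoreplication (3x * 2)
  expect_equal(unique(t5$label), "sexual")
  expect_true(all(t5$endoreplication))

  t6 <- top_of(4, 2, 8)   # reduced parthenogenesis, 4x central + 2x + 2x
  expect_equal(unique(t6$label), "reduced_parthenogenesis")
  expect_equal(unlist(t6[, c("s1", "s2")], use.names = FALSE), c(2, 2))

  t7 <- top_of(4, 4, 12)  # parthenogenetic, 8x central + 2x + 2x; 2m:1p
  expect_equal(unique(t7$label), "parthenogenetic")
  expect_true(all(t7$mp_balanced))

  t8 <- top_of(3, 5, 8)   # B_III with a polyspermy scenario among the ties
  expect_equal(unique(t8$label), "B_III")
  expect_true(any(t8$polyspermy))

  expect_equal(nrow(enumerate_explanations(2, 2, 2)), 0L)  # unresolved
  expect_error(enumerate_explanations(2, 2.3, 3), "grid")
})

test_that("every returned scenario satisfies the conservation equations", {
  set.seed(31)
  grid_m <- c(2, 3, 4)
  for (i in 1:40) {
    m <- sample(grid_m, 1)
    e <- sample(seq(1, 8, 0.5), 1)
    d <- sample(seq(2, 20, 0.5), 1)
    ex <- enumerate_explanations(m, e, d)
    if (!nrow(ex)) next
    lv <- scenario_levels(m, ex$sac, ex$sac_ep, ex$sperm_to_egg,
                          ex$central_nuclei, ex$end_ep, ex$s1, ex$s2)
    expect_equal(lv$embryo_level, ex$embryo_level)
    expect_equal(lv$endosperm_level, ex$endosperm_level)
    expect_true(all(abs(ex$embryo_level - e) <= 0.25 + 1e-9))
    expect_true(all(abs(ex$endosperm_level - d) <= 0.25 + 1e-9))
    # internal consistency of the derived annotations
    expect_equal(ex$endosperm_mode == "pseudogamous", ex$n_sperm_central > 0)
    expect_equal(ex$label == "B_III",
                 ex$sac == "unreduced" & ex$egg_fate == "fertilized")
    expect_equal(ex$polyspermy,
                 ex$n_sperm_central + (ex$egg_fate == "fertilized") > 2)
  }
})

test_that("enumeration equals the brute-force oracle on random triples", {
  set.seed(77)
  universes <- lapply(c(2, 3, 4), oracle_universe)
  names(universes) <- c("2", "3", "4")
  for (i in 1:120) {
    m <- sample(c(2, 3, 4), 1)
    e <- sample(seq(1, 8, 0.5), 1)
    d <- sample(seq(2, 20, 0.5), 1)
    ex <- enumerate_explanations(m, e, d)
    expect_identical(sort(ex$encoding),
                     oracle_enumerate(universes[[as.character(m)]], e, d),
                     label = sprintf("triple (%g,%g,%g)", m, e, d))
  }
})

test_that("enumeration is deterministic with stable ordering", {
  a <- enumerate_explanations(3, 4, 8)
  b <- enumerate_explanations(3, 4, 8)
  expect_identical(a$encoding, b$encoding)
  expect_identical(a$is_top, b$is_top)
})

test_that("the top-ranked interpretation reproduces every printed category line", {
  cells <- line3_cells()
  mode_map <- c(S = "sexual", P = "parthenogenetic", B_III = "B_III",
                rP = "reduced_parthenogenesis")
  for (i in seq_len(nrow(cells))) {
    cell <- cells[i, ]
    top <- top_of(cell$maternal_level, cell$embryo_level,
                  cell$endosperm_level)
    expect_gt(nrow(top), 0)
    expect_equal(unique(top$label),
                 unname(mode_map[[cell$printed_embryo_mode]]),
                 label = paste("embryo mode of", cell$category))
    designations <- vapply(seq_len(nrow(top)), function(k)
      endosperm_designation(top[k, ]), character(1))
    expect_true(cell$printed_endosperm_mode %in% designations ||
                  (cell$printed_endosperm_mode == "pseudogamous" &&
                     all(designations == "pseudogamous")),
                label = paste("endosperm mode of", cell$category))
    if (identical(cell$footnote, "poly")) expect_true(any(top$polyspermy))
  }
})

test_that("classify_seed labels records and carries exclusions through", {
  rec <- list(maternal_level = 3, embryo_level = 3, endosperm_level = 9.5,
              status = "ok")
  out <- classify_seed(rec)
  expect_equal(out$label, "3x_emb/~9.5x_end")
  expect_equal(unique(out$top$label), "parthenogenetic")
  # aneuploid two-sperm compositions tie (1.5+2 vs 1+2.5)
  expect_equal(nrow(out$top), 2L)
  expect_true(all(out$top$cost_aneuploid_sperm == 1))

  excl <- classify_seed(list(status = "excluded_multiple_signals"))
  expect_equal(excl$status, "excluded_multiple_signals")
  expect_true(is.na(excl$label))

  b3 <- classify_seed(list(maternal_level = 4, embryo_level = 6,
                           endosperm_level = 10, status = "ok"))
  expect_equal(unique(b3$top$label), "B_III")
})

test_that("questionable classes are flagged exactly as interpreted", {
  expect_equal(flag_questionable(3, 3, 5.5), "near_unreduced_endosperm")
  expect_equal(flag_questionable(3, 3.5, 5), "none")    # valid meiosis seed
  expect_equal(flag_questionable(3, 3, 8), "none")
  expect_equal(flag_questionable(3, 3.5, c(9, 10, 12)),
               rep("aneuploid_embryo_high_endosperm", 3))
  expect_equal(flag_questionable(3, 3, 14), "high_endosperm_uncertain")
  expect_equal(flag_questionable(4, 4, 4.5), "none")
})

test_that("classify_seeds memoization matches seed-by-seed classification", {
  rec <- data.frame(seed_id = sprintf("s%d", 1:5),
                    mother_id = "m",
                    maternal_level = c(3, 3, 4, 3, 2),
                    embryo_level = c(3, 3, 4, 4, 2),
                    endosperm_level = c(8, 8, 12, 7, 3),
                    status = c("ok", "ok", "ok", "ok",
                               "excluded_missing_signal"))
  cls <- classify_seeds(rec)
  expect_equal(cls$label[1:4],
               c("3x_emb/8x_end", "3x_emb/8x_end", "4x_emb/12x_end",
                 "4x_emb/7x_end"))
  expect_equal(cls$embryo_mode[1:4], c("P", "P", "P", "B_III"))
  expect_true(is.na(cls$label[5]))
  expect_equal(cls$status[5], "excluded_missing_signal")
  expect_equal(cls$tie_count[1], 2L)
})
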