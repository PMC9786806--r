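# Independent brute-force enumerator of reproduction scenarios, written as
# plain nested loops with its own arithmetic. Returns the admissible set as
# encoding strings in the same canonical format as the package, so sets can
# be compared directly.

oracle_universe <- function(maternal, sperm_levels = c(1, 1.5, 2, 2.5, 3, 4)) {
  rows <- list()
  n <- 0L
  for (sac in c("reduced", "unreduced")) {
    for (sac_ep in c(FALSE, TRUE)) {
      egg <- (if (sac == "reduced") maternal / 2 else maternal) *
        (if (sac_ep) 2 else 1)
      for (fate in c("parthenogenetic", "fertilized")) {
        egg_sperm_opts <- if (fate == "fertilized") sperm_levels else NA_real_
        for (se in egg_sperm_opts) {
          embryo <- egg + (if (is.na(se)) 0 else se)
          for (cn in c(2L, 3L)) {
            central <- cn * egg
            # central-cell sperm multisets of size 0-2 (canonical s1 <= s2);
            # a fertilized egg implies a fertilized central cell
            combos <- list()
            if (fate != "fertilized") combos[[1L]] <- c(NA_real_, NA_real_)
            for (a in sperm_levels) combos[[length(combos) + 1L]] <- c(a, NA_real_)
            for (a in sperm_levels) {
              for (b in sperm_levels) {
                if (a <= b) combos[[length(combos) + 1L]] <- c(a, b)
              }
            }
            for (cs in combos) {
              ssum <- sum(cs, na.rm = TRUE)
              for (ep in c(FALSE, TRUE)) {
                endosperm <- (central + ssum) * (if (ep) 2 else 1)
                n <- n + 1L
                rows[[n]] <- list(sac = sac, sac_ep = sac_ep, fate = fate,
                                  se = se, cn = cn, ep = ep,
                                  s1 = cs[[1L]], s2 = cs[[2L]],
                                  embryo = embryo, endosperm = endosperm)
              }
            }
          }
        }
      }
    }
  }
  emb <- vapply(rows, `[[`, numeric(1), "embryo")
  endo <- vapply(rows, `[[`, numeric(1), "endosperm")
  enc <- vapply(rows, function(r) {
    sprintf("%s|sacep%d|%s|e%s|cn%d|ep%d|c%s+%s",
            r$sac, r$sac_ep, r$fate,
            if (is.na(r$se)) "-" else format(r$se),
            r$cn, r$ep,
            if (is.na(r$s1)) "-" else format(r$s1),
            if (is.na(r$s2)) "-" else format(r$s2))
  }, character(1))
  list(embryo = emb, endosperm = endo, encoding = enc)
}

oracle_enumerate <- function(universe, embryo, endosperm, tol = 0.25) {
  keep <- abs(universe$embryo - embryo) <= tol + 1e-9 &
    abs(universe$endosperm - endosperm) <= tol + 1e-9
  sort(universe$encoding[keep])
}

# fixture cells whose printed interpretation line is graded
line3_cells <- function() {
  cats <- fixture_tables()$seed_categories
  cats[!is.na(cats$printed_embryo_mode) &
         cats$printed_embryo_mode != "" &
         cats$printed_embryo_mode != "unresolved" &
         cats$printed_endosperm_mode != "unresolved", , drop = FALSE]
}

# engine endosperm designation in the notation of the printed line 3
endosperm_designation <- function(top_row) {
  if (top_row$endoreplication) "ep"
  else if (top_row$endosperm_mode %in%
             c("autonomous", "autonomous_plus_endoreplication")) "aute"
  else "pseudogamous"
}
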