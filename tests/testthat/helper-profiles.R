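# Species-packing community matrix along a single latent gradient, used by
# the ordination tests.
unimodal_matrix <- function(n_sites = 15, n_sp = 10, seed = 3) {
  set.seed(seed)
  pos <- seq(0, 1, length.out = n_sites)
  opt <- seq(0, 1, length.out = n_sp)
  mu <- outer(pos, opt, function(p, o) exp(-((p - o) / 0.15)^2) * 50)
  matrix(rpois(length(mu), mu), n_sites, n_sp,
         dimnames = list(paste0("s", seq_len(n_sites)),
                         paste0("sp", seq_len(n_sp))))
}

# Two triploid reproductive profiles emulating the published grouping of
# mother trees: group 1 dominated by euploid 1x-sperm endosperm categories
# (7x, 8x), group 2 by ~1.5x/2x-sperm categories (9x, ~9.5x, 10x).

two_profile_population <- function(n_per_group = 10) {
  t_ <- function(sac, se, s1, s2, w) {
    data.frame(sac = sac, sac_ep = FALSE,
               egg_fate = if (is.na(se)) "parthenogenetic" else "fertilized",
               sperm_to_egg = se, central_nuclei = 2L, end_ep = FALSE,
               s1 = s1, s2 = s2, weight = w)
  }
  finish <- function(tpl) {
    tpl$prob <- tpl$weight / sum(tpl$weight)
    tpl$weight <- NULL
    tpl
  }
  gr1 <- finish(rbind(
    t_("unreduced", NA, 1, 1, 50),    # 3x/8x
    t_("unreduced", NA, 1, NA, 30),   # 3x/7x
    t_("unreduced", NA, 2, 2, 5),     # 3x/10x
    t_("unreduced", NA, 1.5, 1.5, 5), # 3x/9x
    t_("unreduced", NA, 1.5, NA, 5),  # 3x/7.5x
    t_("unreduced", 1, 1, NA, 5)))    # 4x/7x B_III
  gr2 <- finish(rbind(
    t_("unreduced", NA, 1.5, 1.5, 35), # 3x/9x
    t_("unreduced", NA, 1.5, 2, 15),   # 3x/~9.5x
    t_("unreduced", NA, 2, 2, 30),     # 3x/10x
    t_("unreduced", NA, 1, 1, 15),     # 3x/8x
    t_("unreduced", NA, 1, NA, 5)))    # 3x/7x
  pop <- list()
  for (i in seq_len(n_per_group)) {
    pop[[i]] <- tree_profile(sprintf("gr1_%02d", i), 3, templates = gr1,
                             p_missing_endosperm = 0, p_multiple_signals = 0)
    pop[[n_per_group + i]] <-
      tree_profile(sprintf("gr2_%02d", i), 3, templates = gr2,
                   p_missing_endosperm = 0, p_multiple_signals = 0)
  }
  attr(pop, "truth") <- rep(1:2, each = n_per_group)
  pop
}

# one clustering replicate: simulate category counts per tree, filter,
# percent-max transform, Bray-Curtis, Ward k = 2; returns group agreement
two_profile_agreement <- function(seed, n_seeds = 60, n_per_group = 10) {
  pop <- two_profile_population(n_per_group)
  truth <- attr(pop, "truth")
  labels <- character(0)
  counts <- list()
  for (i in seq_along(pop)) {
    sim <- simulate_seed_family(pop[[i]], n_seeds, seed = seed * 1000 + i)
    counts[[i]] <- table(sim$truth$category)
    labels <- union(labels, names(counts[[i]]))
  }
  m <- t(vapply(counts, function(tb) {
    v <- as.numeric(tb[labels])
    v[is.na(v)] <- 0
    v
  }, numeric(length(labels))))
  dimnames(m) <- list(vapply(pop, `[[`, character(1), "mother_id"), labels)
  m <- filter_abundant_categories(m, 4)
  groups <- ward_cluster(bray_curtis(percent_max_transform(m)), k = 2)$groups
  max(mean(groups == truth), mean(groups != truth))
}
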