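test_that("missingness filter drops the planted casualty at the threshold", {
  tab <- generate_tracer_table(study_config(seed = 1))
  kept <- missingness_filter(tab, max_missing = 4)
  expect_false("d15N_Met" %in% kept)
  expect_true(all(study_config()$tracer_names %in% kept))
  # a laxer threshold retains it (4 missing < threshold 5)
  kept5 <- missingness_filter(tab, max_missing = 5)
  expect_true("d15N_Met" %in% kept5)
  ev <- attr(kept, "evidence")
  expect_equal(ev$max_missing_per_fraction[ev$variable == "d15N_Met"], 4)
  expect_equal(ev$total_missing[ev$variable == "d15N_Met"], 4)
  expect_true(all(ev$total_missing[ev$variable != "d15N_Met"] == 0))
})

test_that("missingness counting modes differ as documented", {
  tab <- data.frame(fraction = rep(c("a", "b"), each = 4),
                    v1 = c(NA, NA, 3, 4, NA, NA, 7, 8))
  # 2 per fraction, 4 total: per-fraction mode keeps at threshold 4,
  # whole-table mode drops
  expect_true("v1" %in% missingness_filter(tab, max_missing = 4,
                                           candidates = "v1"))
  expect_false("v1" %in% missingness_filter(tab, max_missing = 4,
                                            candidates = "v1",
                                            per_fraction = FALSE))
  expect_error(missingness_filter(tab[0, ]), "empty")
})

test_that("discrimination screen keeps planted tracers and drops centered noise", {
  for (seed in c(1, 2, 7)) {
    tab <- generate_tracer_table(study_config(seed = seed))
    keep <- fraction_discrimination_screen(
      tab, candidates = setdiff(attr(tab, "candidates"), "d15N_Met"))
    expect_setequal(as.character(keep), attr(tab, "planted"))
  }
})

test_that("screen agrees with a hand-run ANOVA and handles replication gaps", {
  tab <- generate_tracer_table(study_config(seed = 3))
  keep <- fraction_discrimination_screen(tab, candidates = "d15N_Phe")
  ev <- attr(keep, "evidence")
  ref <- anova(aov(tab$d15N_Phe ~ factor(tab$fraction)))
  expect_equal(ev$F, ref[["F value"]][1])
  expect_equal(ev$p, ref[["Pr(>F)"]][1])
  # a variable observed in a single fraction cannot be screened
  tab$broken <- ifelse(tab$fraction == "small", 1:21, NA)
  expect_warning(
    keep2 <- fraction_discrimination_screen(tab, candidates = "broken"),
    "lacks replication")
  expect_length(keep2, 0)
})

test_that("PERMANOVA pseudo-F matches the direct within-group-distance oracle", {
  set.seed(101)
  for (rep_i in 1:5) {
    X <- matrix(rnorm(18 * 3), 18, 3)
    labels <- rep(c("a", "b", "c"), each = 6)
    D <- dist(X)
    res <- permanova_pseudo_F(D, labels, n_perm = 49)
    expect_equal(res$F, oracle_permanova_F(D, labels), tolerance = 1e-10)
    expect_equal(res$df, c(2, 15))
  }
})

test_that("PERMANOVA pseudo-F matches vegan::adonis2", {
  set.seed(55)
  X <- matrix(rnorm(15 * 4), 15, 4)
  labels <- rep(c("a", "b", "c"), each = 5)
  res <- permanova_pseudo_F(dist(X), labels, n_perm = 19)
  fit <- vegan::adonis2(dist(X) ~ g,
                        data = data.frame(g = factor(labels)),
                        permutations = 19)
  expect_equal(res$F, fit$F[1], tolerance = 1e-10)
})

test_that("exhaustive enumeration reproduces the combinatorial p exactly", {
  set.seed(9)
  X <- matrix(rnorm(7 * 2), 7, 2)
  labels <- c("a", "a", "a", "b", "b", "b", "b")
  D <- dist(X)
  res <- permanova_pseudo_F(D, labels, exhaustive = TRUE)
  expect_equal(res$n_perm, choose(7, 3))  # distinct label assignments
  expect_equal(res$p, oracle_permanova_exhaustive_p(D, labels),
               tolerance = 1e-12)
  expect_identical(res$method, "exhaustive")
})

test_that("Monte-Carlo p is seeded, add-one bounded, and input-checked", {
  set.seed(12)
  X <- matrix(rnorm(12 * 3), 12, 3)
  labels <- rep(c("a", "b"), each = 6)
  r1 <- permanova_pseudo_F(dist(X), labels, n_perm = 99, seed = 4)
  r2 <- permanova_pseudo_F(dist(X), labels, n_perm = 99, seed = 4)
  expect_identical(r1$p, r2$p)
  expect_gte(r1$p, 1 / 100)
  expect_lte(r1$p, 1)
  D <- as.matrix(dist(X))
  expect_error(permanova_pseudo_F(D[, -1], labels), "square")
  Dn <- D; Dn[1, 2] <- Dn[1, 2] + 1
  expect_error(permanova_pseudo_F(Dn, labels), "symmetric")
  Dd <- D; diag(Dd) <- 1
  expect_error(permanova_pseudo_F(Dd, labels), "zero diagonal")
  expect_error(permanova_pseudo_F(D, labels[-1]), "one label")
  expect_error(permanova_pseudo_F(D, rep("a", 12)), ">= 2 groups")
})

test_that("homogeneity report is clean on an exchangeable design and flags a planted effect", {
  tab <- generate_tracer_table(study_config(seed = 2))
  tracers <- attr(tab, "planted")
  rep_clean <- within_fraction_homogeneity(tab, tracers, n_perm = 199)
  expect_true(all(c("fraction", "factor", "p_adj", "skipped") %in%
                    names(rep_clean)))
  expect_true(all(rep_clean$p_adj[!rep_clean$skipped] > 0.05))
  # plant a site effect and see it flagged
  tab2 <- tab
  tab2$d15N_Phe <- tab2$d15N_Phe + ifelse(tab2$site == "PRZ", 25, 0)
  rep_hot <- within_fraction_homogeneity(tab2, tracers, factors = "site",
                                         n_perm = 199)
  expect_true(any(rep_hot$p_adj[!rep_hot$skipped] < 0.05))
  # a factor level with a single sample is skipped, not tested
  tab3 <- tab
  tab3$site[tab3$fraction == "small"] <- c("LONE", rep("CTA", 6))
  rep_skip <- within_fraction_homogeneity(tab3, tracers, factors = "site")
  expect_true(any(rep_skip$skipped[rep_skip$fraction == "small"]))
  expect_error(within_fraction_homogeneity(tab, "not_a_column"),
               "absent from table")
})

test_that("full tracer screen deterministically recovers the planted set", {
  for (seed in c(1, 2, 7, 11)) {
    tab <- generate_tracer_table(study_config(seed = seed))
    ts <- select_tracers(tab)
    expect_setequal(ts$selected, attr(tab, "planted"))
    expect_false("d15N_Met" %in% ts$selected)
    expect_s3_class(ts, "tracer_set")
    expect_true(all(c("missingness", "anova") %in% names(ts$evidence)))
  }
})

test_that("screen fails loudly when no candidate survives", {
  tab <- data.frame(fraction = rep(c("a", "b"), each = 5),
                    v1 = c(rep(NA, 5), 1:5))
  expect_error(select_tracers(tab, candidates = "v1", factors = NULL),
               "missingness filter")
  # survives missingness but does not discriminate
  set.seed(1)
  tab$v2 <- rnorm(10)
  tab$v2 <- tab$v2 - ave(tab$v2, tab$fraction)
  expect_error(select_tracers(tab, candidates = "v2", factors = NULL),
               "discriminates")
})
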