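test_that("sampler specification rejects inconsistent schedules", {
  expect_error(mixing_model_spec(n_iter = 1001, thin = 50), "multiple of thin")
  expect_error(mixing_model_spec(thin = 0), "multiple of thin")
  expect_error(mixing_model_spec(n_adapt = -1), ">= 0")
  expect_error(mixing_model_spec(measurement_sd = 0), "positive")
  expect_error(mixing_model_spec(dirichlet_alpha = -1), "positive")
  spec <- mixing_model_spec()
  expect_equal(spec$n_chains, 3L)
  expect_equal(spec$n_iter %/% spec$thin, 2000L)
})

test_that("source summaries reproduce sample moments with the SD floor", {
  tab <- data.frame(
    fraction = rep(c("a", "b"), each = 6),
    tracer = rep(rep(c("t1", "t2"), each = 3), 2),
    value_permil = c(1, 2, 3, 10, 10, 10, 4, 5, 6, 7, 8, 9))
  src <- summarize_sources(tab, sd_floor = 0.1)
  expect_equal(src$means["a", "t1"], 2)
  expect_equal(src$sds["a", "t1"], sd(c(1, 2, 3)))
  # constant samples are floored, not degenerate
  expect_equal(src$sds["a", "t2"], 0.1)
  expect_equal(unname(src$n), c(3, 3))
  expect_error(summarize_sources(tab[tab$fraction == "a" | tab$tracer == "t1", ][1:7, ]),
               "< 2 samples")
  # a tracer_set object is accepted as the tracer filter
  ts <- structure(list(selected = "t1"), class = "tracer_set")
  expect_equal(summarize_sources(tab, tracers = ts)$tracers, "t1")
})

test_that("log posterior matches a hand computation and its vectorized form", {
  src <- summarize_sources(generate_source_samples(study_config(seed = 1)))
  spec <- mixing_model_spec(measurement_sd = 0.5)
  p <- c(0.2, 0.3, 0.5)
  x <- c(d15N_Phe = 7.1, d15N_Lys = 10.4, d13C_Leu = -24.2)
  mu <- as.vector(p %*% src$means)
  v <- as.vector(p^2 %*% src$sds^2) + 0.5^2
  by_hand <- sum(dnorm(as.numeric(x), mu, sqrt(v), log = TRUE)) +
    lgamma(3)  # flat Dirichlet(1,1,1) log normalizing constant
  expect_equal(log_posterior(p, x, src, spec), by_hand, tolerance = 1e-12)
  # named vectors are reordered to the source tracer order
  expect_equal(log_posterior(p, x[c(3, 1, 2)], src, spec), by_hand)
  # the batch form is a kernel: add the Dirichlet normalizing constant
  expect_equal(unname(midmix:::log_posterior_batch(rbind(p), as.numeric(x),
                                                   src, spec)[1]) + lgamma(3),
               by_hand, tolerance = 1e-12)
  # non-flat prior: batch and scalar versions still agree
  spec2 <- mixing_model_spec(dirichlet_alpha = 2)
  expect_equal(unname(midmix:::log_posterior_batch(rbind(p), as.numeric(x),
                                                   src, spec2)[1]) +
                 lgamma(6) - 3 * lgamma(2),
               log_posterior(p, x, src, spec2), tolerance = 1e-10)
  expect_error(log_posterior(c(0.5, 0.5), x, src, spec), "one entry per")
})

test_that("MCMC reruns are byte-identical and draws live on the simplex", {
  cfg <- study_config(seed = 5)
  src <- summarize_sources(generate_source_samples(cfg))
  x <- generate_consumers(cfg)[5, ]
  fit1 <- run_mcmc(x, src, quick_spec(seed = 7))
  fit2 <- run_mcmc(x, src, quick_spec(seed = 7))
  expect_identical(fit1$draws, fit2$draws)
  fit3 <- run_mcmc(x, src, quick_spec(seed = 8))
  expect_false(identical(fit1$draws, fit3$draws))
  sums <- apply(fit1$draws, c(1, 3), sum)
  expect_lt(max(abs(sums - 1)), 1e-10)
  expect_true(all(fit1$draws >= 0))
  expect_equal(dim(fit1$draws), c(1000, 3, 3))
})

test_that("MCMC agrees with the quadrature oracle on a seeded instance", {
  cfg <- study_config(seed = 17)
  src <- summarize_sources(generate_source_samples(cfg))
  x <- generate_consumers(cfg)[6, ]
  fit <- run_mcmc(x, src, quick_spec(seed = 2))
  oracle <- brute_force_posterior(x, src, quick_spec(seed = 2),
                                  grid_step = 0.01)
  expect_lt(max(abs(fit$means - oracle$means)), 0.05)
  expect_lt(max(abs(fit$sds - oracle$sds)), 0.05)
  expect_true(fit$converged)
})

test_that("two balanced sources with a midpoint observation invert to one half", {
  src <- two_source_summary()
  spec <- quick_spec(seed = 3)
  oracle <- brute_force_posterior(c(t1 = 5), src, spec, grid_step = 0.002)
  expect_equal(unname(oracle$means[1]), 0.5, tolerance = 1e-6)
  fit <- run_mcmc(c(t1 = 5), src, spec)
  expect_equal(unname(fit$means[1]), 0.5, tolerance = 0.03)
})

test_that("an uninformative likelihood returns the Dirichlet prior mean", {
  cfg <- study_config(seed = 23)
  src <- summarize_sources(generate_source_samples(cfg))
  spec <- quick_spec(seed = 5, measurement_sd = 1e6)
  oracle <- brute_force_posterior(c(5, 5, -25), src, spec, grid_step = 0.01)
  expect_equal(unname(oracle$means), rep(1 / 3, 3), tolerance = 1e-3)
  fit <- run_mcmc(c(d15N_Phe = 5, d15N_Lys = 5, d13C_Leu = -25), src, spec)
  expect_equal(unname(fit$means), rep(1 / 3, 3), tolerance = 0.03)
})

test_that("quadrature oracle guards its applicability limits", {
  src <- two_source_summary()
  expect_error(brute_force_posterior(c(t1 = 5), src, grid_step = 0.5),
               "too coarse")
  tab <- data.frame(fraction = rep(letters[1:5], each = 2), tracer = "t1",
                    value_permil = rnorm(10))
  src5 <- summarize_sources(tab)
  expect_error(brute_force_posterior(c(t1 = 0), src5), "K <= 4")
  # the K = 2 grid enumerates N + 1 points
  expect_equal(brute_force_posterior(c(t1 = 5), src,
                                     grid_step = 0.01)$n_grid, 101)
})

test_that("diagnostics detect stationarity and its absence", {
  set.seed(44)
  n <- 500
  iid <- array(rnorm(n * 2 * 3), c(n, 2, 3))
  d <- diagnose(iid)
  expect_true(all(abs(d$rhat - 1) < 0.02))
  expect_true(all(d$ess > 0.5 * n * 3))
  # one displaced chain inflates R-hat
  bad <- iid
  bad[, 1, 3] <- bad[, 1, 3] + 10
  expect_gt(diagnose(bad)$rhat[1], 1.5)
  # a single chain: R-hat via its own split halves, trending means flagged
  drift <- array(seq(0, 10, length.out = n), c(n, 1, 1))
  expect_gt(diagnose(drift)$rhat[1], 1.5)
  expect_error(diagnose(matrix(0, 5, 2)), "draw x component x chain")
  expect_error(diagnose(array(0, c(1, 2, 3))), "at least 2")
})

test_that("pooling sums per draw and preserves the simplex", {
  cfg <- study_config(seed = 5)
  src <- summarize_sources(generate_source_samples(cfg))
  fit <- run_mcmc(generate_consumers(cfg)[7, ], src, quick_spec(seed = 1))
  pooled <- pool_fractions(fit)
  expect_equal(pooled$fractions, c("small", "large"))
  expect_equal(pooled$draws[, "large", ],
               fit$draws[, "medium", ] + fit$draws[, "large", ])
  expect_equal(pooled$means[["small"]] + pooled$means[["large"]], 1,
               tolerance = 1e-10)
  # pooled SD comes from pooled draws, not component summaries
  expect_equal(pooled$sds[["large"]],
               sd(as.vector(fit$draws[, "medium", ] + fit$draws[, "large", ])))
  expect_error(pool_fractions(fit, mapping = list(a = "small")),
               "partition")
  expect_error(pool_fractions(fit, mapping = list(a = c("small", "medium"),
                                                  b = c("medium", "large"))),
               "partition")
})

test_that("credible intervals are the empirical quantiles at the requested mass", {
  cfg <- study_config(seed = 5)
  src <- summarize_sources(generate_source_samples(cfg))
  fit <- run_mcmc(generate_consumers(cfg)[4, ], src, quick_spec(seed = 9))
  ci <- credible_interval(fit, level = 0.90)
  flat <- apply(fit$draws, 2, as.vector)
  expect_equal(unname(ci[1, ]),
               unname(quantile(flat[, 1], c(0.05, 0.95), names = FALSE)))
  expect_true(all(ci[, 1] <= fit$means & fit$means <= ci[, 2]))
  ci50 <- credible_interval(fit, level = 0.50)
  expect_true(all(ci50[, 2] - ci50[, 1] < ci[, 2] - ci[, 1]))
})

test_that("hierarchical source uncertainty widens the posterior", {
  cfg <- study_config(seed = 19)
  src <- summarize_sources(generate_source_samples(cfg))
  x <- generate_consumers(cfg)[5, ]
  fixed <- brute_force_posterior(x, src, quick_spec(), grid_step = 0.01)
  hier <- brute_force_posterior(
    x, src, quick_spec(source_uncertainty = "hierarchical"),
    grid_step = 0.01)
  expect_gte(mean(hier$sds), mean(fixed$sds))
})
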