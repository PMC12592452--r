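test_that("study generation is deterministic under a fixed seed", {
  a <- generate_study(study_config(seed = 42))
  b <- generate_study(study_config(seed = 42))
  expect_identical(a$source_table, b$source_table)
  expect_identical(a$consumer_table, b$consumer_table)
  expect_identical(a$aa_conc_table, b$aa_conc_table)
  expect_identical(a$trait_table, b$trait_table)
  expect_identical(a$lisst_casts[[1]]$volumes, b$lisst_casts[[1]]$volumes)
  c_ <- generate_study(study_config(seed = 43))
  expect_false(identical(a$source_table, c_$source_table))
})

test_that("source samples collapse to the configured means as noise vanishes", {
  cfg <- study_config(source_sds = matrix(1e-12, 3, 3), seed = 5)
  tab <- generate_source_samples(cfg)
  expected <- cfg$source_means[cbind(tab$fraction, tab$tracer)]
  expect_equal(tab$value_permil, unname(expected), tolerance = 1e-9)
})

test_that("per-fraction sample means respect the standard-error bound", {
  cfg <- study_config(seed = 11)
  tab <- generate_source_samples(cfg)
  for (fr in cfg$fractions) {
    for (tr in cfg$tracer_names) {
      v <- tab$value_permil[tab$fraction == fr & tab$tracer == tr]
      expect_length(v, cfg$n_source_samples)
      bound <- 3 * cfg$source_sds[fr, tr] / sqrt(cfg$n_source_samples)
      expect_lt(abs(mean(v) - cfg$source_means[fr, tr]), bound)
    }
  }
})

test_that("consumers at simplex vertices and centroid match source means", {
  cfg <- study_config(source_sds = matrix(1e-9, 3, 3),
                      measurement_sd = rep(1e-9, 3),
                      consumer_mixtures = list(c(1, 0, 0), rep(1 / 3, 3)),
                      seed = 2)
  tab <- generate_consumers(cfg)
  x1 <- unlist(tab[1, cfg$tracer_names])
  expect_equal(unname(x1), unname(cfg$source_means[1, ]), tolerance = 1e-6)
  x2 <- unlist(tab[2, cfg$tracer_names])
  expect_equal(unname(x2), unname(colMeans(cfg$source_means)),
               tolerance = 1e-6)
})

test_that("consumer sampling variance matches the propagated formula", {
  p <- c(0.2, 0.3, 0.5)
  cfg <- study_config(consumer_mixtures = rep(list(p), 1000), seed = 9)
  tab <- generate_consumers(cfg)
  expected_var <- as.vector(p^2 %*% cfg$source_sds^2) + cfg$measurement_sd^2
  for (j in seq_along(cfg$tracer_names)) {
    emp <- var(tab[[cfg$tracer_names[j]]])
    expect_lt(abs(emp - expected_var[j]) / expected_var[j], 0.10)
  }
  expect_equal(unname(as.matrix(
    tab[1, paste0("true_p_", cfg$fractions)])[1, ]), p)
})

test_that("off-simplex mixtures are rejected", {
  cfg <- study_config()
  expect_error(generate_consumers(cfg, mixtures = list(c(0.5, 0.5, 0.5))),
               "sum to 1")
  expect_error(generate_consumers(cfg, mixtures = list(c(1.2, -0.2, 0))),
               "non-negative")
})

test_that("amino-acid concentrations are moment-matched and seeded", {
  cfg <- study_config(seed = 3)
  cfg$aa_conc$n <- c(background = 400, plume = 400, discharge = 400)
  tab <- generate_aa_concentration_table(cfg)
  expect_true(all(tab$normalized_conc > 0))
  for (ty in rownames(cfg$aa_conc$means)) {
    for (fr in colnames(cfg$aa_conc$means)) {
      v <- tab$normalized_conc[tab$sample_type == ty &
                                 tab$size_fraction == fr]
      m <- cfg$aa_conc$means[ty, fr]
      se <- cfg$aa_conc$sds[ty, fr] / sqrt(length(v))
      expect_lt(abs(mean(v) - m), 3 * se + 0.02 * m)
    }
  }
  expect_identical(tab, generate_aa_concentration_table(cfg))
  # zero-variance configuration gives constant records
  cfg0 <- study_config(seed = 3)
  cfg0$aa_conc$sds[] <- 0
  t0 <- generate_aa_concentration_table(cfg0)
  expect_equal(t0$normalized_conc[t0$sample_type == "background" &
                                    t0$size_fraction == "medium"],
               rep(41.1, 7))
})

test_that("generated records satisfy the normalization identity", {
  tab <- generate_aa_concentration_table(study_config(seed = 8))
  reconstructed <- (tab$total_aa_N / tab$subsample_fraction_csia) /
    (tab$bulk_PN / tab$subsample_fraction_bulk)
  expect_equal(reconstructed, tab$normalized_conc, tolerance = 1e-9)
})

test_that("trait table hits configured guild counts by largest remainder", {
  tab <- generate_trait_table(study_config(seed = 1))
  micro <- tab[tab$group == "micronekton", ]
  expect_equal(nrow(micro), 80)
  counts <- table(micro$guild)
  expect_equal(unname(counts[["zooplanktivore"]]), 48)
  expect_equal(unname(counts[["pelagic_micronektonivore"]]), 30)
  expect_equal(unname(counts[["gelatinous_zooplanktivore"]]), 1)
  expect_equal(unname(counts[["pelagic_generalist"]]), 1)
  # proportions re-derived from the table equal configured values
  zoo <- tab[tab$group == "zooplankton", ]
  prop <- table(zoo$guild)["particle_feeder"] / nrow(zoo)
  expect_equal(unname(prop), 42 / 79)
})

test_that("single-guild and infeasible trait configurations behave", {
  cfg <- study_config()
  cfg$traits <- list(zooplankton = list(
    n_taxa = 10, guilds = c(particle_feeder = 1),
    density_share = c(particle_feeder = 1)))
  tab <- generate_trait_table(cfg)
  expect_equal(unique(tab$guild), "particle_feeder")
  cfg$traits$zooplankton$guilds <- c(a = 0.7, b = 0.6)
  expect_error(generate_trait_table(cfg), "sum to")
})

test_that("plume casts carry the configured anomaly and background casts do not", {
  cfg <- study_config(seed = 6)
  casts <- generate_lisst_casts(cfg)
  expect_length(casts, 8)
  plume <- casts[[which(vapply(casts, function(c) c$cast_type,
                               character(1)) == "plume")[1]]]
  bg <- casts[[1]]
  # fraction totals recovered by processing within 5%
  fr_p <- aggregate_fractions(baseline_calibrate(bin_to_depth(plume)))
  expect_lt(abs(max(fr_p$small_ul_l) - 9.80) / 9.80, 0.05)
  expect_lt(abs(max(fr_p$large_ul_l) - 2.18) / 2.18, 0.05)
  fr_b <- aggregate_fractions(baseline_calibrate(bin_to_depth(bg)))
  expect_lt(abs(max(fr_b$small_ul_l) - 0.08) / 0.08, 0.05)
  expect_lt(abs(max(fr_b$large_ul_l) - 0.23) / 0.23, 0.05)
  # PSD argmax of the plume falls in the configured modal bin
  grid <- lisst_size_grid()
  modal_bin <- which.min(abs(grid$center_um - cfg$lisst$modal_center_um))
  peak_depth <- fr_p$depth_db[which.max(fr_p$small_ul_l)]
  mode <- psd_maxima(baseline_calibrate(bin_to_depth(plume)),
                     peak_depth + c(-5, 5))
  expect_equal(mode, grid$center_um[modal_bin])
})

test_that("zero plume amplitude reduces plume casts to background structure", {
  cfg <- study_config(seed = 13)
  casts <- generate_lisst_casts(cfg, plume_amplitude = 0)
  plume <- casts[[8]]
  bg <- casts[[1]]
  fr_p <- aggregate_fractions(baseline_calibrate(bin_to_depth(plume)))
  fr_b <- aggregate_fractions(baseline_calibrate(bin_to_depth(bg)))
  expect_lt(abs(max(fr_p$small_ul_l) - max(fr_b$small_ul_l)) /
              max(fr_b$small_ul_l), 0.1)
  expect_lt(abs(max(fr_p$large_ul_l) - max(fr_b$large_ul_l)) /
              max(fr_b$large_ul_l), 0.1)
})

test_that("depth ranges too short for calibration are rejected", {
  cfg <- study_config()
  cfg$lisst$depth_max_db <- cfg$lisst$depth_min_db + 5
  expect_error(generate_lisst_casts(cfg), "at least 10 db")
})

test_that("candidate tracer table plants missingness where configured", {
  cfg <- study_config(seed = 4)
  tab <- generate_tracer_table(cfg)
  miss <- tapply(is.na(tab$d15N_Met), tab$fraction, sum)
  expect_equal(unname(miss[["small"]]), 4)
  expect_equal(sum(miss), 4)
  expect_setequal(attr(tab, "planted"), cfg$tracer_names)
})

test_that("census design plants the configured regime", {
  cfg <- study_config(seed = 21)
  des <- census_design(cfg)
  d <- des$design
  expect_equal(nrow(d), 46)
  expect_equal(sum(d$above_threshold), 30)
  expect_equal(length(unique(d$group)), 8)
  deep <- d$depth_m >= 1000 & d$depth_m < 1500
  expect_equal(sum(deep), 26)
  expect_equal(sum(deep & d$above_threshold), 16)
  # groups homogeneous: exactly 5 groups entirely above
  by_group <- tapply(d$above_threshold, d$group, mean)
  expect_equal(sum(by_group == 1), 5)
  expect_equal(sum(by_group == 0), 3)
  # mixtures on the simplex and consistent with the pooled truth
  for (i in seq_along(des$mixtures)) {
    p <- des$mixtures[[i]]
    expect_equal(sum(p), 1, tolerance = 1e-12)
    expect_equal(p[2] + p[3], d$true_p_large_pooled[i], tolerance = 1e-12)
  }
})
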