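#' Draw sample-level source tracer values for each particle size fraction
#'
#' Each size fraction contributes `n_source_samples` independent particle
#' samples per tracer, drawn Normal around the configured fraction means
#' with the configured between-sample SDs. These samples play the role of
#' the field-collected particle pool that is later summarized into the
#' mixing model's source distributions.
#'
#' @param config a [study_config()].
#' @return long data.frame: `sample_id`, `fraction`, `tracer`,
#'   `value_permil`, with the seed as attribute `seed`.
#' @export
generate_source_samples <- function(config) {
  stopifnot(inherits(config, "study_config"))
  if (any(config$source_sds <= 0)) stop("source_sds must be strictly positive")
  set.seed(derive_seed(config$seed, "sources"))
  K <- config$n_sources
  J <- length(config$tracer_names)
  n <- config$n_source_samples
  rows <- expand.grid(rep = seq_len(n), tracer = config$tracer_names,
                      fraction = config$fractions,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  m <- config$source_means[cbind(rows$fraction, rows$tracer)]
  s <- config$source_sds[cbind(rows$fraction, rows$tracer)]
  out <- data.frame(
    sample_id = sprintf("%s_%02d", rows$fraction, rows$rep),
    fraction = rows$fraction, tracer = rows$tracer,
    value_permil = stats::rnorm(nrow(rows), m, s),
    stringsAsFactors = FALSE
  )
  attr(out, "seed") <- config$seed
  out
}

#' Simulate consumer tracer profiles from true diet mixtures
#'
#' Each consumer's expected tracer value is the mixture of the source
#' fraction means, `mu_j = sum_k p_k m_kj`; the sampling SD combines
#' source variability propagated through the mixture with analytical
#' measurement error, `sigma_j^2 = sum_k p_k^2 s_kj^2 + tau_j^2` — the same
#' error structure the mixing model assumes, so parameter recovery tests
#' probe the sampler rather than model mis-specification. Set
#' `misspecify_sd_factor != 1` to inflate/deflate the generating noise for
#' robustness experiments.
#'
#' @param config a [study_config()].
#' @param mixtures optional list of simplex vectors overriding
#'   `config$consumer_mixtures`.
#' @param groups,depth_m optional per-consumer metadata (recycled if
#'   length 1).
#' @param misspecify_sd_factor multiplier on the generating SD (default 1 =
#'   matched to the model).
#' @return data.frame: `consumer_id`, `group`, `depth_m`, one column per
#'   tracer, and `true_p_<fraction>` columns; seed attached as attribute.
#' @export
generate_consumers <- function(config, mixtures = NULL, groups = NULL,
                               depth_m = NULL, misspecify_sd_factor = 1) {
  stopifnot(inherits(config, "study_config"))
  mixtures <- mixtures %||% config$consumer_mixtures
  for (p in mixtures) assert_simplex(p, "true mixture vector")
  set.seed(derive_seed(config$seed, "consumers"))
  n <- length(mixtures)
  groups <- rep(groups %||% "sim", length.out = n)
  depth_m <- rep(depth_m %||% NA_real_, length.out = n)
  P <- do.call(rbind, mixtures)
  mu <- P %*% config$source_means                          # n x J
  sd2 <- (P^2) %*% (config$source_sds^2)
  sd2 <- sweep(sd2, 2, config$measurement_sd^2, "+")
  sig <- sqrt(sd2) * misspecify_sd_factor
  x <- matrix(stats::rnorm(length(mu), mu, sig), nrow = n,
              dimnames = list(NULL, config$tracer_names))
  out <- data.frame(consumer_id = sprintf("consumer_%03d", seq_len(n)),
                    group = groups, depth_m = depth_m,
                    stringsAsFactors = FALSE)
  out <- cbind(out, as.data.frame(x))
  tp <- as.data.frame(P)
  names(tp) <- paste0("true_p_", config$fractions)
  out <- cbind(out, tp)
  attr(out, "seed") <- config$seed
  out
}

#' Planted consumer design mirroring the study's census regime
#'
#' Builds a 46-consumer design in 8 groups (four zooplankton size
#' fractions and four micronekton taxa) in which exactly `n_above`
#' consumers have a true pooled >6 µm (medium + large) diet contribution
#' above 0.5 and `n_below` fall below it. Groups are homogeneous
#' (entirely above or below), so 5 of the 8 group means exceed 0.5; the
#' 1000–1500 m stratum holds 26 consumers of which 16 are above — the
#' regime reported for the emulated community.
#'
#' @param config a [study_config()] (supplies fractions and seed).
#' @param n_above,n_below consumers above/below the pooled 0.5 threshold.
#' @param margin half-width kept clear of the 0.5 boundary; true pooled
#'   large contributions are drawn uniform in `[0.5 + margin, 0.90]`
#'   (above) and `[0.10, 0.5 - margin]` (below).
#' @return list with `mixtures`, `groups`, `depth_m`, and the design
#'   data.frame `design`.
#' @export
census_design <- function(config, n_above = 30, n_below = 16,
                          margin = 0.18) {
  stopifnot(inherits(config, "study_config"), config$n_sources == 3)
  set.seed(derive_seed(config$seed, "consumers") + 1L)
  groups_above <- c("zoop_0.2-0.5mm", "zoop_0.5-1.0mm", "zoop_1.0-2.0mm",
                    "zoop_2.0-5.0mm", "Cyclothone_spp")
  groups_below <- c("A_brevicarinata", "Japatella_spp", "Eucopia_spp")
  size_above <- rep(n_above %/% 5, 5)
  size_above[seq_len(n_above %% 5)] <- size_above[seq_len(n_above %% 5)] + 1
  size_below <- rep(n_below %/% 3, 3)
  size_below[seq_len(n_below %% 3)] <- size_below[seq_len(n_below %% 3)] + 1
  group <- c(rep(groups_above, size_above), rep(groups_below, size_below))
  above <- c(rep(TRUE, n_above), rep(FALSE, n_below))
  n <- n_above + n_below

  p_large_pool <- ifelse(above,
                         stats::runif(n, 0.5 + margin, 0.90),
                         stats::runif(n, 0.10, 0.5 - margin))
  split_med <- stats::runif(n, 0.3, 0.7) # medium share of the pooled part
  mixtures <- lapply(seq_len(n), function(i) {
    c(1 - p_large_pool[i],
      p_large_pool[i] * split_med[i],
      p_large_pool[i] * (1 - split_med[i]))
  })

  # 26 consumers in the 1000-1500 m discharge stratum, 16 of them above.
  deep <- logical(n)
  deep[sample(which(above), 16)] <- TRUE
  deep[sample(which(!above), 10)] <- TRUE
  depth_m <- ifelse(deep, stats::runif(n, 1000, 1499),
                    stats::runif(n, 700, 999))
  design <- data.frame(consumer_id = sprintf("consumer_%03d", seq_len(n)),
                       group = group, depth_m = depth_m,
                       true_p_large_pooled = p_large_pool,
                       above_threshold = above,
                       stringsAsFactors = FALSE)
  list(mixtures = mixtures, groups = group, depth_m = depth_m,
       design = design)
}

#' Moment-matched lognormal (or truncated-normal) amino-acid concentrations
#'
#' Draws per-sample total amino-acid nitrogen normalized to particulate
#' nitrogen (ngN/µgPN) for each sample type (background / plume /
#' discharge) and size fraction, matching the configured group mean and SD.
#' The default family is lognormal with moment-matched `meanlog`/`sdlog`
#' because the emulated concentration contrasts have SD of the same order
#' as the mean and concentrations are non-negative; a zero-truncated
#' normal is available (its realized moments are slightly shifted when the
#' mean/SD ratio is small). Instrument-level columns (`total_aa_N`,
#' `bulk_PN`, subsample fractions) are emitted consistently with the
#' normalization identity so the preparation stage can round-trip them.
#'
#' @param config a [study_config()].
#' @param family `"lognormal"` or `"truncnorm"`.
#' @return data.frame of amino-acid concentration records.
#' @export
generate_aa_concentration_table <- function(config,
                                            family = config$aa_conc$family) {
  stopifnot(inherits(config, "study_config"))
  family <- match.arg(family, c("lognormal", "truncnorm"))
  ac <- config$aa_conc
  if (any(ac$means <= 0)) stop("aa concentration means must be positive")
  set.seed(derive_seed(config$seed, "aa_conc"))
  types <- rownames(ac$means)
  fracs <- colnames(ac$means)
  rows <- list()
  for (ty in types) {
    for (fr in fracs) {
      m <- ac$means[ty, fr]; s <- ac$sds[ty, fr]; n <- ac$n[[ty]]
      conc <- if (s == 0) {
        rep(m, n)
      } else if (family == "lognormal") {
        sdlog <- sqrt(log1p((s / m)^2))
        stats::rlnorm(n, log(m) - sdlog^2 / 2, sdlog)
      } else {
        draw <- stats::rnorm(n * 20, m, s)
        draw <- draw[draw > 0]
        while (length(draw) < n) draw <- c(draw, abs(stats::rnorm(n, m, s)))
        draw[seq_len(n)]
      }
      bulk_pn_whole <- stats::rlnorm(n, log(10), 0.3)   # whole-filter µg N
      f_bulk <- 0.5; f_csia <- 0.5
      rows[[paste(ty, fr)]] <- data.frame(
        sample_id = sprintf("%s_%s_%02d", ty, fr, seq_len(n)),
        sample_type = ty, size_fraction = fr,
        total_aa_N = conc * bulk_pn_whole * f_csia,
        bulk_PN = bulk_pn_whole * f_bulk,
        subsample_fraction_bulk = f_bulk,
        subsample_fraction_csia = f_csia,
        normalized_conc = conc,
        stringsAsFactors = FALSE
      )
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "seed") <- config$seed
  out
}

#' Simulate LISST casts with background and mining-plume structure
#'
#' Each cast is a raw (0.5-db) depth series of 32-class volume
#' concentrations built from: a constant per-class instrument floor, a
#' broad background particle layer whose 1.25–6 µm and 6–250 µm fraction
#' totals hit the configured background targets at the layer maximum, and
#' (for plume casts) a narrow discharge layer centred near 1250 db whose
#' size spectrum is a lognormal mode in the small classes (configured
#' modal center ~3.1 µm, within the 2.6–4.3 µm classes) plus a secondary
#' coarse component, scaled so the plume fraction totals hit their
#' configured targets at the layer peak before noise. All layers taper to
#' the floor over the deepest 10 db so baseline calibration has a
#' quiescent segment. Multiplicative-scale Gaussian noise is added per
#' class and sample.
#'
#' @param config a [study_config()].
#' @param plume_amplitude scale on the plume layer (0 makes plume casts
#'   statistically identical to background casts).
#' @return list of `lisst_cast` objects (background casts first).
#' @export
generate_lisst_casts <- function(config, plume_amplitude = 1) {
  stopifnot(inherits(config, "study_config"))
  L <- config$lisst
  if (L$depth_max_db - L$depth_min_db < 10) {
    stop("depth range must span at least 10 db for baseline calibration")
  }
  set.seed(derive_seed(config$seed, "lisst"))
  grid <- lisst_size_grid()
  depth <- seq(L$depth_min_db, L$depth_max_db, by = L$raw_step_db)

  small_sel <- grid$center_um >= 1.25 & grid$center_um < 6
  large_sel <- grid$center_um >= 6 & grid$center_um < 250
  # meanlog offset by sdlog^2 places the lognormal MODE at the configured
  # modal diameter, so the generated PSD argmax lands in that bin
  sdlog_small <- 0.35
  shape_small <- stats::dlnorm(grid$center_um,
                               log(L$modal_center_um) + sdlog_small^2,
                               sdlog_small)
  shape_small[!small_sel] <- 0
  shape_small <- shape_small / sum(shape_small)
  shape_large <- stats::dlnorm(grid$center_um, log(15), 0.8)
  shape_large[!large_sel] <- 0
  shape_large <- shape_large / sum(shape_large)

  # depth envelopes, each forced to zero over the deepest 10 db
  taper <- pmin(1, pmax(0, (L$depth_max_db - 10 - depth) / 20))
  env_bg <- exp(-0.5 * ((depth - L$background_center_db) /
                          L$background_width_db)^2) * taper
  env_bg <- env_bg / max(env_bg)
  env_pl <- exp(-0.5 * ((depth - L$plume_center_db) / L$plume_width_db)^2) *
    taper
  env_pl <- env_pl / max(env_pl)

  base_bg <- outer(env_bg, L$background_small_ul_l * shape_small +
                     L$background_large_ul_l * shape_large)
  # plume targets are the observed totals at the plume peak, so the
  # discharge layer amplitude is net of the background layer there
  bg_at_plume <- env_bg[which.max(env_pl)]
  pl_small <- max(L$plume_small_ul_l - bg_at_plume * L$background_small_ul_l, 0)
  pl_large <- max(L$plume_large_ul_l - bg_at_plume * L$background_large_ul_l, 0)
  base_pl <- outer(env_pl, pl_small * shape_small + pl_large * shape_large)

  make_cast <- function(id, type, with_plume) {
    signal <- base_bg + if (with_plume) plume_amplitude * base_pl else 0
    signal <- sweep(signal, 2, L$floor_ul_l, "+")
    noise <- matrix(stats::rnorm(length(signal), 0, 1),
                    nrow = nrow(signal)) * L$noise_sd_rel * signal
    lisst_cast(depth, pmax(signal + noise, 0), cast_id = id,
               cast_type = type, grid = grid)
  }
  casts <- c(
    lapply(seq_len(L$n_background_casts), function(i)
      make_cast(sprintf("bg_%02d", i), "background", FALSE)),
    lapply(seq_len(L$n_plume_casts), function(i)
      make_cast(sprintf("plume_%02d", i), "plume", TRUE))
  )
  attr(casts, "seed") <- config$seed
  casts
}

#' Build a taxon-to-feeding-guild trait table with exact guild proportions
#'
#' Taxon counts per guild are obtained from the configured proportions by
#' largest-remainder rounding, so re-deriving proportions from the table
#' recovers the configuration exactly (e.g. 80 micronekton taxa at
#' 60/37.5/1.25/1.25% give counts 48/30/1/1). Any unallocated share
#' becomes guild `"unclassified"`. Each taxon carries a density weight,
#' `density_share[guild] / n_taxa[guild]`, so density-weighted guild
#' shares equal the configured density shares.
#'
#' @param config a [study_config()].
#' @return data.frame: `taxon`, `group` (zooplankton/micronekton),
#'   `guild`, `density_weight`.
#' @export
generate_trait_table <- function(config) {
  stopifnot(inherits(config, "study_config"))
  set.seed(derive_seed(config$seed, "traits"))
  out <- list()
  for (grp in names(config$traits)) {
    tr <- config$traits[[grp]]
    if (sum(tr$guilds) > 1 + 1e-9) {
      stop("guild proportions for ", grp, " sum to more than 1")
    }
    n <- tr$n_taxa
    target <- tr$guilds * n
    counts <- floor(target)
    leftover <- round(n * min(sum(tr$guilds), 1)) - sum(counts)
    if (leftover > 0) {
      ord <- order(target - counts, decreasing = TRUE)
      counts[ord[seq_len(leftover)]] <- counts[ord[seq_len(leftover)]] + 1
    }
    guild <- rep(names(counts), counts)
    if (length(guild) < n) {
      guild <- c(guild, rep("unclassified", n - length(guild)))
    }
    share <- tr$density_share
    if (any(!guild %in% names(share))) {
      share <- c(share, stats::setNames(
        max(0, 1 - sum(share)), "unclassified"))
    }
    w <- as.numeric(share[guild]) / as.numeric(table(guild)[guild])
    out[[grp]] <- data.frame(
      taxon = sprintf("%s_taxon_%03d", grp, seq_len(n)),
      group = grp, guild = guild, density_weight = w,
      stringsAsFactors = FALSE
    )
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  attr(res, "seed") <- config$seed
  res
}

#' Candidate amino-acid tracer table with planted structure
#'
#' Emulates the per-sample table of candidate AA isotope variables the
#' tracer screen operates on. The three configured tracers discriminate
#' between size fractions (between-fraction means from
#' `config$source_means`, rescaled to `separation_sd` within-fraction SDs
#' between adjacent fractions); the remaining candidates share one mean
#' across fractions. One candidate is planted with missing values in
#' `n_missing_planted` samples of the first size fraction so the
#' missingness filter has a known casualty. Site/cruise/depth metadata are
#' assigned from an exchangeable design (no planted factor effects).
#'
#' @param config a [study_config()].
#' @param n_noise number of non-discriminating candidate variables.
#' @param separation_sd between-adjacent-fraction separation of the
#'   discriminating variables, in within-fraction SD units.
#' @param n_missing_planted missing count planted in one fraction for the
#'   variable `missing_var`.
#' @param missing_var name of the missingness-planted candidate.
#' @param center_noise if TRUE (default), noise candidates are centered
#'   within fraction so their lack of discrimination is exact in the
#'   sample (deterministic planted truth); set FALSE for i.i.d. nulls.
#' @return data.frame: sample metadata columns (`sample_id`, `fraction`,
#'   `site`, `cruise`, `depth_stratum`) plus one numeric column per
#'   candidate variable; candidate names in attribute `candidates`,
#'   planted tracers in attribute `planted`.
#' @export
generate_tracer_table <- function(config, n_noise = 4, separation_sd = 5,
                                  n_missing_planted = 4,
                                  missing_var = "d15N_Met",
                                  center_noise = TRUE) {
  stopifnot(inherits(config, "study_config"))
  set.seed(derive_seed(config$seed, "tracer_table"))
  n <- config$n_source_samples
  K <- config$n_sources
  frac <- rep(config$fractions, each = n)
  meta <- data.frame(
    sample_id = sprintf("%s_%02d", frac, rep(seq_len(n), K)),
    fraction = frac,
    site = rep_len(c("PRZ", "CTA"), n * K),
    cruise = rep_len(c("spring21", "fall21", "fall22"), n * K),
    depth_stratum = rep_len(c("800-1000m", "1000-1500m"), n * K),
    stringsAsFactors = FALSE
  )
  vals <- list()
  for (j in seq_along(config$tracer_names)) {
    tr <- config$tracer_names[j]
    m <- config$source_means[, j]
    m <- (m - mean(m)) / mean(diff(sort(m))) * separation_sd + mean(m)
    vals[[tr]] <- stats::rnorm(n * K, m[match(frac, config$fractions)], 1)
  }
  noise_names <- setdiff(
    c(paste0("d15N_", c("Ala", "Glu", "Gly", "Ser", "Thr", "Val", "Pro",
                        "Asp", "Ile", "Tyr")),
      paste0("d13C_", c("Ile", "Val", "Thr"))),
    config$tracer_names
  )[seq_len(n_noise)]
  for (nm in noise_names) {
    v <- stats::rnorm(n * K, 8, 1)
    if (center_noise) {
      # remove the sample between-fraction signal so "does not
      # discriminate" holds exactly in the planted table, not just in
      # expectation (the screen's false-positive channel is studied
      # separately under permuted labels)
      v <- v - stats::ave(v, frac) + mean(v)
    }
    vals[[nm]] <- v
  }
  if (!is.null(missing_var) && n_missing_planted > 0) {
    v <- stats::rnorm(n * K, 8, 1)
    v[which(frac == config$fractions[1])[seq_len(n_missing_planted)]] <- NA
    vals[[missing_var]] <- v
  }
  out <- cbind(meta, as.data.frame(vals))
  attr(out, "candidates") <- names(vals)
  attr(out, "planted") <- config$tracer_names
  attr(out, "seed") <- config$seed
  out
}

#' Generate a complete synthetic study
#'
#' Bundles every generator: source samples, consumers (either the
#' configured mixtures or the planted census regime), amino-acid
#' concentration records, LISST casts, the trait table and the candidate
#' tracer table.
#'
#' @param config a [study_config()].
#' @param census_regime if TRUE, consumers follow [census_design()]
#'   (46 consumers, 30 above the pooled-large 0.5 threshold) instead of
#'   `config$consumer_mixtures`.
#' @return list of class `synthetic_study`.
#' @export
generate_study <- function(config, census_regime = FALSE) {
  stopifnot(inherits(config, "study_config"))
  if (census_regime) {
    des <- census_design(config)
    consumers <- generate_consumers(config, mixtures = des$mixtures,
                                    groups = des$groups,
                                    depth_m = des$depth_m)
    design <- des$design
  } else {
    consumers <- generate_consumers(config)
    design <- NULL
  }
  structure(list(
    config = config,
    source_table = generate_source_samples(config),
    consumer_table = consumers,
    consumer_design = design,
    aa_conc_table = generate_aa_concentration_table(config),
    lisst_casts = generate_lisst_casts(config),
    trait_table = generate_trait_table(config),
    tracer_table = generate_tracer_table(config),
    seed = config$seed
  ), class = "synthetic_study")
}
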