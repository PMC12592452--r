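#' Configuration of a synthetic midwater particle/consumer study
#'
#' Bundles every parameter the synthetic-data generators need: the isotopic
#' signatures of the three particle size fractions used as mixing-model
#' sources, the true diet mixtures of the simulated consumers, the
#' amino-acid concentration contrasts between background and
#' mining-plume/discharge particles, the LISST cast geometry, and the
#' feeding-guild composition of the zooplankton and micronekton communities.
#'
#' Defaults emulate the study conditions of a lower-mesopelagic /
#' upper-bathypelagic community sampled below an oxygen minimum zone:
#' three particle size fractions (0.7–6, 6–53, >53 µm) with 7 source
#' samples each; background amino-acid concentrations of 4.7 ± 2.7,
#' 41.1 ± 25.3 and 46.3 ± 34.7 ngN/µgPN for small/medium/large particles
#' against 3.8 ± 4.4, 1.7 ± 1.5 and 4.2 ± 4.7 for plume/discharge material;
#' LISST plume fraction totals of 9.80 (1.25–6 µm) and 2.18 µL/L (6–250 µm)
#' over background totals of 0.08 and 0.23 µL/L, with the plume volume mode
#' in the 2.6–4.3 µm classes and the discharge layer centred at ~1250 db;
#' and guild tables of 79 zooplankton taxa (53% particle feeders) and 80
#' micronekton taxa (60% zooplanktivores, 37.5% pelagic micronektonivores,
#' 1.25% gelatinous zooplanktivores, 1.25% pelagic generalists) with the
#' zooplanktivores holding 85% of micronekton density at discharge depth.
#'
#' @param n_sources number of particle size-fraction sources (default 3).
#' @param fractions labels of the size fractions, smallest first.
#' @param tracer_names labels of the isotope tracers (per mil).
#' @param source_means K x J matrix of per-fraction tracer means (permil);
#'   rows follow `fractions`, columns `tracer_names`.
#' @param source_sds K x J matrix of per-fraction tracer SDs (permil), all > 0.
#' @param n_source_samples particle samples drawn per fraction (default 7,
#'   the per-fraction count of usable source samples in the emulated study).
#' @param consumer_mixtures list of true diet proportion vectors on the
#'   K-simplex, one per simulated consumer. Defaults to the three vertices,
#'   the centroid, and three mixed diets including a large-particle-dominant
#'   regime.
#' @param measurement_sd length-J vector of analytical measurement SDs
#'   (permil) added to every consumer tracer value (default 0.5 permil, a
#'   typical compound-specific isotope analytical precision).
#' @param aa_conc list with elements `means` and `sds` (3 x 3 matrices,
#'   rows = sample types background/plume/discharge, cols = size fractions,
#'   ngN/µgPN) and `n` (samples per sample type).
#' @param lisst list of LISST-generator parameters: depth range and raw
#'   sampling step (db), background and plume fraction volume targets
#'   (µL/L), plume layer centre/width, modal bin centre (µm), per-class
#'   noise SD and instrument floor offset.
#' @param traits list with per-group taxon counts, guild proportions and
#'   guild density shares.
#' @param seed integer seed carried by every generated table.
#' @return an object of class `study_config`.
#' @export
study_config <- function(n_sources = 3,
                         fractions = c("small", "medium", "large"),
                         tracer_names = c("d15N_Phe", "d15N_Lys", "d13C_Leu"),
                         source_means = NULL,
                         source_sds = NULL,
                         n_source_samples = 7,
                         consumer_mixtures = NULL,
                         measurement_sd = NULL,
                         aa_conc = NULL,
                         lisst = NULL,
                         traits = NULL,
                         seed = 1L) {
  K <- as.integer(n_sources)
  J <- length(tracer_names)
  if (K < 2) stop("need at least 2 sources")
  if (length(fractions) != K) stop("fractions must have length n_sources")

  if (is.null(source_means)) {
    if (K != 3 || J != 3) stop("default source_means only defined for 3x3")
    # Fraction signatures must span a non-degenerate triangle in tracer
    # space or mixtures are unidentifiable; ~5 permil spacing against
    # 1 permil SDs, with the Lys axis breaking collinearity (baseline
    # d15N offsets differ by amino acid across particle classes while
    # d13C of the essential AA grows heavier in larger aggregates).
    source_means <- matrix(c(2.0, 6.0, -28.0,
                             7.0, 14.0, -24.0,
                             12.0, 8.0, -19.0),
                           nrow = 3, byrow = TRUE,
                           dimnames = list(fractions, tracer_names))
  }
  source_means <- as.matrix(source_means)
  if (!all(dim(source_means) == c(K, J))) stop("source_means must be K x J")
  dimnames(source_means) <- list(fractions, tracer_names)

  if (is.null(source_sds)) {
    source_sds <- matrix(1.0, K, J, dimnames = dimnames(source_means))
  }
  source_sds <- as.matrix(source_sds)
  if (!all(dim(source_sds) == c(K, J))) stop("source_sds must be K x J")
  if (any(source_sds <= 0)) stop("source_sds must be strictly positive")
  dimnames(source_sds) <- dimnames(source_means)

  if (is.null(measurement_sd)) measurement_sd <- rep(0.5, J)
  if (length(measurement_sd) == 1) measurement_sd <- rep(measurement_sd, J)
  if (any(measurement_sd <= 0)) stop("measurement_sd must be strictly positive")
  names(measurement_sd) <- tracer_names

  if (is.null(consumer_mixtures)) {
    consumer_mixtures <- c(
      lapply(seq_len(K), function(k) { p <- numeric(K); p[k] <- 1; p }),
      list(rep(1 / K, K)),
      if (K == 3) list(c(0.20, 0.30, 0.50),
                       c(0.10, 0.35, 0.55),
                       c(0.45, 0.30, 0.25))
    )
  }
  for (p in consumer_mixtures) {
    if (length(p) != K) stop("each mixture must have length n_sources")
    assert_simplex(p, "true mixture vector")
  }

  if (is.null(aa_conc)) {
    aa_conc <- list(
      means = matrix(c(4.7, 41.1, 46.3,
                       3.8, 1.7, 4.2,
                       3.8, 1.7, 4.2),
                     nrow = 3, byrow = TRUE,
                     dimnames = list(c("background", "plume", "discharge"),
                                     fractions[seq_len(min(3, K))])),
      sds = matrix(c(2.7, 25.3, 34.7,
                     4.4, 1.5, 4.7,
                     4.4, 1.5, 4.7),
                   nrow = 3, byrow = TRUE,
                   dimnames = list(c("background", "plume", "discharge"),
                                   fractions[seq_len(min(3, K))])),
      n = c(background = 7, plume = 3, discharge = 3),
      family = "lognormal"
    )
  }
  if (any(aa_conc$means <= 0)) stop("aa_conc means must be positive")
  if (any(aa_conc$sds < 0)) stop("aa_conc sds must be non-negative")

  if (is.null(lisst)) {
    lisst <- list(
      depth_min_db = 700, depth_max_db = 1500, raw_step_db = 0.5,
      background_small_ul_l = 0.08, background_large_ul_l = 0.23,
      plume_small_ul_l = 9.80, plume_large_ul_l = 2.18,
      plume_center_db = 1250, plume_width_db = 40,
      background_center_db = 1000, background_width_db = 250,
      modal_center_um = 3.1,
      noise_sd_rel = 0.01, floor_ul_l = 0.002,
      n_background_casts = 3, n_plume_casts = 5
    )
  }

  if (is.null(traits)) {
    traits <- list(
      zooplankton = list(
        n_taxa = 79,
        guilds = c(particle_feeder = 0.53, gelatinous = 0.20,
                   carnivore = 0.27),
        density_share = c(particle_feeder = 0.50, gelatinous = 0.20,
                          carnivore = 0.30)
      ),
      micronekton = list(
        n_taxa = 80,
        guilds = c(zooplanktivore = 0.60, pelagic_micronektonivore = 0.375,
                   gelatinous_zooplanktivore = 0.0125,
                   pelagic_generalist = 0.0125),
        density_share = c(zooplanktivore = 0.85,
                          pelagic_micronektonivore = 0.13,
                          gelatinous_zooplanktivore = 0.01,
                          pelagic_generalist = 0.01)
      )
    )
  }
  for (g in traits) {
    if (sum(g$guilds) > 1 + 1e-9) stop("guild proportions must sum to <= 1")
  }

  structure(list(
    n_sources = K, fractions = fractions, tracer_names = tracer_names,
    source_means = source_means, source_sds = source_sds,
    n_source_samples = as.integer(n_source_samples),
    consumer_mixtures = consumer_mixtures,
    measurement_sd = measurement_sd,
    aa_conc = aa_conc, lisst = lisst, traits = traits,
    seed = as.integer(seed)
  ), class = "study_config")
}

#' @export
print.study_config <- function(x, ...) {
  cat("Synthetic study configuration\n")
  cat("  sources:", paste(x$fractions, collapse = ", "),
      sprintf("(%d samples each)\n", x$n_source_samples))
  cat("  tracers:", paste(x$tracer_names, collapse = ", "), "\n")
  cat("  consumers:", length(x$consumer_mixtures), "true mixtures\n")
  cat("  seed:", x$seed, "\n")
  invisible(x)
}
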