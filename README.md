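# midmix

Bayesian particle-source mixing models for midwater food webs.

Deep-sea mining would discharge a particle-rich waste plume into the ocean's
midwater. How much that threatens the resident food web depends on how
strongly midwater animals rely on the particle size classes the plume
perturbs. `midmix` quantifies that reliance from compound-specific isotope
analysis of amino acids (CSIA-AA): the δ¹⁵N of source amino acids
(phenylalanine, lysine) and the δ¹³C of essential amino acids (leucine)
pass from diet to consumer essentially unfractionated, so a consumer's
tracer values are a mixture of the signatures of the particle size
fractions at the base of its food chain — and diet attribution becomes a
Bayesian source-mixing inversion.

The package implements the full chain:

- **Synthetic study generation** (`study_config()`, `generate_study()`):
  seeded generators with planted truths for particle-source isotope
  samples, consumers, amino-acid concentration records, LISST casts,
  feeding-guild trait tables, and candidate tracer tables.
- **Concentration contrasts** (`flag_outliers()`,
  `compare_groups_anova()`): amino-acid nitrogen per particulate nitrogen,
  background vs mining plume/discharge particles.
- **Tracer selection** (`select_tracers()`): missingness filter, ANOVA
  discrimination screen, and pairwise-PERMANOVA within-fraction
  homogeneity report (`permanova_pseudo_F()` with Monte-Carlo or exhaustive
  permutation p-values).
- **Mixing model** (`run_mcmc()`): per-consumer fit on the diet simplex.
  For tracer *j*, `x_j ~ N(Σ_k p_k m_kj, Σ_k p_k² s_kj² + τ_j²)` with a
  Dirichlet(1) "generalist" prior and zero trophic discrimination;
  additive-log-ratio random-walk Metropolis in compiled code, 3 chains ×
  100,000 steps after 50,000 adaptation + 40,000 burn-in, thinned by 50
  (6,000 retained draws). A deterministic simplex-quadrature oracle
  (`brute_force_posterior()`) and split-chain R-hat / ESS diagnostics
  (`diagnose()`) check every fit.
- **Particle field** (`bin_to_depth()`, `baseline_calibrate()`,
  `aggregate_fractions()`, `volume_to_counts()`, `psd_maxima()`): LISST
  cast processing from raw 32-class volume spectra to fraction
  concentration profiles and modal diameters.
- **Food-web census** (`pool_fractions()`, `threshold_census()`,
  `group_contributions()`, `guild_proportions()`, `build_report()`):
  per-draw pooling of the >6 µm classes and the conclusion-level census of
  consumers relying on large particles for at least half their trophic
  base.

## Worked example

Fit the planted 46-consumer community and run the census (full sampling
schedule; ~20 s):

```r
library(midmix)

cfg   <- study_config(seed = 1)
study <- generate_study(cfg, census_regime = TRUE)

ts  <- select_tracers(study$tracer_table)
ts
#> Selected tracers: d15N_Phe, d15N_Lys, d13C_Leu
#>   (missingness threshold 4, ANOVA screen alpha 0.05)

src  <- summarize_sources(study$source_table, tracers = ts)
spec <- mixing_model_spec(seed = 1)
pooled <- lapply(seq_len(nrow(study$consumer_table)), function(i)
  pool_fractions(run_mcmc(study$consumer_table[i, ], src, spec)))
summaries <- consumer_summaries(pooled, study$consumer_table)

threshold_census(summaries)
#>      stratum  n count  percent count_prob_criterion
#> 1  700-1500m 46    30 65.21739                   30
#> 2 1000-1500m 26    16 61.53846                   16

group_contributions(summaries)$n_groups_large_over_half
#> [1] 5
```

All 46 fits converge (split-chain R-hat ≤ 1.05) and the posterior means
recover the planted pooled >6 µm contributions with mean absolute error
0.067. The concentration contrast on the same seed gives, for the medium
(6–53 µm) fraction, background 26.9 vs pooled plume/discharge
2.6 ngN/µgPN, F(1,10) = 19.87, p = 0.0012; LISST processing recovers the
planted plume anomaly (small-fraction peak 9.84 µL/L vs 0.081 background,
modal diameter 3.1 µm).

## Analysis workflow

`analysis/` holds numbered drivers that run the study end to end and write
their tables under `results/` (generated, not committed):

```sh
Rscript analysis/01_simulate.R        # synthetic study tables + LISST casts
Rscript analysis/02_prep_contrasts.R  # outlier flags + concentration ANOVA
Rscript analysis/03_select_tracers.R  # tracer screen + homogeneity report
Rscript analysis/04_mixing_model.R    # per-consumer fits, pooled summaries
Rscript analysis/05_particle_field.R  # LISST fraction profiles + modes
Rscript analysis/06_foodweb_report.R  # census, groups, guilds -> report.json/.md
```

`run_pipeline()` runs the same stages programmatically from a validated
config (`validate_config()`, plain list or YAML).

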