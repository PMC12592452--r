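#' Validate a raw pipeline configuration
#'
#' Accepts a list (or a YAML file path), fills defaults, type-checks every
#' stage's parameters and rejects unknown keys. All problems are reported
#' at once in the error message rather than one at a time.
#'
#' @param raw named list of settings, or path to a YAML file.
#' @return a validated `pipeline_config` list.
#' @export
validate_config <- function(raw = list()) {
  if (is.character(raw) && length(raw) == 1) raw <- yaml::read_yaml(raw)
  if (!is.list(raw)) stop("config must be a list or a YAML file path")
  known <- c("seed", "outdir", "census_threshold", "tracer_alpha",
             "max_missing", "n_perm", "mixing", "census_regime",
             "outlier_rule", "stages")
  errors <- character(0)
  unknown <- setdiff(names(raw), known)
  if (length(unknown)) {
    errors <- c(errors, paste("unknown keys:", paste(unknown, collapse = ", ")))
  }
  cfg <- list(
    seed = raw$seed %||% NA_integer_,
    outdir = raw$outdir %||% tempfile("midmix_run_"),
    census_threshold = raw$census_threshold %||% 0.5,
    tracer_alpha = raw$tracer_alpha %||% 0.05,
    max_missing = raw$max_missing %||% 4,
    n_perm = raw$n_perm %||% 199,
    census_regime = isTRUE(raw$census_regime %||% TRUE),
    outlier_rule = raw$outlier_rule %||% "tukey",
    stages = raw$stages %||% c("simulate", "prep", "select", "mix",
                               "lisst", "report")
  )
  if (is.na(cfg$seed)) {
    warning("no seed supplied; defaulting to 1")
    cfg$seed <- 1L
  }
  mix_defaults <- formals(mixing_model_spec)
  mix <- raw$mixing %||% list()
  unknown_mix <- setdiff(names(mix), names(mix_defaults))
  if (length(unknown_mix)) {
    errors <- c(errors, paste("unknown mixing keys:",
                              paste(unknown_mix, collapse = ", ")))
  }
  for (f in c("n_chains", "n_adapt", "n_burnin", "n_iter", "thin")) {
    if (!is.null(mix[[f]]) && (!is.numeric(mix[[f]]) || mix[[f]] < 0)) {
      errors <- c(errors, paste0("mixing$", f, " must be a non-negative number"))
    }
  }
  if (!is.null(mix$thin) && mix$thin <= 0) {
    errors <- c(errors, "mixing$thin must be positive")
  }
  if (cfg$tracer_alpha <= 0 || cfg$tracer_alpha > 1) {
    errors <- c(errors, "tracer_alpha must lie in (0, 1]")
  }
  if (cfg$census_threshold < 0 || cfg$census_threshold > 1) {
    errors <- c(errors, "census_threshold must lie in [0, 1]")
  }
  if (!cfg$outlier_rule %in% c("tukey", "none")) {
    errors <- c(errors, "outlier_rule must be 'tukey' or 'none'")
  }
  bad_stage <- setdiff(cfg$stages, c("simulate", "prep", "select", "mix",
                                     "lisst", "report"))
  if (length(bad_stage)) {
    errors <- c(errors, paste("unknown stages:",
                              paste(bad_stage, collapse = ", ")))
  }
  if (length(errors)) {
    stop("invalid pipeline config:\n  - ",
         paste(errors, collapse = "\n  - "), call. = FALSE)
  }
  cfg$mixing <- mix
  class(cfg) <- "pipeline_config"
  cfg
}

#' Run the analysis pipeline end to end
#'
#' Executes the requested stages — simulate, prep (concentration
#' contrasts), select (tracer screen), mix (per-consumer mixing model +
#' pooling), lisst (cast processing), report — writing stage outputs as
#' CSV/JSON under `config$outdir` and returning a manifest (seed, stage
#' timings, output files). Fully deterministic under a fixed seed; stages
#' not requested leave their outputs untouched.
#'
#' @param config a `pipeline_config` from [validate_config()] (or a raw
#'   list, validated on the way in).
#' @param study_config optional [study_config()] overriding the default
#'   built from `config$seed`.
#' @return invisible list: the manifest plus in-memory stage results.
#' @export
run_pipeline <- function(config = list(), study_config = NULL) {
  if (!inherits(config, "pipeline_config")) config <- validate_config(config)
  dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
  sc <- study_config %||% midmix::study_config(seed = config$seed)
  manifest <- list(seed = config$seed, outdir = config$outdir,
                   stages = list())
  results <- list(config = config)
  t_stage <- function(name, expr) {
    t0 <- proc.time()[["elapsed"]]
    val <- tryCatch(expr, error = function(e) {
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE)
    })
    manifest$stages[[name]] <<- list(seconds =
                                       proc.time()[["elapsed"]] - t0)
    val
  }
  out_path <- function(f) file.path(config$outdir, f)

  if ("simulate" %in% config$stages) {
    study <- t_stage("simulate", generate_study(sc, census_regime =
                                                  config$census_regime))
    utils::write.csv(study$source_table, out_path("source_samples.csv"),
                     row.names = FALSE)
    utils::write.csv(study$consumer_table, out_path("consumers.csv"),
                     row.names = FALSE)
    utils::write.csv(study$aa_conc_table, out_path("aa_conc.csv"),
                     row.names = FALSE)
    utils::write.csv(study$trait_table, out_path("traits.csv"),
                     row.names = FALSE)
    for (cast in study$lisst_casts) {
      utils::write.csv(cbind(depth_db = cast$depth_db,
                             as.data.frame(cast$volumes)),
                       out_path(sprintf("lisst_cast_%s.csv", cast$cast_id)),
                       row.names = FALSE)
    }
    results$study <- study
  } else {
    study <- results$study
  }

  if ("prep" %in% config$stages && !is.null(study)) {
    prep <- t_stage("prep", {
      recs <- flag_outliers(study$aa_conc_table, rule = config$outlier_rule)
      contrasts <- lapply(sc$fractions, function(fr)
        compare_groups_anova(recs, fr))
      list(records = recs, contrasts = contrasts)
    })
    utils::write.csv(prep$records, out_path("aa_conc_flagged.csv"),
                     row.names = FALSE)
    results$prep <- prep
  }

  if ("select" %in% config$stages && !is.null(study)) {
    tracer_set <- t_stage("select",
                          select_tracers(study$tracer_table,
                                         alpha = config$tracer_alpha,
                                         max_missing = config$max_missing,
                                         n_perm = config$n_perm,
                                         seed = config$seed))
    jsonlite::write_json(list(selected = tracer_set$selected,
                              alpha = tracer_set$alpha,
                              max_missing = tracer_set$max_missing),
                         out_path("tracer_set.json"), auto_unbox = TRUE)
    results$tracer_set <- tracer_set
  }

  if ("mix" %in% config$stages && !is.null(study)) {
    mix <- t_stage("mix", {
      spec <- do.call(mixing_model_spec,
                      c(config$mixing, list(seed = config$seed)))
      tracers <- results$tracer_set$selected %||% sc$tracer_names
      src <- summarize_sources(study$source_table, tracers = tracers)
      pooled <- lapply(seq_len(nrow(study$consumer_table)), function(i) {
        fit <- run_mcmc(study$consumer_table[i, ], src, spec)
        pool_fractions(fit)
      })
      summaries <- consumer_summaries(pooled, study$consumer_table)
      list(spec = spec, src = src, pooled = pooled, summaries = summaries)
    })
    utils::write.csv(mix$summaries, out_path("mixing_summary.csv"),
                     row.names = FALSE)
    results$mix <- mix
  }

  if ("lisst" %in% config$stages && !is.null(study)) {
    lisst <- t_stage("lisst", {
      do.call(rbind, lapply(study$lisst_casts, function(cast) {
        cal <- baseline_calibrate(bin_to_depth(cast))
        fr <- aggregate_fractions(cal)
        modes <- psd_maxima(cal)
        data.frame(cast_id = cast$cast_id, cast_type = cast$cast_type,
                   peak_small_ul_l = max(fr$small_ul_l),
                   peak_large_ul_l = max(fr$large_ul_l),
                   modal_um = modes[1], stringsAsFactors = FALSE)
      }))
    })
    utils::write.csv(lisst, out_path("fraction_profiles.csv"),
                     row.names = FALSE)
    results$lisst <- lisst
  }

  if ("report" %in% config$stages && !is.null(results$mix)) {
    report <- t_stage("report", {
      census <- threshold_census(results$mix$summaries,
                                 threshold = config$census_threshold)
      groups <- group_contributions(results$mix$summaries)
      guilds <- guild_proportions(study$trait_table)
      build_report(census, groups, guilds,
                   aa_contrasts = results$prep$contrasts,
                   lisst_summary = results$lisst, seed = config$seed)
    })
    jsonlite::write_json(unclass(report), out_path("report.json"),
                         auto_unbox = TRUE, digits = NA, force = TRUE)
    writeLines(format(report), out_path("report.md"))
    results$report <- report
  }

  manifest$files <- list.files(config$outdir)
  results$manifest <- manifest
  invisible(results)
}
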