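#' Derive a reproducible sub-seed for a named pipeline stage
#'
#' A single global seed drives every stochastic stage of the pipeline. Each
#' stage (and each MCMC chain) gets its own RNG stream derived
#' deterministically from that seed, so rerunning one stage never perturbs
#' another.
#'
#' @param seed integer global seed.
#' @param stage stage name, one of the known pipeline stages, or an integer
#'   index.
#' @return an integer seed (< 2^31) for `set.seed()`.
#' @keywords internal
derive_seed <- function(seed, stage) {
  stages <- c("sources", "consumers", "aa_conc", "lisst", "traits",
              "tracer_table", "mcmc", "permanova", "simulation")
  idx <- if (is.character(stage)) match(stage, stages) else as.integer(stage)
  if (is.na(idx)) stop("unknown stage: ", stage)
  old <- get0(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  sample.int(.Machine$integer.max - 1L, 32L)[idx]
}

#' Check that a vector lies on the probability simplex
#' @param p numeric vector.
#' @param tol absolute tolerance on the sum.
#' @return TRUE or FALSE.
#' @keywords internal
is_simplex <- function(p, tol = 1e-12) {
  is.numeric(p) && all(is.finite(p)) && all(p >= -tol) &&
    abs(sum(p) - 1) <= max(tol, 1e-12 * length(p))
}

assert_simplex <- function(p, what = "mixture vector", tol = 1e-12) {
  if (!is_simplex(p, tol)) {
    stop(what, " must be non-negative and sum to 1 (got sum = ",
         format(sum(p), digits = 15), ")", call. = FALSE)
  }
  invisible(p)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
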