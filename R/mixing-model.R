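#' Sampler specification for the Bayesian mixing model
#'
#' Defaults reproduce the study's sampling schedule: three chains of
#' 100,000 steps retained after a 50,000-step adaptation and a
#' 40,000-step burn-in, thinned by 50 — 2000 retained draws per chain,
#' 6000 in total. The prior is a flat ("generalist") Dirichlet(1) over
#' the source proportions; `dirichlet_alpha = 1/K` is the common
#' alternative. Trophic discrimination factors are identically zero: the
#' tracers are source/essential amino acids, taken as non-fractionating
#' across trophic transfer. The analytical measurement SD (default
#' 0.5 permil for both nitrogen and carbon tracers, a typical
#' compound-specific precision) is a fixed model parameter, not an
#' estimated one, because each consumer is fit individually with a single
#' observation per tracer.
#'
#' @param dirichlet_alpha Dirichlet prior concentration (scalar, recycled
#'   over sources, or vector of length K).
#' @param measurement_sd fixed analytical SD per tracer (permil; scalar or
#'   vector of length J).
#' @param n_chains,n_adapt,n_burnin,n_iter,thin sampling schedule.
#' @param seed global seed; per-chain streams are derived from it.
#' @param tdf trophic discrimination factor added to source means
#'   (fixed 0 for non-fractionating tracers).
#' @param sd_floor lower bound applied to source SDs to avoid degenerate
#'   likelihoods (permil).
#' @param source_uncertainty `"fixed"` uses the sample SDs as the source
#'   spread; `"hierarchical"` adds the standard error of the source means
#'   (`s^2/n`) to the propagated variance.
#' @param target_accept Metropolis acceptance rate targeted during
#'   adaptation.
#' @return object of class `mixing_model_spec`.
#' @export
mixing_model_spec <- function(dirichlet_alpha = 1, measurement_sd = 0.5,
                              n_chains = 3, n_adapt = 50000,
                              n_burnin = 40000, n_iter = 100000, thin = 50,
                              seed = 1, tdf = 0, sd_floor = 0.1,
                              source_uncertainty = c("fixed", "hierarchical"),
                              target_accept = 0.3) {
  if (thin <= 0 || n_iter <= 0 || n_iter %% thin != 0) {
    stop("n_iter must be a positive multiple of thin")
  }
  if (n_adapt < 0 || n_burnin < 0) stop("n_adapt and n_burnin must be >= 0")
  if (any(measurement_sd <= 0)) stop("measurement_sd must be positive")
  if (any(dirichlet_alpha <= 0)) stop("dirichlet_alpha must be positive")
  structure(list(dirichlet_alpha = dirichlet_alpha,
                 measurement_sd = measurement_sd,
                 n_chains = as.integer(n_chains),
                 n_adapt = as.integer(n_adapt),
                 n_burnin = as.integer(n_burnin),
                 n_iter = as.integer(n_iter), thin = as.integer(thin),
                 seed = as.integer(seed), tdf = tdf, sd_floor = sd_floor,
                 source_uncertainty = match.arg(source_uncertainty),
                 target_accept = target_accept),
            class = "mixing_model_spec")
}

#' Summarize sample-level source data into the model's source distributions
#'
#' Per size fraction and tracer: sample mean, sample SD (floored at
#' `sd_floor` permil so constant samples cannot produce a degenerate
#' likelihood) and sample count.
#'
#' @param source_table long table from [generate_source_samples()] (or
#'   same schema: `fraction`, `tracer`, `value_permil`).
#' @param tracers tracer names to keep (default: all present).
#' @param sd_floor SD floor (permil).
#' @return object of class `source_summary` with matrices `means`, `sds`
#'   (K x J) and counts `n` (per fraction).
#' @export
summarize_sources <- function(source_table, tracers = NULL, sd_floor = 0.1) {
  tracers <- tracers %||% unique(source_table$tracer)
  if (inherits(tracers, "tracer_set")) tracers <- tracers$selected
  tab <- source_table[source_table$tracer %in% tracers, , drop = FALSE]
  fractions <- unique(tab$fraction)
  cnt <- tapply(tab$value_permil,
                list(factor(tab$fraction, fractions),
                     factor(tab$tracer, tracers)), length)
  if (any(is.na(cnt)) || any(cnt < 2)) {
    bad <- fractions[apply(is.na(cnt) | cnt < 2, 1, any)]
    stop("fraction(s) with < 2 samples for some tracer: ",
         paste(bad, collapse = ", "))
  }
  means <- tapply(tab$value_permil,
                  list(factor(tab$fraction, fractions),
                       factor(tab$tracer, tracers)), mean)
  sds <- tapply(tab$value_permil,
                list(factor(tab$fraction, fractions),
                     factor(tab$tracer, tracers)), stats::sd)
  sds <- pmax(sds, sd_floor)
  structure(list(fractions = fractions, tracers = tracers,
                 means = means, sds = sds,
                 n = stats::setNames(as.vector(cnt[, 1]), fractions),
                 sd_floor = sd_floor),
            class = "source_summary")
}

#' @export
print.source_summary <- function(x, ...) {
  cat("Source summary:", length(x$fractions), "fractions x",
      length(x$tracers), "tracers\n")
  print(round(x$means, 2))
  invisible(x)
}

# propagated sampling variance per tracer for mixture p (internal)
mix_moments <- function(p, src, spec) {
  m <- src$means + spec$tdf
  s2 <- src$sds^2
  if (spec$source_uncertainty == "hierarchical") {
    s2 <- s2 + src$sds^2 / src$n
  }
  J <- length(src$tracers)
  tau2 <- rep(spec$measurement_sd^2, length.out = J)
  list(mu = as.vector(p %*% m),
       var = as.vector(p^2 %*% s2) + tau2, m = m, s2 = s2, tau2 = tau2)
}

#' Log posterior density of a source-proportion vector
#'
#' The model's unnormalized-in-data but fully specified log density:
#' independent Normal likelihoods per tracer with mixture mean
#' `mu_j = sum_k p_k m_kj` and propagated variance
#' `sigma_j^2 = sum_k p_k^2 s_kj^2 + tau_j^2`, plus the full
#' Dirichlet(alpha) log density over p (normalizing constant included).
#' This pure-R density is the reference the compiled sampler and the
#' quadrature oracle both target.
#'
#' @param p proportion vector on the K-simplex.
#' @param x named (or ordered) tracer observation vector of length J.
#' @param src a [summarize_sources()] result.
#' @param spec a [mixing_model_spec()].
#' @return log density (scalar).
#' @export
log_posterior <- function(p, x, src, spec = mixing_model_spec()) {
  assert_simplex(p, "proportion vector", tol = 1e-9)
  K <- length(src$fractions)
  if (length(p) != K) stop("p must have one entry per source fraction")
  if (!is.null(names(x))) x <- x[src$tracers]
  x <- as.numeric(x)
  mom <- mix_moments(p, src, spec)
  ll <- sum(stats::dnorm(x, mom$mu, sqrt(mom$var), log = TRUE))
  alpha <- rep(spec$dirichlet_alpha, length.out = K)
  ldir <- lgamma(sum(alpha)) - sum(lgamma(alpha)) +
    sum(ifelse(alpha == 1, 0, (alpha - 1) * log(p)))
  ll + ldir
}

# vectorized log posterior over rows of a proportion matrix (internal)
log_posterior_batch <- function(P, x, src, spec) {
  m <- src$means + spec$tdf
  s2 <- src$sds^2
  if (spec$source_uncertainty == "hierarchical") s2 <- s2 + src$sds^2 / src$n
  J <- length(src$tracers)
  tau2 <- rep(spec$measurement_sd^2, length.out = J)
  mu <- P %*% m
  v <- sweep((P^2) %*% s2, 2, tau2, "+")
  ll <- rowSums(-0.5 * log(2 * pi * v) -
                  0.5 * sweep(mu, 2, as.numeric(x), "-")^2 / v)
  alpha <- rep(spec$dirichlet_alpha, length.out = ncol(P))
  if (any(alpha != 1)) {
    lp <- log(P)
    lp[P == 0] <- -Inf
    ll <- ll + as.vector(lp %*% (alpha - 1))
  }
  ll
}

#' Fit the mixing model to one consumer by MCMC
#'
#' Runs `n_chains` additive-log-ratio random-walk Metropolis chains over
#' the source-proportion simplex with the spec's exact schedule
#' (adaptation confined to the first `n_adapt` steps, then `n_burnin`
#' discarded steps, then `n_iter` steps retained at stride `thin`). Each
#' chain has its own RNG stream derived from `spec$seed`, so reruns are
#' byte-identical. Convergence is assessed by split-chain R-hat; any
#' component above `rhat_limit` flags the result as non-converged (it is
#' still returned).
#'
#' @param x consumer observation: named numeric vector of tracer values,
#'   or a one-row data.frame carrying the tracer columns.
#' @param src a [summarize_sources()] result.
#' @param spec a [mixing_model_spec()].
#' @param rhat_limit convergence flag threshold.
#' @return object of class `mixing_posterior`: `draws` (n_keep x K x
#'   chain array on the simplex), `means`, `sds`, `rhat`, `ess`,
#'   `converged`, plus the inputs.
#' @export
run_mcmc <- function(x, src, spec = mixing_model_spec(), rhat_limit = 1.05) {
  stopifnot(inherits(src, "source_summary"),
            inherits(spec, "mixing_model_spec"))
  if (is.data.frame(x)) x <- unlist(x[1, src$tracers, drop = TRUE])
  if (!is.null(names(x))) x <- x[src$tracers]
  if (anyNA(x)) stop("tracer vector incomplete for the selected tracers")
  K <- length(src$fractions)
  J <- length(src$tracers)
  m <- src$means + spec$tdf
  s2 <- src$sds^2
  if (spec$source_uncertainty == "hierarchical") s2 <- s2 + src$sds^2 / src$n
  tau2 <- rep(spec$measurement_sd^2, length.out = J)
  alpha <- rep(spec$dirichlet_alpha, length.out = K)

  old <- get0(".Random.seed", envir = globalenv(), inherits = FALSE)
  set.seed(spec$seed)
  chain_seeds <- sample.int(.Machine$integer.max - 1L, spec$n_chains)
  n_keep <- spec$n_iter %/% spec$thin
  draws <- array(NA_real_, c(n_keep, K, spec$n_chains),
                 dimnames = list(NULL, src$fractions, NULL))
  for (ch in seq_len(spec$n_chains)) {
    set.seed(chain_seeds[ch])
    draws[, , ch] <- alr_rwm_chain(as.numeric(x), m, s2, tau2, alpha,
                                   spec$n_adapt, spec$n_burnin,
                                   spec$n_iter, spec$thin,
                                   spec$target_accept)
  }
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())

  flat <- apply(draws, 2, as.vector)
  diag <- diagnose(draws)
  structure(list(draws = draws,
                 means = colMeans(flat), sds = apply(flat, 2, stats::sd),
                 rhat = diag$rhat, ess = diag$ess,
                 converged = all(is.na(diag$rhat) | diag$rhat <= rhat_limit),
                 fractions = src$fractions, x = x, spec = spec),
            class = "mixing_posterior")
}

#' @export
print.mixing_posterior <- function(x, ...) {
  cat("Mixing posterior over", length(x$fractions), "sources",
      sprintf("(%d draws)\n", prod(dim(x$draws)[c(1, 3)])))
  print(round(rbind(mean = x$means, sd = x$sds, rhat = x$rhat), 3))
  if (!x$converged) cat("  WARNING: flagged non-converged\n")
  invisible(x)
}

#' Deterministic simplex-quadrature posterior (testing oracle)
#'
#' Evaluates the same posterior density on a regular grid over the
#' (K-1)-simplex (step `grid_step` in each proportion) and returns
#' normalized-weight means and SDs. Deterministic, so it serves as the
#' independent oracle against which the MCMC sampler is checked.
#'
#' @param x consumer tracer vector (named or ordered as `src$tracers`).
#' @param src a [summarize_sources()] result (K <= 4).
#' @param spec a [mixing_model_spec()].
#' @param grid_step grid resolution on each proportion (must be < 0.2).
#' @return list with `means`, `sds`, `n_grid`.
#' @export
brute_force_posterior <- function(x, src, spec = mixing_model_spec(),
                                  grid_step = 0.005) {
  stopifnot(inherits(src, "source_summary"))
  K <- length(src$fractions)
  if (K > 4) stop("quadrature oracle supports K <= 4")
  if (grid_step >= 0.2) stop("grid too coarse: grid_step must be < 0.2")
  if (is.data.frame(x)) x <- unlist(x[1, src$tracers, drop = TRUE])
  if (!is.null(names(x))) x <- x[src$tracers]
  N <- round(1 / grid_step)
  P <- simplex_grid(K, N)
  lp <- log_posterior_batch(P, as.numeric(x), src, spec)
  w <- exp(lp - max(lp))
  w <- w / sum(w)
  means <- as.vector(t(P) %*% w)
  sds <- sqrt(pmax(as.vector(t(P^2) %*% w) - means^2, 0))
  names(means) <- names(sds) <- src$fractions
  list(means = means, sds = sds, n_grid = nrow(P))
}

# all K-part compositions of N on the simplex grid (internal)
simplex_grid <- function(K, N) {
  if (K == 2) {
    i <- 0:N
    return(cbind(i, N - i) / N)
  }
  if (K == 3) {
    g <- expand.grid(i = 0:N, j = 0:N)
    g <- g[g$i + g$j <= N, ]
    return(cbind(g$i, g$j, N - g$i - g$j) / N)
  }
  if (K == 4) {
    g <- expand.grid(i = 0:N, j = 0:N, k = 0:N)
    g <- g[g$i + g$j + g$k <= N, ]
    return(cbind(g$i, g$j, g$k, N - g$i - g$j - g$k) / N)
  }
  stop("simplex_grid supports K in 2..4")
}

#' Multi-chain convergence diagnostics
#'
#' Split-chain Gelman-Rubin statistic and effective sample size per
#' simplex component. Each chain is split in half; R-hat is
#' `sqrt(((n-1)/n W + B/n) / W)` over the 2M half-chains. ESS uses the
#' multi-chain autocorrelation estimate truncated by Geyer's initial
#' positive-sequence rule. With a single chain R-hat is undefined (NA)
#' and only ESS is returned; zero-variance chains yield NA R-hat.
#'
#' @param draws array (draw x component x chain), or a `mixing_posterior`.
#' @return list with numeric vectors `rhat` and `ess` per component.
#' @export
diagnose <- function(draws) {
  if (inherits(draws, "mixing_posterior")) draws <- draws$draws
  if (length(dim(draws)) != 3) stop("draws must be draw x component x chain")
  n <- dim(draws)[1]; K <- dim(draws)[2]; M <- dim(draws)[3]
  if (n < 2) stop("need at least 2 retained draws per chain")
  rhat <- rep(NA_real_, K)
  ess <- rep(NA_real_, K)
  for (k in seq_len(K)) {
    ch <- draws[, k, , drop = TRUE]
    ch <- matrix(ch, nrow = n)
    # split each chain in half
    half <- floor(n / 2)
    splits <- do.call(cbind, lapply(seq_len(M), function(m) {
      cbind(ch[seq_len(half), m], ch[half + seq_len(half), m])
    }))
    if (M >= 2 || ncol(splits) >= 2) {
      W <- mean(apply(splits, 2, stats::var))
      B <- half * stats::var(colMeans(splits))
      rhat[k] <- if (W <= 1e-300) NA_real_ else
        sqrt(((half - 1) / half * W + B / half) / W)
    }
    # ESS from averaged per-chain autocovariances (Geyer truncation)
    W_full <- mean(apply(ch, 2, stats::var))
    if (W_full <= 1e-300) next
    B_full <- if (M >= 2) n * stats::var(colMeans(ch)) else 0
    var_plus <- (n - 1) / n * W_full + B_full / n
    max_lag <- min(n - 1, 1000)
    acov <- rowMeans(vapply(seq_len(M), function(m) {
      a <- stats::acf(ch[, m], lag.max = max_lag, plot = FALSE,
                      type = "covariance", demean = TRUE)$acf[, 1, 1]
      a
    }, numeric(max_lag + 1)))
    rho <- 1 - (W_full - acov[-1]) / var_plus
    # Geyer: sum over pairs while pair sums stay positive
    s <- 0; t <- 1
    while (t + 1 <= length(rho)) {
      pair <- rho[t] + rho[t + 1]
      if (pair < 0) break
      s <- s + pair
      t <- t + 2
    }
    ess[k] <- min(M * n, M * n / (1 + 2 * s))
  }
  names(rhat) <- names(ess) <- dimnames(draws)[[2]]
  list(rhat = rhat, ess = ess)
}

#' Pool posterior source fractions into composite classes
#'
#' Sums proportions within each pooled class per retained draw (so pooled
#' SDs come from pooled draws, not from summing component summaries).
#' The default pools the medium and large fractions into the ">6 µm"
#' class against the small (0.7–6 µm) class. The mapping must partition
#' the fractions.
#'
#' @param posterior a `mixing_posterior`.
#' @param mapping named list of fraction-label vectors.
#' @return a `mixing_posterior` over the pooled classes.
#' @export
pool_fractions <- function(posterior,
                           mapping = list(small = "small",
                                          large = c("medium", "large"))) {
  stopifnot(inherits(posterior, "mixing_posterior"))
  all_mapped <- unlist(mapping)
  if (length(all_mapped) != length(posterior$fractions) ||
      !setequal(all_mapped, posterior$fractions) ||
      anyDuplicated(all_mapped)) {
    stop("mapping must partition the source fractions")
  }
  dims <- dim(posterior$draws)
  pooled <- array(NA_real_, c(dims[1], length(mapping), dims[3]),
                  dimnames = list(NULL, names(mapping), NULL))
  for (i in seq_along(mapping)) {
    sel <- posterior$fractions %in% mapping[[i]]
    pooled[, i, ] <- apply(posterior$draws[, sel, , drop = FALSE],
                           c(1, 3), sum)
  }
  flat <- apply(pooled, 2, as.vector)
  out <- posterior
  out$draws <- pooled
  out$fractions <- names(mapping)
  out$means <- colMeans(flat)
  out$sds <- apply(flat, 2, stats::sd)
  diag <- diagnose(pooled)
  out$rhat <- diag$rhat
  out$ess <- diag$ess
  out
}

#' Equal-tailed credible interval per source fraction
#'
#' @param posterior a `mixing_posterior`.
#' @param level interval mass (default 0.90).
#' @return matrix (fraction x c(lower, upper)).
#' @export
credible_interval <- function(posterior, level = 0.90) {
  stopifnot(inherits(posterior, "mixing_posterior"))
  flat <- apply(posterior$draws, 2, as.vector)
  a <- (1 - level) / 2
  t(apply(flat, 2, stats::quantile, probs = c(a, 1 - a), names = FALSE))
}
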