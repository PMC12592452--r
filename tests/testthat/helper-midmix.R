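# shared fixtures: a short sampling schedule for tests that only need a
# correct posterior, not the full production schedule
quick_spec <- function(seed = 1, ...) {
  mixing_model_spec(n_adapt = 2000, n_burnin = 2000, n_iter = 10000,
                    thin = 10, seed = seed, ...)
}

# independent PERMANOVA oracle: pseudo-F from within-group pairwise
# squared distances (no Gower centering), Anderson's direct formula
oracle_permanova_F <- function(D, labels) {
  D <- as.matrix(D)
  n <- nrow(D)
  labels <- as.factor(labels)
  a <- nlevels(labels)
  ss_pairs <- function(idx) {
    if (length(idx) < 2) return(0)
    sum(D[idx, idx]^2) / 2 / length(idx)
  }
  ss_total <- sum(D^2) / 2 / n
  ss_within <- sum(vapply(split(seq_len(n), labels), ss_pairs, numeric(1)))
  ss_among <- ss_total - ss_within
  (ss_among / (a - 1)) / (ss_within / (n - a))
}

# exhaustive-permutation p for a two-group design, via the oracle F
oracle_permanova_exhaustive_p <- function(D, labels) {
  labels <- as.factor(labels)
  n <- length(labels)
  lv <- levels(labels)
  stopifnot(length(lv) == 2)
  n1 <- sum(labels == lv[1])
  f_obs <- oracle_permanova_F(D, labels)
  combos <- utils::combn(n, n1)
  f_all <- apply(combos, 2, function(idx) {
    lab <- rep(lv[2], n)
    lab[idx] <- lv[1]
    oracle_permanova_F(D, lab)
  })
  mean(f_all >= f_obs - 1e-12)
}

# two-source one-tracer summary with near-degenerate source spread
two_source_summary <- function(m1 = 0, m2 = 10, sd_floor = 0.01) {
  tab <- data.frame(
    fraction = rep(c("src1", "src2"), each = 3),
    tracer = "t1",
    value_permil = c(rep(m1, 3), rep(m2, 3))
  )
  summarize_sources(tab, sd_floor = sd_floor)
}
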