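#' Drop candidate tracers with excessive missingness
#'
#' A candidate AA isotope variable is unusable for the mixing model if it
#' is absent from too many particle samples: the default drops a variable
#' missing from at least `max_missing` samples within any single size
#' fraction (the strictest reading; set `per_fraction = FALSE` to count
#' across all fractions instead).
#'
#' @param table candidate table from [generate_tracer_table()] or with the
#'   same layout (`fraction` column + numeric candidate columns).
#' @param max_missing missing-count threshold (default 4).
#' @param candidates candidate column names (default: attribute
#'   `candidates`, else all numeric columns).
#' @param per_fraction count missingness within each fraction separately.
#' @return character vector of retained variable names, with a data.frame
#'   of per-variable missing counts in attribute `evidence`.
#' @export
missingness_filter <- function(table, max_missing = 4, candidates = NULL,
                               per_fraction = TRUE) {
  if (nrow(table) == 0) stop("empty table")
  candidates <- candidates %||% attr(table, "candidates") %||%
    names(table)[vapply(table, is.numeric, logical(1))]
  ev <- lapply(candidates, function(v) {
    miss <- tapply(is.na(table[[v]]), table$fraction, sum)
    data.frame(variable = v, max_missing_per_fraction = max(miss),
               total_missing = sum(miss), stringsAsFactors = FALSE)
  })
  ev <- do.call(rbind, ev)
  drop <- if (per_fraction) {
    ev$max_missing_per_fraction >= max_missing
  } else {
    ev$total_missing >= max_missing
  }
  keep <- ev$variable[!drop]
  attr(keep, "evidence") <- ev
  keep
}

#' Retain candidate tracers that discriminate between size fractions
#'
#' A variable is useful as a mixing-model tracer only if its values differ
#' between the particle size fractions; each candidate is screened by
#' one-way ANOVA across fractions and kept when `p < alpha`. Candidates
#' with insufficient replication (fewer than 2 fractions with 2+
#' non-missing values) are dropped with a warning.
#'
#' @param table candidate table (see [missingness_filter()]).
#' @param alpha significance level of the screen (default 0.05).
#' @param candidates candidate column names.
#' @return retained variable names, with per-variable F and p in attribute
#'   `evidence`.
#' @export
fraction_discrimination_screen <- function(table, alpha = 0.05,
                                           candidates = NULL) {
  if (alpha <= 0 || alpha > 1) stop("alpha must lie in (0, 1]")
  candidates <- candidates %||% attr(table, "candidates") %||%
    names(table)[vapply(table, is.numeric, logical(1))]
  ev <- lapply(candidates, function(v) {
    ok <- !is.na(table[[v]])
    tab <- table(table$fraction[ok])
    if (sum(tab >= 2) < 2) {
      warning("variable ", v, " lacks replication; dropped from screen")
      return(data.frame(variable = v, F = NA_real_, p = NA_real_,
                        stringsAsFactors = FALSE))
    }
    an <- stats::anova(stats::aov(table[[v]][ok] ~ factor(table$fraction[ok])))
    data.frame(variable = v, F = an[["F value"]][1], p = an[["Pr(>F)"]][1],
               stringsAsFactors = FALSE)
  })
  ev <- do.call(rbind, ev)
  keep <- ev$variable[!is.na(ev$p) & ev$p < alpha]
  attr(keep, "evidence") <- ev
  keep
}

#' Permutational multivariate ANOVA pseudo-F on a distance matrix
#'
#' Computes the pseudo-F of a one-way group design directly from a
#' distance matrix via the Gower-centered decomposition: with
#' `G = -1/2 C D^2 C` (C the centering matrix), the among-group sum of
#' squares is `tr(H G)` for the group-design hat matrix H and the within
#' sum of squares is `tr((I - H) G)`. The p value is obtained by permuting
#' the label vector, with the add-one estimator
#' `p = (1 + #(F* >= F)) / (1 + n_perm)` so p is never zero, or by
#' exhaustive enumeration of distinct label assignments (then
#' `p = #(F* >= F) / #assignments`, the identity included).
#'
#' @param distance_matrix square symmetric non-negative matrix with zero
#'   diagonal (or a `dist` object).
#' @param labels group labels, one per row.
#' @param n_perm number of Monte-Carlo permutations (default 999).
#' @param seed RNG seed for the permutations.
#' @param exhaustive enumerate all distinct label assignments instead of
#'   sampling (feasible for small n).
#' @return list with `F`, `p`, `df`, `n_perm` (or number of enumerated
#'   assignments), `method`.
#' @export
permanova_pseudo_F <- function(distance_matrix, labels, n_perm = 999,
                               seed = 1, exhaustive = FALSE) {
  D <- as.matrix(distance_matrix)
  n <- nrow(D)
  if (ncol(D) != n) stop("distance matrix must be square")
  if (any(abs(D - t(D)) > 1e-8)) stop("distance matrix must be symmetric")
  if (any(D < -1e-12)) stop("distances must be non-negative")
  if (any(abs(diag(D)) > 1e-8)) stop("distance matrix must have zero diagonal")
  labels <- as.factor(labels)
  if (length(labels) != n) stop("one label per observation required")
  tab <- table(labels)
  if (length(tab) < 2 || any(tab < 2)) {
    stop("need >= 2 groups with >= 2 members each")
  }
  a <- length(tab)

  A <- -0.5 * D^2
  G <- sweep(sweep(A, 1, rowMeans(A)), 2, colMeans(A)) + mean(A)
  ss_total <- sum(diag(G))

  pseudo_F <- function(lab) {
    # tr(HG) = sum_g 1_g' G 1_g / n_g
    ss_among <- sum(vapply(split(seq_len(n), lab), function(i) {
      sum(G[i, i]) / length(i)
    }, numeric(1)))
    ss_within <- ss_total - ss_among
    (ss_among / (a - 1)) / (ss_within / (n - a))
  }
  f_obs <- pseudo_F(labels)

  if (exhaustive) {
    perms <- distinct_assignments(labels)
    f_perm <- vapply(perms, pseudo_F, numeric(1))
    p <- mean(f_perm >= f_obs - 1e-12)
    return(list(F = f_obs, p = p, df = c(a - 1, n - a),
                n_perm = length(perms), method = "exhaustive"))
  }
  set.seed(seed)
  f_perm <- vapply(seq_len(n_perm), function(i) {
    pseudo_F(labels[sample.int(n)])
  }, numeric(1))
  p <- (1 + sum(f_perm >= f_obs - 1e-12)) / (1 + n_perm)
  list(F = f_obs, p = p, df = c(a - 1, n - a), n_perm = n_perm,
       method = "monte_carlo")
}

# all distinct assignments of the multiset of labels to positions
distinct_assignments <- function(labels) {
  labels <- as.factor(labels)
  n <- length(labels)
  rec <- function(pos, remaining) {
    lv <- names(remaining)[remaining > 0]
    if (length(pos) == n) return(list(factor(pos, levels = levels(labels))))
    out <- list()
    for (l in lv) {
      r2 <- remaining
      r2[l] <- r2[l] - 1
      out <- c(out, rec(c(pos, l), r2))
    }
    out
  }
  rec(character(0), table(labels))
}

#' Within-fraction homogeneity report over sampling factors
#'
#' For each size fraction and each sampling factor (site, cruise, depth
#' stratum), runs pairwise PERMANOVA on Euclidean distances over the
#' tracer columns between every pair of factor levels, with
#' Benjamini-Hochberg adjustment across the pairs of each
#' fraction x factor cell (raw p also reported). A clean report (no
#' adjusted p below alpha) supports pooling samples across those factors
#' when summarizing sources. Pairs where a level has fewer than 2 samples
#' are skipped and reported as such.
#'
#' @param table candidate/tracer table with metadata columns.
#' @param tracers tracer column names to compute distances over.
#' @param factors metadata columns to test.
#' @param n_perm,seed permutation settings per test.
#' @return data.frame report: fraction, factor, level pair, n per level,
#'   F, raw p, BH-adjusted p (NA for skipped pairs).
#' @export
within_fraction_homogeneity <- function(table, tracers,
                                        factors = c("site", "cruise",
                                                    "depth_stratum"),
                                        n_perm = 999, seed = 1) {
  missing_cols <- setdiff(c(factors, tracers, "fraction"), names(table))
  if (length(missing_cols)) {
    stop("columns absent from table: ", paste(missing_cols, collapse = ", "))
  }
  rows <- list()
  for (fr in unique(table$fraction)) {
    d_fr <- table[table$fraction == fr, , drop = FALSE]
    X <- as.matrix(d_fr[, tracers, drop = FALSE])
    keep <- stats::complete.cases(X)
    X <- X[keep, , drop = FALSE]
    d_fr <- d_fr[keep, , drop = FALSE]
    for (fac in factors) {
      lv <- unique(d_fr[[fac]])
      if (length(lv) < 2) next
      pairs <- utils::combn(sort(lv), 2, simplify = FALSE)
      for (pr in pairs) {
        sel <- d_fr[[fac]] %in% pr
        lab <- d_fr[[fac]][sel]
        n_by <- table(lab)
        if (length(n_by) < 2 || any(n_by < 2)) {
          rows[[length(rows) + 1]] <- data.frame(
            fraction = fr, factor = fac, level_a = pr[1], level_b = pr[2],
            n_a = sum(lab == pr[1]), n_b = sum(lab == pr[2]),
            F = NA_real_, p = NA_real_, skipped = TRUE,
            stringsAsFactors = FALSE)
          next
        }
        res <- permanova_pseudo_F(stats::dist(X[sel, , drop = FALSE]),
                                  lab, n_perm = n_perm,
                                  seed = seed + length(rows))
        rows[[length(rows) + 1]] <- data.frame(
          fraction = fr, factor = fac, level_a = pr[1], level_b = pr[2],
          n_a = sum(lab == pr[1]), n_b = sum(lab == pr[2]),
          F = res$F, p = res$p, skipped = FALSE, stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(rows)) {
    return(data.frame(fraction = character(0), factor = character(0),
                      level_a = character(0), level_b = character(0),
                      n_a = integer(0), n_b = integer(0), F = numeric(0),
                      p = numeric(0), skipped = logical(0),
                      p_adj = numeric(0)))
  }
  rep <- do.call(rbind, rows)
  rep$p_adj <- NA_real_
  for (cell in unique(paste(rep$fraction, rep$factor))) {
    idx <- paste(rep$fraction, rep$factor) == cell & !rep$skipped
    rep$p_adj[idx] <- stats::p.adjust(rep$p[idx], method = "BH")
  }
  rep
}

#' Select mixing-model tracers by the iterative statistical screen
#'
#' Chains the two per-variable filters — missingness (drop variables
#' absent from `max_missing`+ samples of any size fraction) and
#' fraction discrimination (keep variables whose one-way ANOVA across
#' fractions has `p < alpha`) — and attaches the within-fraction
#' homogeneity report over the sampling factors. On a candidate table
#' built to emulate the study, this selects the two nitrogen source amino
#' acids (Phe, Lys) and the carbon essential amino acid (Leu).
#'
#' @param table candidate table (see [generate_tracer_table()]).
#' @param alpha ANOVA screen level.
#' @param max_missing missingness threshold.
#' @param candidates candidate column names.
#' @param factors homogeneity factors present in `table` (set NULL to skip
#'   the report).
#' @param n_perm,seed permutation settings for the homogeneity report.
#' @return list of class `tracer_set`: `selected`, `evidence` (per-filter
#'   tables), `homogeneity` report.
#' @export
select_tracers <- function(table, alpha = 0.05, max_missing = 4,
                           candidates = NULL,
                           factors = c("site", "cruise", "depth_stratum"),
                           n_perm = 199, seed = 1) {
  candidates <- candidates %||% attr(table, "candidates") %||%
    names(table)[vapply(table, is.numeric, logical(1))]
  kept1 <- missingness_filter(table, max_missing = max_missing,
                              candidates = candidates)
  if (length(kept1) == 0) stop("no usable tracers: all candidates fail the missingness filter")
  kept2 <- fraction_discrimination_screen(table, alpha = alpha,
                                          candidates = as.character(kept1))
  if (length(kept2) == 0) stop("no usable tracers: no candidate discriminates between fractions")
  hom <- if (!is.null(factors) && all(factors %in% names(table))) {
    within_fraction_homogeneity(table, tracers = as.character(kept2),
                                factors = factors, n_perm = n_perm,
                                seed = seed)
  }
  structure(list(selected = as.character(kept2),
                 evidence = list(missingness = attr(kept1, "evidence"),
                                 anova = attr(kept2, "evidence")),
                 homogeneity = hom,
                 alpha = alpha, max_missing = max_missing),
            class = "tracer_set")
}

#' @export
print.tracer_set <- function(x, ...) {
  cat("Selected tracers:", paste(x$selected, collapse = ", "), "\n")
  cat(sprintf("  (missingness threshold %d, ANOVA screen alpha %.3g)\n",
              x$max_missing, x$alpha))
  invisible(x)
}
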