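#' Summarize fitted consumers into one table
#'
#' Convenience collector: takes per-consumer pooled posteriors (from
#' [pool_fractions()]) plus metadata and builds the flat summary table the
#' census and group summaries consume.
#'
#' @param posteriors named list of pooled `mixing_posterior` objects (two
#'   classes, small / large).
#' @param metadata data.frame with `consumer_id`, `group`, `depth_m`
#'   matching the list names or order.
#' @return data.frame: `consumer_id`, `group`, `depth_m`, `mean_small`,
#'   `mean_large`, `sd_small`, `sd_large`, `p_large_ge_half` (posterior
#'   probability the large-class contribution is at least 0.5),
#'   `converged`.
#' @export
consumer_summaries <- function(posteriors, metadata) {
  stopifnot(nrow(metadata) == length(posteriors))
  rows <- lapply(seq_along(posteriors), function(i) {
    po <- posteriors[[i]]
    stopifnot(inherits(po, "mixing_posterior"))
    large <- as.vector(po$draws[, "large", ])
    data.frame(consumer_id = metadata$consumer_id[i],
               group = metadata$group[i], depth_m = metadata$depth_m[i],
               mean_small = po$means[["small"]],
               mean_large = po$means[["large"]],
               sd_small = po$sds[["small"]], sd_large = po$sds[["large"]],
               p_large_ge_half = mean(large >= 0.5),
               converged = po$converged, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Census of consumers relying on large particles for their trophic base
#'
#' For each depth stratum, counts the consumers whose pooled >6 µm
#' (medium + large) contribution is at least `threshold`. The criterion
#' applies to the posterior mean by default (the natural reading of a
#' consumer "relying on large particles for at least half of its trophic
#' base"); `statistic = "probability"` instead thresholds the posterior
#' probability `P(p_large >= 0.5) >= 0.5`, reported side by side in the
#' output either way. Strata are half-open `[lower, upper)` in meters so
#' a consumer at exactly 1000 m is never double-counted; consumers with
#' missing depth fall outside every stratum.
#'
#' @param summaries table from [consumer_summaries()] (needs `depth_m`,
#'   `mean_large`, `p_large_ge_half`).
#' @param threshold pooled large-fraction cutoff (default 0.5).
#' @param strata named list of `c(lower, upper)` depth windows (m).
#' @param statistic posterior summary the criterion applies to.
#' @return data.frame of class `census_report`: stratum, n, count,
#'   percent, and the probability-criterion count for comparison.
#' @export
threshold_census <- function(summaries, threshold = 0.5,
                             strata = list(`700-1500m` = c(700, 1500),
                                           `1000-1500m` = c(1000, 1500)),
                             statistic = c("mean", "probability")) {
  statistic <- match.arg(statistic)
  rows <- lapply(names(strata), function(s) {
    w <- strata[[s]]
    sel <- !is.na(summaries$depth_m) &
      summaries$depth_m >= w[1] & summaries$depth_m < w[2]
    n <- sum(sel)
    stat <- if (statistic == "mean") summaries$mean_large[sel] else
      summaries$p_large_ge_half[sel]
    count <- sum(stat >= threshold)
    data.frame(stratum = s, n = n, count = count,
               percent = if (n > 0) 100 * count / n else NA_real_,
               count_prob_criterion =
                 sum(summaries$p_large_ge_half[sel] >= 0.5),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  attr(out, "threshold") <- threshold
  attr(out, "statistic") <- statistic
  class(out) <- c("census_report", class(out))
  out
}

#' Mean particle-source contributions by consumer group
#'
#' Per group (zooplankton size fraction or micronekton taxon): mean and SD
#' across consumers of the pooled posterior-mean contributions, plus the
#' count of groups whose mean large-fraction contribution exceeds 0.5.
#'
#' @param summaries table from [consumer_summaries()].
#' @param grouping column name holding the group label.
#' @return list with `groups` (data.frame: group, n, mean/sd of small and
#'   large contributions) and `n_groups_large_over_half`.
#' @export
group_contributions <- function(summaries, grouping = "group") {
  g <- summaries[[grouping]]
  if (anyNA(g)) {
    stop("consumers without a group assignment: ",
         paste(summaries$consumer_id[is.na(g)], collapse = ", "))
  }
  sp <- split(summaries, g)
  tab <- do.call(rbind, lapply(names(sp), function(nm) {
    d <- sp[[nm]]
    data.frame(group = nm, n = nrow(d),
               mean_small = mean(d$mean_small),
               sd_small = stats::sd(d$mean_small),
               mean_large = mean(d$mean_large),
               sd_large = stats::sd(d$mean_large),
               stringsAsFactors = FALSE)
  }))
  list(groups = tab,
       n_groups_large_over_half = sum(tab$mean_large > 0.5))
}

#' Feeding-guild proportions, unweighted and density-weighted
#'
#' Per community group (zooplankton / micronekton): the share of taxa in
#' each feeding guild, and optionally the share of total density held by
#' each guild.
#'
#' @param trait_table table from [generate_trait_table()] (`taxon`,
#'   `group`, `guild`, `density_weight`).
#' @param weights `"none"` for taxon proportions, `"density"` to weight
#'   each taxon by its density.
#' @return data.frame: group, guild, n_taxa, percent (per the requested
#'   weighting; percentages sum to 100 within each group).
#' @export
guild_proportions <- function(trait_table, weights = c("none", "density")) {
  weights <- match.arg(weights)
  if (anyNA(trait_table$guild)) stop("guild labels incomplete")
  if (weights == "density" && (!"density_weight" %in% names(trait_table) ||
                               anyNA(trait_table$density_weight))) {
    stop("density weights requested but missing")
  }
  out <- list()
  for (grp in unique(trait_table$group)) {
    d <- trait_table[trait_table$group == grp, , drop = FALSE]
    w <- if (weights == "density") d$density_weight else rep(1, nrow(d))
    tot <- tapply(w, d$guild, sum)
    out[[grp]] <- data.frame(group = grp, guild = names(tot),
                             n_taxa = as.vector(table(d$guild)[names(tot)]),
                             percent = 100 * as.vector(tot) / sum(tot),
                             stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Assemble the conclusion-level report
#'
#' Single structured artifact gathering the census, group contributions,
#' guild proportions, and (optionally) the amino-acid concentration
#' contrasts and LISST fraction summaries, each traceable to the seed that
#' produced its inputs. Empty optional sections are omitted. The report
#' is machine-readable (JSON via [jsonlite::write_json()]) and renders to
#' markdown via `format()`.
#'
#' @param census a `census_report`.
#' @param groups a [group_contributions()] result.
#' @param guilds a [guild_proportions()] result.
#' @param aa_contrasts optional list of [compare_groups_anova()] results.
#' @param lisst_summary optional data.frame of per-cast fraction peaks.
#' @param seed seed recorded in the report.
#' @return list of class `foodweb_report`.
#' @export
build_report <- function(census, groups, guilds, aa_contrasts = NULL,
                         lisst_summary = NULL, seed = NA_integer_) {
  rep <- list(seed = seed,
              census = as.data.frame(census),
              census_threshold = attr(census, "threshold"),
              groups = groups$groups,
              n_groups_large_over_half = groups$n_groups_large_over_half,
              guilds = guilds)
  if (!is.null(aa_contrasts) && length(aa_contrasts)) {
    rep$aa_contrasts <- do.call(rbind, lapply(aa_contrasts, function(a) {
      data.frame(fraction = a$fraction, F = a$F, df1 = a$df[1],
                 df2 = a$df[2], p = a$p, stringsAsFactors = FALSE)
    }))
  }
  if (!is.null(lisst_summary) && nrow(lisst_summary)) {
    rep$lisst <- lisst_summary
  }
  class(rep) <- "foodweb_report"
  rep
}

#' @export
format.foodweb_report <- function(x, ...) {
  lines <- c("# Midwater food-web report",
             sprintf("seed: %s", x$seed), "",
             "## Large-particle census")
  for (i in seq_len(nrow(x$census))) {
    r <- x$census[i, ]
    lines <- c(lines, sprintf(
      "- %s: %d of %d consumers (%.1f%%) with pooled >6 um contribution >= %.2f",
      r$stratum, r$count, r$n, r$percent, x$census_threshold))
  }
  lines <- c(lines, "", sprintf(
    "## Group contributions (%d of %d groups with mean >6 um contribution > 0.5)",
    x$n_groups_large_over_half, nrow(x$groups)))
  for (i in seq_len(nrow(x$groups))) {
    g <- x$groups[i, ]
    lines <- c(lines, sprintf("- %s (n=%d): large %.2f +/- %.2f",
                              g$group, g$n, g$mean_large, g$sd_large))
  }
  lines <- c(lines, "", "## Feeding-guild proportions")
  for (i in seq_len(nrow(x$guilds))) {
    g <- x$guilds[i, ]
    lines <- c(lines, sprintf("- %s / %s: %.1f%% (%d taxa)",
                              g$group, g$guild, g$percent, g$n_taxa))
  }
  if (!is.null(x$aa_contrasts)) {
    lines <- c(lines, "", "## Amino-acid concentration contrasts")
    for (i in seq_len(nrow(x$aa_contrasts))) {
      a <- x$aa_contrasts[i, ]
      lines <- c(lines, sprintf(
        "- %s fraction: F(%d,%d) = %.2f, p = %.3f",
        a$fraction, a$df1, a$df2, a$F, a$p))
    }
  }
  paste(lines, collapse = "\n")
}

#' @export
print.foodweb_report <- function(x, ...) {
  cat(format(x), "\n")
  invisible(x)
}
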