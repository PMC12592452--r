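#' Quantify an analyte from its chromatographic peak area
#'
#' Instrument response is calibrated against reference material: the
#' response factor is the ratio of peak area (volt-seconds) to reference
#' size (µg particulate nitrogen for bulk analysis, nmol amino acid for
#' compound-specific runs). A sample's amount is then its peak area
#' divided by the response factor.
#'
#' @param peak_area_vs peak area in volt-seconds (>= 0).
#' @param standard a [calibration_standard()].
#' @return amount in the standard's reference units (µg PN or nmol AA).
#' @export
quantify_by_response_factor <- function(peak_area_vs, standard) {
  stopifnot(inherits(standard, "calibration_standard"))
  if (any(peak_area_vs < 0)) stop("peak area must be non-negative")
  peak_area_vs / standard$response_factor
}

#' Calibration standard for response-factor quantification
#'
#' @param kind `"bulk_N"` (reference size in µg PN) or `"amino_acid"`
#'   (reference size in nmol AA).
#' @param response_factor peak area per reference size (Vs per µg PN or
#'   Vs per nmol AA); must be > 0.
#' @param reference_id label of the reference material.
#' @return object of class `calibration_standard`.
#' @export
calibration_standard <- function(kind = c("bulk_N", "amino_acid"),
                                 response_factor, reference_id = "ref") {
  kind <- match.arg(kind)
  if (!is.numeric(response_factor) || length(response_factor) != 1 ||
      !is.finite(response_factor) || response_factor <= 0) {
    stop("response_factor must be a single positive number")
  }
  structure(list(kind = kind, response_factor = response_factor,
                 reference_id = reference_id),
            class = "calibration_standard")
}

#' Total amino-acid nitrogen normalized to particulate nitrogen
#'
#' Filters are subsampled for the two analyses (e.g. half for bulk
#' elemental analysis, half for compound-specific work), so measured
#' amounts are scaled back to whole-filter values by their subsample
#' fractions before forming the ratio:
#' `(sum(aa) / f_csia) / (bulk_pn / f_bulk)` in ngN/µgPN. Equal subsample
#' fractions cancel, and the ratio is invariant to common rescaling of
#' both fractions.
#'
#' @param aa_amounts_ng per-amino-acid nitrogen amounts measured on the
#'   CSIA subsample (ng N).
#' @param bulk_pn_ug particulate nitrogen measured on the bulk subsample
#'   (µg N); must be > 0.
#' @param subsample_fraction_csia,subsample_fraction_bulk fractions of the
#'   filter used for each analysis, in (0, 1].
#' @return normalized concentration, ngN/µgPN.
#' @export
total_aa_per_pn <- function(aa_amounts_ng, bulk_pn_ug,
                            subsample_fraction_csia = 0.5,
                            subsample_fraction_bulk = 0.5) {
  if (length(aa_amounts_ng) < 1) stop("need at least one amino-acid amount")
  if (bulk_pn_ug <= 0) stop("bulk PN must be positive")
  for (f in c(subsample_fraction_csia, subsample_fraction_bulk)) {
    if (f <= 0 || f > 1) stop("subsample fractions must lie in (0, 1]")
  }
  whole_aa <- sum(aa_amounts_ng) / subsample_fraction_csia
  whole_pn <- bulk_pn_ug / subsample_fraction_bulk
  whole_aa / whole_pn
}

#' Flag outlying concentration records within sample-type x fraction strata
#'
#' Default rule is Tukey's 1.5 x IQR fence applied to `normalized_conc`
#' within each `sample_type` x `size_fraction` stratum — standard and
#' parameter-free. Flagged records are retained in the output with
#' `outlier = TRUE` so downstream summaries can exclude them while keeping
#' the record of what was dropped. Strata with fewer than `min_n` records
#' are skipped with a warning (nothing flagged there).
#'
#' @param records data.frame with `sample_type`, `size_fraction`,
#'   `normalized_conc`.
#' @param rule `"tukey"` or `"none"`.
#' @param k fence multiplier for the Tukey rule.
#' @param min_n minimum stratum size for the rule to apply.
#' @return `records` with a logical `outlier` column.
#' @export
flag_outliers <- function(records, rule = c("tukey", "none"), k = 1.5,
                          min_n = 4) {
  rule <- match.arg(rule)
  records$outlier <- FALSE
  if (rule == "none") return(records)
  strata <- interaction(records$sample_type, records$size_fraction,
                        drop = TRUE)
  for (s in levels(strata)) {
    idx <- which(strata == s)
    if (length(idx) < min_n) {
      warning("stratum ", s, " has fewer than ", min_n,
              " records; outlier rule skipped")
      next
    }
    v <- records$normalized_conc[idx]
    q <- stats::quantile(v, c(0.25, 0.75), names = FALSE, type = 7)
    iqr <- q[2] - q[1]
    records$outlier[idx] <- v < q[1] - k * iqr | v > q[2] + k * iqr
  }
  records
}

#' One-way ANOVA contrast of amino-acid concentration between sample groups
#'
#' Compares normalized amino-acid concentration between background
#' particles and mining plume/discharge particles within one size
#' fraction. By default plume and discharge are pooled into a single
#' comparison group (mirroring how the contrast is framed for material of
#' mining origin); set `pool_plume_discharge = FALSE` for a three-group
#' ANOVA. Concentrations are right-skewed, so a log-transform option is
#' provided; the default is untransformed.
#'
#' @param records data.frame of concentration records (pre-filter with
#'   [flag_outliers()]; rows with `outlier == TRUE` are excluded here).
#' @param fraction size-fraction label to test.
#' @param pool_plume_discharge pool plume + discharge into one group.
#' @param log_transform analyse `log(normalized_conc)`.
#' @return list with `F`, `df` (numerator, denominator), `p`,
#'   `group_means`, `group_n`, and the fraction tested.
#' @export
compare_groups_anova <- function(records, fraction,
                                 pool_plume_discharge = TRUE,
                                 log_transform = FALSE) {
  d <- records[records$size_fraction == fraction, , drop = FALSE]
  if ("outlier" %in% names(d)) d <- d[!d$outlier, , drop = FALSE]
  if (nrow(d) == 0) stop("no records for fraction ", fraction)
  d$grp <- if (pool_plume_discharge) {
    ifelse(d$sample_type == "background", "background", "plume_discharge")
  } else {
    d$sample_type
  }
  tab <- table(d$grp)
  if (length(tab) < 2 || any(tab < 2)) {
    stop("degenerate groups for fraction ", fraction, ": need >= 2 groups ",
         "with >= 2 records each (got ",
         paste(names(tab), tab, sep = "=", collapse = ", "), ")")
  }
  y <- if (log_transform) log(d$normalized_conc) else d$normalized_conc
  fit <- stats::aov(y ~ grp, data = data.frame(y = y, grp = factor(d$grp)))
  an <- stats::anova(fit)
  list(F = an[["F value"]][1],
       df = c(an[["Df"]][1], an[["Df"]][2]),
       p = an[["Pr(>F)"]][1],
       group_means = tapply(y, d$grp, mean),
       group_n = as.vector(tab),
       fraction = fraction)
}
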