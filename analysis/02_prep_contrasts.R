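#!/usr/bin/env Rscript
# Flag outlying amino-acid concentration records (Tukey fence within
# sample-type x fraction strata) and contrast background against pooled
# plume/discharge material per size fraction by one-way ANOVA.

suppressPackageStartupMessages(library(midmix))

seed <- 1L
cfg <- study_config(seed = seed)
recs <- generate_aa_concentration_table(cfg)

# plume/discharge strata (n = 3) are below the fence's minimum size and
# are skipped by design; silence the expected warnings in this driver
recs <- suppressWarnings(flag_outliers(recs))
write.csv(recs, "results/aa_conc_flagged.csv", row.names = FALSE)
cat(sprintf("%d of %d records flagged as outliers\n",
            sum(recs$outlier), nrow(recs)))

contrasts <- lapply(cfg$fractions, function(fr)
  compare_groups_anova(recs, fr))
tab <- do.call(rbind, lapply(contrasts, function(a)
  data.frame(fraction = a$fraction, F = a$F, df1 = a$df[1], df2 = a$df[2],
             p = a$p,
             background_mean = a$group_means[["background"]],
             plume_discharge_mean = a$group_means[["plume_discharge"]])))
tab$p_adj <- p.adjust(tab$p, method = "BH")
write.csv(tab, "results/aa_contrasts.csv", row.names = FALSE)

for (i in seq_len(nrow(tab))) {
  cat(sprintf(
    "%s fraction: background %.1f vs plume/discharge %.1f ngN/ugPN, F(%d,%d) = %.2f, p = %.4f (BH %.4f)\n",
    tab$fraction[i], tab$background_mean[i], tab$plume_discharge_mean[i],
    tab$df1[i], tab$df2[i], tab$F[i], tab$p[i], tab$p_adj[i]))
}
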