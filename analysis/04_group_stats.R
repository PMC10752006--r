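#!/usr/bin/env Rscript
# Group statistics on the fitted cohort: fixed-effects two-way ANOVA
# (group x day) per metric, day-30 Welch contrasts, and correlation of
# fitted against generative axon volume. Reads the tables written by
# 02_fit_cohort.R (recomputing them if absent).

suppressPackageStartupMessages(library(dbsir))
dir.create("results", showWarnings = FALSE)

if (file.exists("results/cohort_metrics.csv")) {
  tab <- read.csv("results/cohort_metrics.csv")
  truth <- read.csv("results/cohort_ground_truth.csv")
} else {
  spec <- cohort_spec("invivo", days = c(1, 3, 7, 30), n_per_group = 5,
                      snr = 30, seed = 20231213, voxel_dims = c(0.1, 0.1, 1))
  cohort <- simulate_cohort(spec)
  tab <- summarize_cohort(cohort)
  truth <- cohort$truth
}

metrics <- c("fiber_fraction", "restricted_fraction",
             "nonrestricted_fraction", "dbsi_lambda_par", "dbsi_lambda_perp",
             "dti_lambda_par", "dti_lambda_perp", "dti_fa", "axon_volume")
anova_tab <- do.call(rbind, lapply(metrics, function(m)
  cbind(metric = m, two_way_anova(tab, m))))
write.csv(anova_tab, "results/anova.csv", row.names = FALSE)
message("two-way ANOVA (fixed effects; eyes treated as independent):")
print(within(anova_tab, { F <- round(F, 1); p <- signif(p, 2) }),
      row.names = FALSE)

welch <- do.call(rbind, lapply(metrics, function(m) {
  d <- subset(tab, metric == m & day == 30)
  t <- t.test(value ~ group, d)
  data.frame(metric = m,
             sham_mean = mean(d$value[d$group == "sham"]),
             tbi_mean = mean(d$value[d$group == "TBI"]),
             p = t$p.value)
}))
write.csv(welch, "results/welch_day30.csv", row.names = FALSE)

# does the fitted axon volume track the generative one per eye?
f <- subset(tab, metric == "axon_volume")
key <- paste(f$animal, f$eye, f$day)
tr <- subset(truth, metric == "axon_volume")
tr_val <- tr$value[match(key, paste(tr$animal, tr$eye, tr$day))]
corr <- pearson_r2(tr_val, f$value)
write.csv(data.frame(comparison = "fitted_vs_generated_axon_volume",
                     r = corr$r, r2 = corr$r2, p = corr$p, n = corr$n),
          "results/correlations.csv", row.names = FALSE)
message(sprintf("fitted vs generated axon volume: r^2 = %.3f (p = %.2g, n = %d)",
                corr$r2, corr$p, corr$n))
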