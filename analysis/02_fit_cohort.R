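#!/usr/bin/env Rscript
# Invert every simulated nerve voxel with the multi-compartment model
# and the single-tensor comparison fit, average over the metric ROIs,
# and tabulate per-eye metrics plus Table-style group summaries.
# Regenerates the cohort from its seed, so it runs standalone.

suppressPackageStartupMessages(library(dbsir))
dir.create("results", showWarnings = FALSE)

spec <- cohort_spec("invivo", days = c(1, 3, 7, 30), n_per_group = 5,
                    snr = 30, seed = 20231213, voxel_dims = c(0.1, 0.1, 1))
cohort <- simulate_cohort(spec)

t0 <- Sys.time()
tab <- summarize_cohort(cohort)
message("fitted ", length(cohort$nerves), " nerves in ",
        round(as.numeric(Sys.time() - t0, units = "secs"), 1), " s")

write.csv(tab, "results/cohort_metrics.csv", row.names = FALSE)
gs <- group_summary(tab)
write.csv(gs, "results/cohort_summary.csv", row.names = FALSE)

show <- subset(gs, metric %in% c("restricted_fraction", "dbsi_lambda_par",
                                 "dti_lambda_par", "fiber_fraction") &
                 day == 30)
show$mean <- round(show$mean, 3); show$sd <- round(show$sd, 3)
message("day-30 group summaries (fitted):")
print(show, row.names = FALSE)
message("note the TBI drop in dti_lambda_par exceeding the dbsi one: ",
        "the single-tensor fit conflates axon injury with added ",
        "isotropic (cellular) signal")
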