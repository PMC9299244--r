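#!/usr/bin/env Rscript
# Step 4: the four figure archetypes on the synthetic results:
# estimate-vs-SE funnels, fitted systematic-error distributions,
# type 1/2 error bars pre/post calibration, months-to-sensitivity tiles.

suppressMessages(library(vaxeval))
suppressMessages(library(data.table))
suppressMessages(library(ggplot2))

est <- fread("scratch/estimates.csv")
perf <- fread("results/tables/performance.csv")
dir.create("results/figures", showWarnings = FALSE, recursive = TRUE)

sel <- est[look_month == max(look_month, na.rm = TRUE) &
           variant %in% c("age_sex_adj_post_visit", "matched_controls",
                          "ps_weight_visit", "sccs_adj")]
ggsave("results/figures/01_estimates_vs_se.png",
       plot_estimates(sel), width = 9, height = 6, dpi = 120)
ggsave("results/figures/02_systematic_error.png",
       plot_null_distributions(est), width = 12, height = 10, dpi = 120)
ggsave("results/figures/03_type1_type2.png",
       plot_type12(perf), width = 10, height = 7, dpi = 120)
ggsave("results/figures/04_time_to_sensitivity.png",
       plot_time_to_sensitivity(perf), width = 8, height = 10, dpi = 120)
cat("Figures written to results/figures/\n")
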