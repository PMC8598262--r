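#!/usr/bin/env Rscript
# Simulated drug screen: activated microtissues treated across a dose
# range, analyzed like the screen's drug studies — normalization to the
# carrier control, one-way ANOVA with Tukey post hoc, star codes.
# Runs measurement-level (no rendering): the imaging chain is validated in
# 01-03; here the interest is the dose-response statistics at screen scale.

library(microtiss)

seed <- 20260931L
cfg <- generator_config(seed = seed, e_max = 1, ic50 = 1, hill = 1.2)
doses <- c(0, 0.1, 0.3, 1, 3, 10)   # uM; 0 = carrier control
des <- do.call(rbind, lapply(doses, function(d) {
  cohort_design(sprintf("dose_%g", d), 26, activated = TRUE, dose_uM = d,
                timepoint_days = 3)
}))
coh <- generate_cohort(cfg, des, render = FALSE, seed = seed)
meas <- coh$truth
meas$normalized_intensity_per_cell <- meas$true_normalized_intensity

dir.create("results/dose_response", recursive = TRUE, showWarnings = FALSE)
res <- run_stats(meas, metrics = "normalized_intensity_per_cell",
                 control_level = "dose_0",
                 out_dir = "results/dose_response")

per_dose <- do.call(rbind, lapply(split(meas, meas$condition), function(g) {
  ci <- mean_ci95(g$normalized_intensity_per_cell)
  data.frame(condition = g$condition[1], dose_uM = g$dose_uM[1],
             n = nrow(g), mean = ci[["mean"]], ci_low = ci[["low"]],
             ci_high = ci[["high"]])
}))
per_dose <- per_dose[order(per_dose$dose_uM), ]
utils::write.csv(per_dose, "results/dose_response/per_dose_summary.csv",
                 row.names = FALSE)

message("ANOVA across doses:")
print(res[res$test == "anova_oneway",
          c("statistic", "df", "p_value", "stars")])
message("Tukey pairs vs carrier control:")
vs_ctrl <- res[res$test == "tukey_hsd" &
                 (res$group1 == "dose_0" | res$group2 == "dose_0"), ]
print(vs_ctrl[, c("group1", "group2", "statistic", "p_value", "stars")])
message("per-dose means with 95% CI in results/dose_response/")
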