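#!/usr/bin/env Rscript
# Statistical analysis of the quantified cohorts, following the screen's
# battery: 3-SD outlier removal per (metric, group), then
#   activation cohort -> paired t on per-replicate condition means
#   compaction cohort -> volume fold-changes + paired t on droplet areas
#   patient cohort    -> nested t with the patient as the unit of analysis
# Star codes: * p<0.05, ** p<0.01, *** p<0.001, **** p<0.0001.

library(microtiss)

read_meas <- function(cohort) {
  path <- file.path("results", cohort, "measurements.csv")
  if (!file.exists(path)) stop("run analysis/02_quantify.R first")
  utils::read.csv(path, stringsAsFactors = FALSE)
}

message("== activation cohort: marker expression ==")
act <- read_meas("activation")
res_act <- run_stats(act, metrics = c("normalized_intensity_per_cell",
                                      "area_um2"),
                     out_dir = file.path("results", "activation"))
print(res_act[, c("metric", "test", "statistic", "df", "p_value", "stars")])

message("== compaction cohort: volume folds ==")
cmp <- read_meas("compaction")
folds <- vapply(split(cmp$equiv_diameter_um, cmp$condition), function(d) {
  volume_fold_change(300, mean(d))
}, numeric(1))
message(sprintf("volume fold vs 300 um construct: activated %.1f, control %.1f",
                folds[["activated"]], folds[["control"]]))
res_cmp <- run_stats(cmp, metrics = "area_um2",
                     out_dir = file.path("results", "compaction"))
print(res_cmp[, c("metric", "test", "statistic", "df", "p_value", "stars")])
utils::write.csv(data.frame(condition = names(folds),
                            volume_fold = unname(folds)),
                 "results/compaction/volume_folds.csv", row.names = FALSE)

message("== patient cohort: nested t (patients are the unit) ==")
pat <- read_meas("patients")
res_pat <- run_stats(pat, metrics = c("normalized_intensity_per_cell",
                                      "area_um2"),
                     nested = TRUE, out_dir = file.path("results", "patients"))
print(res_pat[, c("metric", "test", "n1", "n2", "statistic", "df",
                  "p_value", "stars")])

message("stats summaries written under results/<cohort>/")
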