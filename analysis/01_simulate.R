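#!/usr/bin/env Rscript
# Simulate the study's synthetic cohorts to disk.
#
# Three cohorts mirror the assay's main experiments:
#   (a) activation:   control vs growth-factor-activated microtissues,
#                     imaged at day 3 (marker staining timepoint)
#   (b) compaction:   the same two arms after two weeks of culture, when
#                     droplet size has plateaued
#   (c) patients:     fibrotic vs control patient lines (4 + 4), exercising
#                     the nested design
# Images (TIFF) land under scratch/ (regenerable bulk data); manifests and
# ground truth CSVs are what downstream steps consume.

library(microtiss)

out_root <- "scratch/analysis"
seed <- 20260928L

message("== (a) activation cohort, day 3 ==")
cfg_act <- generator_config(image_size = 224L, patient_sd = 0, seed = seed)
# three replicate experiments, 12 droplets per arm each (the paired t
# pairs per-replicate condition means)
des_act <- rbind(
  cohort_design("control", 12, activated = FALSE, timepoint_days = 3,
                replicate = 1:3),
  cohort_design("activated", 12, activated = TRUE, timepoint_days = 3,
                replicate = 1:3)
)
run_simulate(cfg_act, des_act, file.path(out_root, "activation"))

message("== (b) compaction cohort, day 14 ==")
cfg_cmp <- generator_config(image_size = 192L, patient_sd = 0, seed = seed + 1L)
des_cmp <- rbind(
  cohort_design("control", 12, activated = FALSE, timepoint_days = 14,
                replicate = 1:3),
  cohort_design("activated", 12, activated = TRUE, timepoint_days = 14,
                replicate = 1:3)
)
run_simulate(cfg_cmp, des_cmp, file.path(out_root, "compaction"))

message("== (c) patient cohort, day 7 ==")
cfg_pat <- generator_config(image_size = 224L, seed = seed + 2L)
des_pat <- rbind(
  cohort_design("ipf", 12, activated = TRUE, timepoint_days = 7,
                patient_id = paste0("IPF-", 1:4)),
  cohort_design("control", 12, activated = FALSE, timepoint_days = 7,
                patient_id = paste0("CTL-", 1:4))
)
run_simulate(cfg_pat, des_pat, file.path(out_root, "patients"))

message("cohorts written under ", out_root)
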