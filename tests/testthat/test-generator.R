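test_that("config validation rejects inconsistent parameters", {
  expect_s3_class(generator_config(), "generator_config")
  expect_error(generator_config(bit_depth = 12), "bit_depth")
  expect_error(generator_config(d_inf_control = 310), "plateau")
  expect_error(generator_config(tau = 0), "tau")
  expect_error(generator_config(live_fraction = 1.2), "live_fraction")
  expect_error(generator_config(hill = 0), "hill")
  expect_error(generator_config(read_sigma = -1), "non-negative")
})

test_that("compaction follows exponential decay to the plateau", {
  cfg <- generator_config()
  # boundary of the decay model
  expect_equal(simulate_compaction(cfg, 0), 300)
  expect_equal(simulate_compaction(cfg, 0, activated = TRUE), 300)
  # closed form at t = tau
  expect_equal(simulate_compaction(cfg, cfg$tau),
               cfg$d_inf_control + (300 - cfg$d_inf_control) / exp(1))
  # long-time limit reaches the plateau implied by the printed volume folds
  d_act <- simulate_compaction(cfg, 1e6, activated = TRUE)
  expect_equal(d_act, cfg$d_inf_activated)
  expect_equal(volume_fold_change(300, d_act), 37, tolerance = 1e-10)
  expect_equal(volume_fold_change(300, simulate_compaction(cfg, 1e6)), 18,
               tolerance = 1e-10)
  # strictly decreasing in t
  t_grid <- seq(0, 20, by = 0.5)
  d_grid <- simulate_compaction(cfg, t_grid, activated = TRUE)
  expect_true(all(diff(d_grid) < 0))
  expect_error(simulate_compaction(cfg, -1), "non-negative")
})

test_that("dose effect is a Hill curve: 1 at zero, 0.5 at IC50, saturating", {
  cfg <- generator_config(e_max = 1, ic50 = 2, hill = 1.5)
  expect_equal(simulate_dose_effect(cfg, 0), 1)
  expect_equal(simulate_dose_effect(cfg, 2), 0.5)
  expect_lt(simulate_dose_effect(cfg, 1e6), 1e-6)
  doses <- c(0, 0.1, 0.5, 1, 2, 5, 20, 100)
  eff <- simulate_dose_effect(cfg, doses)
  expect_true(all(diff(eff) <= 0))
  expect_true(all(eff >= 0 & eff <= 1))
  expect_error(simulate_dose_effect(cfg, -0.1), "non-negative")
})

test_that("rendering is deterministic and respects geometric contracts", {
  cfg <- test_config()
  d <- list(droplet_id = "d1", diameter_um = 120, cell_count = 20)
  a <- render_microtissue(cfg, d, seed = 99)
  b <- render_microtissue(cfg, d, seed = 99)
  expect_identical(a$image$channels, b$image$channels)
  expect_identical(a$truth, b$truth)
  c2 <- render_microtissue(cfg, d, seed = 100)
  expect_false(identical(a$image$channels, c2$image$channels))
  # ground-truth area consistency
  expect_equal(a$truth$true_area_um2, pi * (120 / 2)^2)
  # droplet must fit the field
  expect_error(render_microtissue(cfg, list(droplet_id = "big",
                                            diameter_um = 400,
                                            cell_count = 5)),
               "does not fit")
  # cell packing limit reported with the achievable maximum
  expect_error(render_microtissue(cfg, list(droplet_id = "dense",
                                            diameter_um = 80,
                                            cell_count = 500)),
               "achievable maximum")
})

test_that("zero noise and zero background leave the marker empty outside the disk", {
  cfg <- clean_config()
  out <- render_microtissue(cfg, list(droplet_id = "d", diameter_um = 100,
                                      cell_count = 15), seed = 5)
  n <- cfg$image_size
  rows <- matrix(seq_len(n), n, n); cols <- t(rows)
  # recover the disk from the truth diameter; marker support must be inside
  marker <- out$image$channels$marker
  outside_far <- marker[((rows - n / 2)^2 + (cols - n / 2)^2) >
                          (100 / 2 + 6)^2]
  expect_true(all(outside_far == 0))
})

test_that("live_fraction 1 marks every nucleus live; 0 marks none", {
  cfg <- clean_config(live_fraction = 1)
  out <- render_microtissue(cfg, list(droplet_id = "d", diameter_um = 120,
                                      cell_count = 20), seed = 8)
  expect_equal(out$truth$true_live_fraction, 1)
  # one live blob per nucleus: total live mass ~ n_cells * amp * 2 pi sigma^2
  expect_equal(sum(out$image$channels$live),
               20 * cfg$live_amp * 2 * pi * cfg$nucleus_sigma^2,
               tolerance = 0.01)
  cfg0 <- clean_config(live_fraction = 0)
  out0 <- render_microtissue(cfg0, list(droplet_id = "d", diameter_um = 120,
                                        cell_count = 20), seed = 8)
  expect_equal(out0$truth$true_live_fraction, 0)
  expect_true(all(out0$image$channels$live == 0))
})

test_that("marker signal is conserved: diffuse plus per-cell blob mass", {
  cfg <- clean_config()
  out <- render_microtissue(cfg, list(droplet_id = "d", diameter_um = 110,
                                      cell_count = 18), seed = 13)
  marker <- out$image$channels$marker
  n <- cfg$image_size
  rows <- matrix(seq_len(n), n, n); cols <- t(rows)
  # count disk pixels from the rendered diffuse support
  disk_px <- sum(marker >= cfg$diffuse_base - 0.5)
  expected <- cfg$diffuse_base * disk_px +
    18 * cfg$per_cell_amp * 2 * pi * cfg$marker_sigma^2
  expect_equal(sum(marker), expected, tolerance = 0.01)
})

test_that("cohort generation counts, labels and reproduces exactly", {
  cfg <- test_config()
  des <- rbind(
    cohort_design("control", 30, activated = FALSE, diameter_um = 110),
    cohort_design("activated", 30, activated = TRUE, diameter_um = 110)
  )
  coh <- generate_cohort(cfg, des, render = FALSE, seed = 3)
  expect_equal(nrow(coh$truth), 60)
  expect_equal(sort(unique(coh$truth$condition)), c("activated", "control"))
  expect_equal(nrow(coh$manifest), 60)
  coh2 <- generate_cohort(cfg, des, render = FALSE, seed = 3)
  expect_identical(coh$truth, coh2$truth)
  expect_identical(coh$manifest, coh2$manifest)
  # duplicate droplet ids (identical group rows) are rejected
  expect_error(generate_cohort(cfg, rbind(des, des[1, ]), render = FALSE),
               "duplicate droplet identifiers")
  expect_error(generate_cohort(cfg, des[0, ], render = FALSE), "non-empty")
})

test_that("zero patient SD collapses patient effects to identical true means", {
  cfg <- test_config(patient_sd = 0, marker_cv = 0, size_cv = 0)
  des <- cohort_design("ipf", 5, activated = TRUE, timepoint_days = 3,
                       patient_id = c("P1", "P2", "P3"))
  coh <- generate_cohort(cfg, des, render = FALSE, seed = 4)
  means <- tapply(coh$truth$true_normalized_intensity, coh$truth$patient_id,
                  mean)
  expect_true(max(means) - min(means) < 1e-12)
  # with patient heterogeneity the patient means differ
  cfgp <- test_config(patient_sd = 0.3, marker_cv = 0, size_cv = 0)
  cohp <- generate_cohort(cfgp, des, render = FALSE, seed = 4)
  meansp <- tapply(cohp$truth$true_normalized_intensity,
                   cohp$truth$patient_id, mean)
  expect_gt(max(meansp) - min(meansp), 1e-6)
})

test_that("TIFF round trip preserves every pixel and the manifest layout", {
  cfg <- test_config()
  des <- cohort_design("control", 2, diameter_um = 100)
  out_dir <- withr::local_tempdir()
  coh <- generate_cohort(cfg, des, out_dir = out_dir, seed = 6)
  expect_true(file.exists(file.path(out_dir, "manifest.csv")))
  expect_true(file.exists(file.path(out_dir, "ground_truth.csv")))
  man <- utils::read.csv(file.path(out_dir, "manifest.csv"))
  expect_true(all(file.exists(man$image_path)))
  img <- read_microtissue_tiff(man$image_path[1], man$channel_map[1],
                               pixel_size = man$pixel_size[1],
                               bit_depth = man$bit_depth[1])
  expect_equal(img$channels$marker, coh$images[[1]]$channels$marker,
               ignore_attr = TRUE)
  expect_equal(img$channels$nuclei, coh$images[[1]]$channels$nuclei,
               ignore_attr = TRUE)
})
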