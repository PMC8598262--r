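test_that("preprocess removes constant and planar backgrounds", {
  # constant image: background subtraction leaves zeros, warning (no contrast)
  const <- matrix(7, 64, 64)
  expect_warning(out <- preprocess(const), "no contrast")
  expect_true(all(out == 0))

  # additive offset invariance: same output with and without the offset
  img <- make_disk(128, radius = 30, height = 100)
  p1 <- preprocess(img)
  p2 <- preprocess(img + 250)
  expect_equal(as.vector(p1), as.vector(p2), tolerance = 1e-8)

  # multiplicative gain invariance (percentile stretch normalizes scale)
  p3 <- preprocess(img * 3.7)
  expect_equal(as.vector(p1), as.vector(p3), tolerance = 1e-8)

  # a disk on a linear ramp: ramp removed within 5% of the disk contrast
  ramp <- outer(rep(1, 128), seq_len(128)) * 0.8
  pr <- preprocess(img + ramp)
  pars <- attr(pr, "preprocess_params")
  corrected <- pr * (pars$stretch_hi - pars$stretch_lo) + pars$stretch_lo
  outside <- make_disk(128, radius = 36, height = 1) == 0
  expect_lt(max(abs(corrected[outside])), 5)
  inside <- make_disk(128, radius = 24, height = 1) > 0
  expect_equal(mean(corrected[inside]), 100, tolerance = 0.05)

  expect_error(preprocess(numeric(0)), "non-empty")
})

test_that("segmentation recovers a noiseless disk's area and shape", {
  img <- make_disk(160, radius = 50, height = 100)
  pre <- preprocess(img)
  masks <- segment_droplets(pre, pixel_size = 1)
  expect_length(masks, 1)
  m <- masks[[1]]
  expect_equal(m$area_um2, pi * 50^2, tolerance = 0.02)
  expect_equal(m$equiv_diameter_um, 100, tolerance = 0.01)
  expect_gt(m$circularity, 0.95)
  expect_lt(m$circularity, 1.05)
  expect_false(m$touches_border)
  expect_equal(unname(m$centroid), c(80, 80), tolerance = 0.01)
  # mask invariants relating pixel and physical units
  expect_equal(m$area_um2, m$area_px * 1^2)
  expect_equal(m$equiv_diameter_um, 2 * sqrt(m$area_um2 / pi))
})

test_that("border-touching droplets are censored by default, flagged otherwise", {
  img <- make_disk(128, radius = 40, height = 100, center = c(5, 64))
  pre <- preprocess(img)
  expect_warning(masks <- segment_droplets(pre, pixel_size = 1),
                 "no droplets")
  expect_length(masks, 0)
  expect_equal(attr(masks, "qc")$removed_border, 1)
  kept <- segment_droplets(pre, pixel_size = 1, exclude_border = FALSE)
  expect_length(kept, 1)
  expect_true(kept[[1]]$touches_border)
})

test_that("small components are treated as debris", {
  img <- make_disk(128, radius = 10, height = 100)  # 314 px < 1000 px
  pre <- preprocess(img)
  expect_warning(masks <- segment_droplets(pre, pixel_size = 1),
                 "no droplets")
  expect_equal(attr(masks, "qc")$removed_small, 1)
  masks2 <- segment_droplets(pre, pixel_size = 1, min_area_px = 100)
  expect_length(masks2, 1)
})

test_that("masks are invariant to global offset and gain", {
  cfg <- test_config()
  out <- render_microtissue(cfg, list(droplet_id = "d", diameter_um = 110,
                                      cell_count = 20), seed = 31)
  ch <- out$image$channels$marker
  area <- function(x) {
    segment_droplets(preprocess(x), pixel_size = 1)[[1]]$area_px
  }
  expect_equal(area(ch), area(ch + 500))
  expect_equal(area(ch), area(ch * 1.8))
})

test_that("nucleus counting is exact on clean scenes and merges close blobs", {
  cfg <- clean_config()
  out <- render_microtissue(cfg, list(droplet_id = "d", diameter_um = 120,
                                      cell_count = 20), seed = 17)
  pre <- preprocess(out$image$channels$marker)
  mask <- segment_droplets(pre, pixel_size = 1)[[1]]
  res <- count_nuclei(out$image$channels$nuclei, mask,
                      sigma = cfg$nucleus_sigma)
  expect_identical(res$count, 20L)
  # centroids land within the mask, close to true nuclei (all inside disk)
  expect_true(all(mask$pixels[res$centroids]))

  # identically zero channel -> zero nuclei
  zero <- matrix(0, 160, 160)
  expect_equal(count_nuclei(zero, mask)$count, 0)

  # two blobs closer than min_sep are merged and counted once
  two <- make_blobs(rbind(c(60, 60), c(60, 65)), n = 128, sigma = 2)
  full <- matrix(TRUE, 128, 128)
  expect_equal(count_nuclei(two, full, sigma = 2, min_sep = 8)$count, 1)
  # ... and counted separately once separated beyond min_sep
  apart <- make_blobs(rbind(c(60, 60), c(60, 80)), n = 128, sigma = 2)
  expect_equal(count_nuclei(apart, full, sigma = 2, min_sep = 8)$count, 2)

  expect_error(count_nuclei(zero, matrix(FALSE, 128, 128)), "empty")
})

test_that("viability classification handles bright, dark and degenerate droplets", {
  centroids <- rbind(c(40, 40), c(40, 60), c(60, 40), c(60, 60))
  # slightly uneven staining: bright but not all-equal per-cell means
  bright <- make_blobs(centroids, n = 100, sigma = 2, amp = 5000) +
    make_blobs(centroids[1:2, , drop = FALSE], n = 100, sigma = 2, amp = 400)
  res <- classify_viability(bright, centroids)
  expect_equal(res$fraction, 1)
  expect_equal(res$live + (res$total - res$live), res$total)

  # identically zero live channel -> fraction 0 with fallback warning
  expect_warning(res0 <- classify_viability(matrix(0, 100, 100), centroids),
                 "fixed threshold")
  expect_equal(res0$fraction, 0)

  # genuinely mixed droplet: 3 live, 1 dark
  mixed <- make_blobs(centroids[1:3, , drop = FALSE], n = 100, sigma = 2,
                      amp = 5000)
  resm <- classify_viability(mixed + 50, centroids)
  expect_equal(resm$live, 3)
  expect_equal(resm$fraction, 0.75)

  expect_error(classify_viability(bright, centroids[0, , drop = FALSE]),
               "centroid")
})
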