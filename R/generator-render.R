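#' Construct a multi-channel microtissue image
#'
#' Container for one field of view: named channel matrices sharing one shape,
#' plus acquisition and experimental metadata.
#'
#' @param channels Named list of numeric matrices (e.g. `nuclei`, `marker`,
#'   `live`), all with identical dimensions.
#' @param pixel_size Physical pixel size, um/px.
#' @param bit_depth 8 or 16; pixel values must lie in `[0, 2^bit_depth - 1]`.
#' @param metadata Named list of experimental labels (condition, dose_uM,
#'   timepoint_days, patient_id, replicate, droplet_id).
#' @return An object of class `microtissue_image`.
#' @export
microtissue_image <- function(channels, pixel_size, bit_depth = 16L,
                              metadata = list()) {
  if (length(channels) == 0 || is.null(names(channels)) ||
      any(!nzchar(names(channels)))) {
    stop("channels must be a non-empty named list", call. = FALSE)
  }
  dims <- lapply(channels, dim)
  if (any(vapply(dims, is.null, logical(1))) ||
      length(unique(vapply(dims, paste, character(1), collapse = "x"))) != 1) {
    stop("all channels must be 2D arrays of one shape", call. = FALSE)
  }
  top <- 2^bit_depth - 1
  rng <- range(unlist(lapply(channels, range)))
  if (rng[1] < 0 || rng[2] > top) {
    stop("pixel values outside [0, 2^bit_depth - 1]", call. = FALSE)
  }
  if (pixel_size <= 0) stop("pixel_size must be positive", call. = FALSE)
  structure(list(channels = channels, pixel_size = pixel_size,
                 bit_depth = as.integer(bit_depth), metadata = metadata),
            class = "microtissue_image")
}

#' @export
print.microtissue_image <- function(x, ...) {
  d <- dim(x$channels[[1]])
  cat(sprintf("microtissue_image: %d x %d px, %d-bit, channels: %s\n",
              d[1], d[2], x$bit_depth, paste(names(x$channels),
                                             collapse = ", ")))
  if (!is.null(x$metadata$droplet_id)) {
    cat("  droplet:", x$metadata$droplet_id, "\n")
  }
  invisible(x)
}

# Add isotropic Gaussian blobs (peak `amp`, width `sigma`) at the given
# (row, col) centers. Each blob is rendered on a +/- 4 sigma window, so its
# support is strictly bounded.
add_blobs <- function(mat, centers, sigma, amp) {
  if (nrow(centers) == 0) return(mat)
  w <- ceiling(4 * sigma)
  n <- nrow(mat); m <- ncol(mat)
  for (k in seq_len(nrow(centers))) {
    r0 <- centers[k, 1]; c0 <- centers[k, 2]
    rs <- max(1, floor(r0 - w)):min(n, ceiling(r0 + w))
    cs <- max(1, floor(c0 - w)):min(m, ceiling(c0 + w))
    g <- amp * exp(-outer((rs - r0)^2, (cs - c0)^2, "+") / (2 * sigma^2))
    mat[rs, cs] <- mat[rs, cs] + g
  }
  mat
}

# Random sequential placement of cell centers inside a disk with a minimum
# pairwise separation. Hard-core packing jams well below hexagonal density,
# so the achievable count is capped conservatively.
max_packable_cells <- function(r_place, min_sep) {
  if (r_place <= 0) return(0L)
  as.integer(floor(0.45 * (r_place / (min_sep / 2))^2))
}

place_cells <- function(n_cells, center, r_place, min_sep) {
  if (n_cells == 0) return(matrix(numeric(0), 0, 2))
  n_max <- max_packable_cells(r_place, min_sep)
  if (n_cells > n_max) {
    stop(sprintf(
      "requested %d cells exceeds the packing limit for this droplet (achievable maximum ~%d)",
      n_cells, n_max), call. = FALSE)
  }
  pts <- matrix(NA_real_, n_cells, 2)
  placed <- 0L
  attempts <- 0L
  max_attempts <- 500L * n_cells
  while (placed < n_cells && attempts < max_attempts) {
    attempts <- attempts + 1L
    # uniform in the disk
    u <- stats::runif(1); th <- stats::runif(1, 0, 2 * pi)
    rr <- r_place * sqrt(u)
    cand <- center + rr * c(cos(th), sin(th))
    ok <- placed == 0L ||
      min((pts[seq_len(placed), 1] - cand[1])^2 +
            (pts[seq_len(placed), 2] - cand[2])^2) >= min_sep^2
    if (ok) {
      placed <- placed + 1L
      pts[placed, ] <- cand
    }
  }
  if (placed < n_cells) {
    stop(sprintf(
      "could not place %d cells at min separation %.3g px (achievable maximum ~%d)",
      n_cells, min_sep, placed), call. = FALSE)
  }
  pts
}

#' Render one synthetic microtissue field of view
#'
#' Draws a disk-shaped collagen region of the requested diameter, places
#' `cell_count` nuclei inside it with a minimum center separation of
#' `4 * nucleus_sigma`, and renders three channels: nuclei (Gaussian blobs
#' of width `nucleus_sigma`), marker (diffuse signal over the disk plus
#' wider cytoplasmic per-cell blobs of width `marker_sigma`, both scaled by
#' the droplet's marker fold and restricted to the disk, so at zero noise
#' and zero background the marker channel is exactly zero outside the
#' tissue), and live stain (blobs at the nuclei sampled live with
#' probability `live_fraction`). An additive background offset and linear
#' gradient are applied to every channel, followed by signal-dependent shot
#' noise plus Gaussian read noise (variance
#' `shot_scale * signal + read_sigma^2`), and clipping to the bit depth.
#' Cell centers are kept far enough inside the disk boundary that nuclear
#' blob support never leaves the disk, keeping the counting ground truth
#' unambiguous.
#'
#' @param config A [generator_config()].
#' @param droplet Named list of per-droplet parameters: `droplet_id`,
#'   `diameter_um`, `cell_count`, and optionally `marker_fold` (default 1),
#'   `live_fraction` (default from config), plus metadata labels
#'   (`condition`, `dose_uM`, `timepoint_days`, `patient_id`, `replicate`).
#' @param seed Integer seed; identical seeds give bit-identical images.
#' @return A list with elements `image` (a [microtissue_image()]) and
#'   `truth` (a one-row data.frame of ground-truth values: true diameter,
#'   area, cell count, marker fold, analytic per-cell normalized intensity,
#'   realized live fraction).
#' @export
render_microtissue <- function(config, droplet, seed = config$seed) {
  validate_generator_config(config)
  need <- c("droplet_id", "diameter_um", "cell_count")
  if (!all(need %in% names(droplet))) {
    stop("droplet must provide droplet_id, diameter_um, cell_count",
         call. = FALSE)
  }
  n <- config$image_size
  px <- config$pixel_size
  sg <- config$nucleus_sigma
  r_px <- droplet$diameter_um / (2 * px)
  if (2 * r_px + 8 > n) {
    stop(sprintf("droplet (%.4g um = %.4g px diameter) does not fit the %d px field with margin",
                 droplet$diameter_um, 2 * r_px, n), call. = FALSE)
  }
  marker_fold <- if (is.null(droplet$marker_fold)) 1 else droplet$marker_fold
  live_fraction <- if (is.null(droplet$live_fraction)) {
    config$live_fraction
  } else {
    droplet$live_fraction
  }

  set.seed(as.integer(seed))
  center <- n / 2 + stats::runif(2, -0.02, 0.02) * n

  # blob windows are +/- 4 sigma squares; keep their corners inside the disk
  margin <- ceiling(4 * sg * sqrt(2))
  r_place <- r_px - margin
  cells <- place_cells(droplet$cell_count, center, r_place, 4 * sg)

  rows <- matrix(seq_len(n), n, n)
  cols <- t(rows)
  disk <- ((rows - center[1])^2 + (cols - center[2])^2) <= r_px^2

  zero <- matrix(0, n, n)
  nuclei <- add_blobs(zero, cells, sg, config$nucleus_amp)
  marker <- marker_fold * disk *
    (config$diffuse_base +
       add_blobs(zero, cells, config$marker_sigma, config$per_cell_amp))
  live_flags <- if (droplet$cell_count > 0) {
    stats::rbinom(droplet$cell_count, 1, live_fraction) == 1
  } else {
    logical(0)
  }
  live <- add_blobs(zero, cells[live_flags, , drop = FALSE], sg,
                    config$live_amp)

  bg <- config$bg_offset + config$bg_gradient * (cols - 1)
  channels <- list(nuclei = nuclei + bg, marker = marker + bg,
                   live = live + bg)

  top <- 2^config$bit_depth - 1
  clipped <- 0L
  channels <- lapply(channels, function(x) {
    if (config$shot_scale > 0 || config$read_sigma > 0) {
      x <- x + stats::rnorm(length(x),
                            sd = sqrt(config$shot_scale * pmax(x, 0) +
                                        config$read_sigma^2))
    }
    clipped <<- clipped + sum(x > top)
    round(pmin(pmax(x, 0), top))
  })
  if (clipped > 0) {
    warning(sprintf("%d pixels clipped at the %d-bit ceiling", clipped,
                    config$bit_depth), call. = FALSE)
  }

  meta <- droplet[intersect(names(droplet),
                            c("droplet_id", "condition", "dose_uM",
                              "timepoint_days", "patient_id", "replicate"))]
  img <- microtissue_image(channels, pixel_size = px,
                           bit_depth = config$bit_depth, metadata = meta)

  # Analytic expectation of the per-cell normalized intensity readout:
  # (mean - p10) over the disk is driven by the per-cell blob mass
  # (amp * 2 * pi * marker_sigma^2 per cell over pi * r^2 pixels).
  true_norm <- marker_fold * config$per_cell_amp *
    2 * config$marker_sigma^2 / r_px^2
  truth <- data.frame(
    droplet_id = droplet$droplet_id,
    condition = meta$condition %||% NA_character_,
    dose_uM = meta$dose_uM %||% NA_real_,
    timepoint_days = meta$timepoint_days %||% NA_real_,
    patient_id = meta$patient_id %||% NA_character_,
    replicate = meta$replicate %||% NA_integer_,
    true_equiv_diameter_um = droplet$diameter_um,
    true_area_um2 = pi * (droplet$diameter_um / 2)^2,
    true_cell_count = as.integer(droplet$cell_count),
    true_marker_fold = marker_fold,
    true_normalized_intensity = true_norm,
    true_live_fraction = if (droplet$cell_count > 0) mean(live_flags) else NA_real_,
    seed = as.integer(seed),
    stringsAsFactors = FALSE
  )
  list(image = img, truth = truth)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
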