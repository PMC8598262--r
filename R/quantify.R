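#' Mean fluorescence intensity across a microtissue
#'
#' Arithmetic mean of the raw marker pixels inside the mask. Computed on the
#' unstretched channel: quantification must not depend on display-oriented
#' rescaling.
#'
#' @param marker Raw 2D matrix.
#' @param mask A `droplet_mask` or logical matrix.
#' @return Mean intensity, camera units.
#' @export
mean_intensity <- function(marker, mask) {
  pix <- if (inherits(mask, "droplet_mask")) mask$pixels else mask
  if (!any(pix)) stop("mask is empty", call. = FALSE)
  mean(marker[pix])
}

#' Per-construct background: tenth percentile of in-mask intensity
#'
#' The background fluorescence of each microtissue is taken as the 10th
#' percentile of its own in-mask pixel values (linear-interpolation
#' percentile convention, R type 7).
#'
#' @inheritParams mean_intensity
#' @return 10th-percentile intensity, camera units. Masks under 10 px are
#'   flagged with a warning but still computed.
#' @export
background_p10 <- function(marker, mask) {
  pix <- if (inherits(mask, "droplet_mask")) mask$pixels else mask
  if (!any(pix)) stop("mask is empty", call. = FALSE)
  if (sum(pix) < 10) {
    warning("mask smaller than 10 px; percentile is poorly determined",
            call. = FALSE)
  }
  stats::quantile(marker[pix], 0.10, names = FALSE, type = 7)
}

#' Background-subtracted mean intensity per cell
#'
#' `(mean - p10) / cell_count`, floored at zero (signal is physically
#' non-negative) with a QC flag when the mean falls below the background
#' percentile.
#'
#' @param mean_value Mean in-mask intensity.
#' @param p10 In-mask 10th-percentile background.
#' @param cell_count Nuclear count, >= 1.
#' @return Numeric value with attribute `qc_flag` (`"negative_floored"` or
#'   `NULL`).
#' @export
normalized_intensity_per_cell <- function(mean_value, p10, cell_count) {
  if (cell_count < 1) {
    stop("cell_count must be >= 1; zero-cell droplets are excluded from intensity statistics",
         call. = FALSE)
  }
  v <- (mean_value - p10) / cell_count
  if (v < 0) {
    v <- 0
    attr(v, "qc_flag") <- "negative_floored"
  }
  v
}

#' Volume fold-change of a compacting droplet
#'
#' Treats the microtissue as a sphere whose diameter is the projected-area
#' equivalent diameter: fold = `(d0 / d)^3`.
#'
#' @param d0 Starting equivalent diameter, um.
#' @param d Current equivalent diameter, um.
#' @return Unitless fold (>= 1 when `d <= d0`).
#' @export
volume_fold_change <- function(d0, d) {
  if (any(d0 <= 0) || any(d <= 0)) {
    stop("diameters must be positive", call. = FALSE)
  }
  (d0 / d)^3
}

#' Normalize a secreted-protein concentration to the cultured cell number
#'
#' @param concentration Mass/volume (e.g. ng/mL).
#' @param media_volume Culture volume in the same volume unit (e.g. mL).
#' @param cell_count Number of cells in the well, >= 1.
#' @return Mass per cell.
#' @export
normalize_secreted_protein <- function(concentration, media_volume,
                                       cell_count) {
  if (any(concentration < 0) || any(media_volume < 0)) {
    stop("concentration and volume must be non-negative", call. = FALSE)
  }
  if (any(cell_count < 1)) stop("cell_count must be >= 1", call. = FALSE)
  concentration * media_volume / cell_count
}

#' Cells required for a collagen batch
#'
#' @param collagen_volume_uL Collagen volume in uL.
#' @param seeding_density Cells per mL of collagen.
#' @return Cell count.
#' @export
batch_cell_requirement <- function(collagen_volume_uL, seeding_density) {
  if (any(collagen_volume_uL <= 0) || any(seeding_density <= 0)) {
    stop("volume and density must be positive", call. = FALSE)
  }
  collagen_volume_uL / 1000 * seeding_density
}

cohort_table_columns <- c(
  "droplet_id", "condition", "dose_uM", "timepoint_days", "patient_id",
  "replicate", "area_um2", "equiv_diameter_um", "cell_count",
  "mean_intensity", "background_p10", "normalized_intensity_per_cell",
  "live_fraction", "qc_flags"
)

#' Assemble per-droplet measurements into a validated cohort table
#'
#' Long format, one row per droplet. When a ground-truth table is supplied
#' (synthetic cohorts), it is joined by `droplet_id` for recovery analyses;
#' every measured droplet must have a ground-truth row.
#'
#' @param measurements data.frame of per-droplet measurement rows.
#' @param ground_truth Optional ground-truth data.frame with `droplet_id`.
#' @return data.frame of class `cohort_table` with the canonical column
#'   order (empty input yields an empty table with the schema intact).
#' @export
build_cohort_table <- function(measurements, ground_truth = NULL) {
  if (is.null(measurements) || nrow(measurements) == 0) {
    empty <- as.data.frame(
      stats::setNames(rep(list(character(0)), length(cohort_table_columns)),
                      cohort_table_columns)
    )
    class(empty) <- c("cohort_table", "data.frame")
    return(empty)
  }
  missing_cols <- setdiff(cohort_table_columns, names(measurements))
  for (col in missing_cols) measurements[[col]] <- NA
  dup <- duplicated(measurements$droplet_id)
  if (any(dup)) {
    stop("duplicate droplet_id in rows: ",
         paste(which(dup), collapse = ", "), call. = FALSE)
  }
  out <- measurements[, c(cohort_table_columns,
                          setdiff(names(measurements),
                                  cohort_table_columns))]
  if (!is.null(ground_truth)) {
    miss <- setdiff(out$droplet_id, ground_truth$droplet_id)
    if (length(miss) > 0) {
      stop("droplet_id missing from ground truth: ",
           paste(miss, collapse = ", "), call. = FALSE)
    }
    gt <- ground_truth[, c("droplet_id",
                           grep("^true_", names(ground_truth), value = TRUE))]
    out <- merge(out, gt, by = "droplet_id", all.x = TRUE, sort = FALSE)
  }
  class(out) <- c("cohort_table", "data.frame")
  out
}

#' Measure one droplet from a multi-channel image
#'
#' Convenience wrapper running the full per-image chain: preprocess the
#' segmentation channel, segment, keep the largest droplet, then compute raw
#' mean intensity, in-mask background percentile, nuclear count, per-cell
#' normalized intensity, and (when a live channel is present) the live
#' fraction.
#'
#' @param image A [microtissue_image()] with at least `nuclei` and `marker`
#'   channels.
#' @param seg_channel Channel used for mask finding (default `"marker"`).
#' @param nucleus_sigma Expected nucleus width in px for blob detection.
#' @param min_area_px Minimum droplet area in px^2.
#' @param viability_radius Sampling radius for live classification, px.
#' @return One-row data.frame (a cohort-table row), or `NULL` with a warning
#'   when no droplet is found.
#' @export
measure_droplet <- function(image, seg_channel = "marker",
                            nucleus_sigma = 2, min_area_px = 1000,
                            viability_radius = 3) {
  stopifnot(inherits(image, "microtissue_image"))
  if (!all(c("nuclei", seg_channel) %in% names(image$channels))) {
    stop("image must carry nuclei and ", seg_channel, " channels",
         call. = FALSE)
  }
  pre <- preprocess(image$channels[[seg_channel]])
  masks <- segment_droplets(pre, pixel_size = image$pixel_size,
                            min_area_px = min_area_px)
  if (length(masks) == 0) {
    warning("no droplet found in ",
            image$metadata$droplet_id %||% "image", call. = FALSE)
    return(NULL)
  }
  qc <- character(0)
  if (length(masks) > 1) qc <- c(qc, "multiple_components_kept_largest")
  mask <- masks[[which.max(vapply(masks, `[[`, numeric(1), "area_px"))]]

  marker <- image$channels$marker
  mi <- mean_intensity(marker, mask)
  p10 <- background_p10(marker, mask)
  nuc <- count_nuclei(image$channels$nuclei, mask, sigma = nucleus_sigma)
  if (nuc$count >= 1) {
    nipc <- normalized_intensity_per_cell(mi, p10, nuc$count)
    if (!is.null(attr(nipc, "qc_flag"))) qc <- c(qc, attr(nipc, "qc_flag"))
    nipc <- as.numeric(nipc)
  } else {
    qc <- c(qc, "zero_cells")
    nipc <- NA_real_
  }
  live_fraction <- NA_real_
  if ("live" %in% names(image$channels) && nuc$count >= 1) {
    via <- classify_viability(image$channels$live, nuc$centroids,
                              radius = viability_radius)
    live_fraction <- via$fraction
  }
  md <- image$metadata
  data.frame(
    droplet_id = md$droplet_id %||% NA_character_,
    condition = md$condition %||% NA_character_,
    dose_uM = md$dose_uM %||% NA_real_,
    timepoint_days = md$timepoint_days %||% NA_real_,
    patient_id = md$patient_id %||% NA_character_,
    replicate = md$replicate %||% NA_integer_,
    area_um2 = mask$area_um2,
    equiv_diameter_um = mask$equiv_diameter_um,
    cell_count = nuc$count,
    mean_intensity = mi,
    background_p10 = p10,
    normalized_intensity_per_cell = nipc,
    live_fraction = live_fraction,
    qc_flags = paste(qc, collapse = ";"),
    stringsAsFactors = FALSE
  )
}
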