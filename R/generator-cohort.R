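#' Build a cohort design table
#'
#' One row per experimental group; `generate_cohort()` expands each row into
#' `n_droplets` droplets. Missing optional columns get the defaults shown.
#'
#' @param condition Character vector of condition labels.
#' @param n_droplets Droplets per group (recycled).
#' @param activated Logical: group receives the activating stimulus
#'   (default `FALSE`).
#' @param dose_uM Drug dose in uM (default 0; attenuates activation via the
#'   Hill model).
#' @param timepoint_days Imaging day (default 3).
#' @param patient_id Cell-source label (default `"P1"`); patients carry a
#'   shared random effect across all their droplets.
#' @param replicate Replicate-experiment index (default 1).
#' @param diameter_um Optional explicit droplet diameter (um) overriding the
#'   compaction model, e.g. for matched-size cohorts that isolate marker
#'   intensity from compaction (default `NA`: use the model).
#' @return A data.frame usable as a `design` argument.
#' @export
cohort_design <- function(condition, n_droplets, activated = FALSE,
                          dose_uM = 0, timepoint_days = 3,
                          patient_id = "P1", replicate = 1L,
                          diameter_um = NA_real_) {
  data.frame(condition = condition, n_droplets = as.integer(n_droplets),
             activated = activated, dose_uM = dose_uM,
             timepoint_days = timepoint_days, patient_id = patient_id,
             replicate = as.integer(replicate), diameter_um = diameter_um,
             stringsAsFactors = FALSE)
}

#' Generate a synthetic cohort of microtissue images with ground truth
#'
#' Expands a design table into per-droplet parameters and renders one image
#' per droplet. Per-patient random effects (lognormal, SD `patient_sd`) are
#' drawn once per patient and multiply the marker amplitude and the
#' compaction depth, so nested (patient-level) analyses can be exercised.
#' Droplet diameters follow the compaction model at each group's timepoint,
#' with fabrication size dispersion `size_cv`; marker folds combine the
#' activation fold, Hill dose attenuation, the patient effect, and
#' droplet-level biological variability `marker_cv`. Per-droplet substream
#' seeding makes any single droplet reproducible independently of the rest.
#'
#' @param config A [generator_config()].
#' @param design A data.frame as from [cohort_design()]; must be non-empty
#'   with columns `condition` and `n_droplets`.
#' @param out_dir Optional directory; when given, multi-page TIFFs plus
#'   `manifest.csv` and `ground_truth.csv` are written there.
#' @param render If `FALSE`, skip image rendering and return ground truth
#'   only (fast path for statistical simulations).
#' @param seed Master seed (default from config).
#' @return List with `images` (named list of [microtissue_image()], or
#'   `NULL` when `render = FALSE`), `truth` (ground-truth data.frame) and
#'   `manifest` (data.frame; `image_path` filled only when written).
#' @export
generate_cohort <- function(config, design, out_dir = NULL, render = TRUE,
                            seed = config$seed) {
  validate_generator_config(config)
  if (!is.data.frame(design) || nrow(design) == 0) {
    stop("design must be a non-empty data.frame", call. = FALSE)
  }
  if (!all(c("condition", "n_droplets") %in% names(design))) {
    stop("design needs columns condition and n_droplets", call. = FALSE)
  }
  design$activated <- if (is.null(design$activated)) FALSE else design$activated
  design$dose_uM <- if (is.null(design$dose_uM)) 0 else design$dose_uM
  design$timepoint_days <- if (is.null(design$timepoint_days)) 3 else design$timepoint_days
  design$patient_id <- if (is.null(design$patient_id)) "P1" else design$patient_id
  design$replicate <- if (is.null(design$replicate)) 1L else design$replicate
  design$diameter_um <- if (is.null(design$diameter_um)) NA_real_ else design$diameter_um

  # one lognormal effect pair per patient, drawn in sorted order for
  # determinism regardless of design row order
  patients <- sort(unique(design$patient_id))
  set.seed(droplet_seed(seed, 0L))
  pe <- data.frame(
    patient_id = patients,
    marker_effect = exp(stats::rnorm(length(patients), 0, config$patient_sd)),
    compaction_effect = exp(stats::rnorm(length(patients), 0,
                                         config$patient_sd)),
    stringsAsFactors = FALSE
  )

  droplets <- list()
  idx <- 0L
  for (g in seq_len(nrow(design))) {
    row <- design[g, ]
    m <- if (isTRUE(row$activated)) {
      simulate_dose_effect(config, row$dose_uM)
    } else {
      0
    }
    p <- pe[pe$patient_id == row$patient_id, ]
    base_fold <- activation_marker_fold(config, m) * p$marker_effect
    d_inf <- activation_d_inf(config, m)
    depth <- (config$droplet_d0 - d_inf) * p$compaction_effect
    d_inf_p <- max(config$droplet_d0 - depth, 0.05 * config$droplet_d0)
    d_t <- if (!is.na(row$diameter_um)) {
      row$diameter_um
    } else {
      simulate_compaction(config, row$timepoint_days, d_inf = d_inf_p)
    }
    for (i in seq_len(row$n_droplets)) {
      idx <- idx + 1L
      set.seed(droplet_seed(seed, 2L * idx))
      diameter <- d_t * exp(stats::rnorm(1, 0, config$size_cv))
      fold <- base_fold * exp(stats::rnorm(1, 0, config$marker_cv))
      count <- max(1L, stats::rnbinom(1, mu = config$cells_mean,
                                      size = config$cells_dispersion))
      r_place <- diameter / (2 * config$pixel_size) -
        ceiling(4 * config$nucleus_sigma * sqrt(2))
      n_max <- max_packable_cells(r_place, 4 * config$nucleus_sigma)
      capped <- count > n_max
      if (capped) count <- n_max
      droplets[[idx]] <- list(
        droplet_id = sprintf("%s_t%g_%s_r%d_%03d", row$condition,
                             row$timepoint_days, row$patient_id,
                             row$replicate, i),
        condition = row$condition, dose_uM = row$dose_uM,
        timepoint_days = row$timepoint_days, patient_id = row$patient_id,
        replicate = row$replicate, diameter_um = diameter,
        cell_count = count, marker_fold = fold,
        live_fraction = config$live_fraction,
        count_capped = capped,
        render_seed = droplet_seed(seed, 2L * idx + 1L)
      )
    }
  }

  ids <- vapply(droplets, `[[`, character(1), "droplet_id")
  if (anyDuplicated(ids)) {
    stop("duplicate droplet identifiers in design: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  }

  images <- if (render) vector("list", length(droplets)) else NULL
  truth <- vector("list", length(droplets))
  for (k in seq_along(droplets)) {
    d <- droplets[[k]]
    if (render) {
      out <- render_microtissue(config, d, seed = d$render_seed)
      images[[k]] <- out$image
      truth[[k]] <- out$truth
    } else {
      truth[[k]] <- data.frame(
        droplet_id = d$droplet_id, condition = d$condition,
        dose_uM = d$dose_uM, timepoint_days = d$timepoint_days,
        patient_id = d$patient_id, replicate = d$replicate,
        true_equiv_diameter_um = d$diameter_um,
        true_area_um2 = pi * (d$diameter_um / 2)^2,
        true_cell_count = as.integer(d$cell_count),
        true_marker_fold = d$marker_fold,
        true_normalized_intensity = d$marker_fold * config$per_cell_amp *
          2 * config$marker_sigma^2 /
          (d$diameter_um / (2 * config$pixel_size))^2,
        true_live_fraction = config$live_fraction,
        seed = d$render_seed, stringsAsFactors = FALSE
      )
    }
    truth[[k]]$count_capped <- d$count_capped
  }
  truth <- do.call(rbind, truth)
  if (render) names(images) <- ids

  manifest <- data.frame(
    image_path = NA_character_, droplet_id = ids,
    condition = truth$condition, dose_uM = truth$dose_uM,
    timepoint_days = truth$timepoint_days, patient_id = truth$patient_id,
    replicate = truth$replicate,
    channel_map = "nuclei=1;marker=2;live=3",
    pixel_size = config$pixel_size, bit_depth = config$bit_depth,
    stringsAsFactors = FALSE
  )

  if (!is.null(out_dir)) {
    if (!render) stop("out_dir requires render = TRUE", call. = FALSE)
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    manifest$image_path <- file.path(out_dir, paste0(ids, ".tif"))
    for (k in seq_along(images)) {
      write_microtissue_tiff(images[[k]], manifest$image_path[k])
    }
    utils::write.csv(manifest, file.path(out_dir, "manifest.csv"),
                     row.names = FALSE)
    utils::write.csv(truth, file.path(out_dir, "ground_truth.csv"),
                     row.names = FALSE)
  }

  list(images = images, truth = truth, manifest = manifest)
}

#' Write a microtissue image as a multi-page TIFF
#'
#' One page per channel, in the order given by the image's channel list.
#'
#' @param image A [microtissue_image()].
#' @param path Output file path.
#' @return The path, invisibly.
#' @export
write_microtissue_tiff <- function(image, path) {
  stopifnot(inherits(image, "microtissue_image"))
  top <- 2^image$bit_depth - 1
  pages <- lapply(image$channels, function(ch) ch / top)
  tiff::writeTIFF(pages, path, bits.per.sample = image$bit_depth)
  invisible(path)
}

#' Read a multi-page TIFF back into a microtissue image
#'
#' @param path TIFF file path.
#' @param channel_map Either a named integer vector (`c(nuclei = 1, ...)`) or
#'   a manifest-style string `"nuclei=1;marker=2;live=3"`.
#' @param pixel_size Physical pixel size, um/px.
#' @param bit_depth Camera bit depth used when the file was written.
#' @param metadata Optional metadata list.
#' @return A [microtissue_image()].
#' @export
read_microtissue_tiff <- function(path, channel_map, pixel_size,
                                  bit_depth = 16L, metadata = list()) {
  if (!file.exists(path)) stop("image file not found: ", path, call. = FALSE)
  if (is.character(channel_map) && length(channel_map) == 1) {
    parts <- strsplit(strsplit(channel_map, ";")[[1]], "=")
    channel_map <- stats::setNames(
      as.integer(vapply(parts, `[`, character(1), 2)),
      vapply(parts, `[`, character(1), 1)
    )
  }
  pages <- tiff::readTIFF(path, all = TRUE)
  top <- 2^bit_depth - 1
  channels <- lapply(channel_map, function(i) round(pages[[i]] * top))
  microtissue_image(channels, pixel_size = pixel_size,
                    bit_depth = bit_depth, metadata = metadata)
}
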