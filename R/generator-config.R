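#' Configuration for the synthetic microtissue generator
#'
#' Builds and validates the parameter set that drives synthetic image and
#' cohort generation. Defaults encode the assay conditions the generator
#' emulates: collagen droplets fabricated at 300 um diameter seeded with
#' roughly 10-40 fibroblasts each, which compact over days of culture toward
#' a plateau diameter. Plateau diameters default to the values implied by the
#' assay's volume fold-changes: a 37-fold volume reduction for growth-factor
#' activated tissues and an 18-fold reduction for controls, obtained by
#' inverting (d0/d)^3 = fold.
#'
#' @param image_size Square field-of-view side, pixels.
#' @param pixel_size Physical pixel size, um/px.
#' @param bit_depth Camera bit depth, 8 or 16.
#' @param droplet_d0 Equivalent diameter at fabrication, um.
#' @param d_inf_control,d_inf_activated Plateau diameters (um) for control and
#'   activated tissues; both must be below `droplet_d0`.
#' @param tau Compaction time constant, days.
#' @param cells_mean,cells_dispersion Mean and negative-binomial size of the
#'   per-droplet cell-count distribution (`cells_dispersion = Inf` gives
#'   Poisson-like counts; larger values mean less overdispersion).
#' @param nucleus_sigma Gaussian width of a rendered nucleus, px.
#' @param nucleus_amp Peak intensity of a nucleus blob, camera units.
#' @param marker_sigma Gaussian width of the per-cell marker (cytoplasmic)
#'   blob, px; wider than a nucleus.
#' @param diffuse_base Diffuse marker intensity over the collagen disk.
#' @param per_cell_amp Peak per-cell marker blob intensity.
#' @param activated_fold Multiplicative marker effect of activation (>= 1).
#' @param live_amp Peak live-stain blob intensity.
#' @param bg_offset Additive background level, camera units.
#' @param bg_gradient Linear background slope, camera units per pixel column.
#' @param shot_scale Signal-dependent (shot) noise scale: variance
#'   contribution `shot_scale * signal`.
#' @param read_sigma Additive Gaussian read-noise SD, camera units.
#' @param e_max,ic50,hill Hill dose-response parameters of drug attenuation
#'   of activation: maximal effect in `[0,1]`, midpoint dose (uM), slope.
#' @param live_fraction True probability that a cell is alive.
#' @param size_cv Droplet-to-droplet fabrication size dispersion
#'   (lognormal CV on diameter).
#' @param marker_cv Droplet-level biological variability of marker amplitude
#'   (lognormal CV).
#' @param patient_sd SD of the lognormal per-patient random effect applied to
#'   marker amplitude and compaction depth.
#' @param seed Master seed; every randomized operation derives its stream
#'   from this.
#'
#' @return A validated list of class `generator_config`.
#' @export
generator_config <- function(image_size = 384L,
                             pixel_size = 1.0,
                             bit_depth = 16L,
                             droplet_d0 = 300,
                             d_inf_control = 300 / 18^(1 / 3),
                             d_inf_activated = 300 / 37^(1 / 3),
                             tau = 2,
                             cells_mean = 25,
                             cells_dispersion = 60,
                             nucleus_sigma = 2,
                             nucleus_amp = 8000,
                             marker_sigma = 5,
                             diffuse_base = 1500,
                             per_cell_amp = 4000,
                             activated_fold = 2.2,
                             live_amp = 6000,
                             bg_offset = 300,
                             bg_gradient = 0.5,
                             shot_scale = 1,
                             read_sigma = 10,
                             e_max = 1,
                             ic50 = 1,
                             hill = 1,
                             live_fraction = 0.95,
                             size_cv = 0.05,
                             marker_cv = 0.15,
                             patient_sd = 0.15,
                             seed = 1L) {
  cfg <- list(
    image_size = as.integer(image_size), pixel_size = pixel_size,
    bit_depth = as.integer(bit_depth), droplet_d0 = droplet_d0,
    d_inf_control = d_inf_control, d_inf_activated = d_inf_activated,
    tau = tau, cells_mean = cells_mean, cells_dispersion = cells_dispersion,
    nucleus_sigma = nucleus_sigma, nucleus_amp = nucleus_amp,
    marker_sigma = marker_sigma,
    diffuse_base = diffuse_base, per_cell_amp = per_cell_amp,
    activated_fold = activated_fold, live_amp = live_amp,
    bg_offset = bg_offset, bg_gradient = bg_gradient,
    shot_scale = shot_scale, read_sigma = read_sigma,
    e_max = e_max, ic50 = ic50, hill = hill,
    live_fraction = live_fraction, size_cv = size_cv,
    marker_cv = marker_cv, patient_sd = patient_sd,
    seed = as.integer(seed)
  )
  class(cfg) <- "generator_config"
  validate_generator_config(cfg)
  cfg
}

validate_generator_config <- function(cfg) {
  stopifnot(inherits(cfg, "generator_config"))
  if (!cfg$bit_depth %in% c(8L, 16L)) {
    stop("bit_depth must be 8 or 16", call. = FALSE)
  }
  if (cfg$image_size < 16L) stop("image_size too small", call. = FALSE)
  if (cfg$pixel_size <= 0) stop("pixel_size must be positive", call. = FALSE)
  if (cfg$droplet_d0 <= 0) stop("droplet_d0 must be positive", call. = FALSE)
  if (cfg$d_inf_control >= cfg$droplet_d0 ||
      cfg$d_inf_activated >= cfg$droplet_d0) {
    stop("plateau diameters must be below the fabrication diameter",
         call. = FALSE)
  }
  if (cfg$d_inf_control <= 0 || cfg$d_inf_activated <= 0) {
    stop("plateau diameters must be positive", call. = FALSE)
  }
  if (cfg$tau <= 0) stop("tau must be positive", call. = FALSE)
  if (cfg$hill <= 0) stop("hill must be positive", call. = FALSE)
  if (cfg$ic50 <= 0) stop("ic50 must be positive", call. = FALSE)
  if (cfg$e_max < 0 || cfg$e_max > 1) {
    stop("e_max must be in [0, 1]", call. = FALSE)
  }
  if (cfg$live_fraction < 0 || cfg$live_fraction > 1) {
    stop("live_fraction must be in [0, 1]", call. = FALSE)
  }
  if (cfg$activated_fold < 1) {
    stop("activated_fold must be >= 1", call. = FALSE)
  }
  intens <- c(cfg$nucleus_amp, cfg$diffuse_base, cfg$per_cell_amp,
              cfg$live_amp, cfg$bg_offset, cfg$shot_scale, cfg$read_sigma)
  if (any(intens < 0)) {
    stop("intensity and noise parameters must be non-negative", call. = FALSE)
  }
  if (cfg$nucleus_sigma <= 0 || cfg$marker_sigma <= 0) {
    stop("blob widths must be positive", call. = FALSE)
  }
  if (cfg$cells_mean <= 0 || cfg$cells_dispersion <= 0) {
    stop("cell-count parameters must be positive", call. = FALSE)
  }
  invisible(cfg)
}

#' @export
print.generator_config <- function(x, ...) {
  cat("generator_config:",
      sprintf("%d x %d px @ %.3g um/px, %d-bit", x$image_size, x$image_size,
              x$pixel_size, x$bit_depth), "\n")
  cat(sprintf("  d0 %.4g um -> plateau %.4g (control) / %.4g (activated) um, tau %.3g d\n",
              x$droplet_d0, x$d_inf_control, x$d_inf_activated, x$tau))
  cat(sprintf("  cells/droplet ~ NB(mu = %.3g, size = %.3g), activation fold %.3g, live fraction %.3g\n",
              x$cells_mean, x$cells_dispersion, x$activated_fold,
              x$live_fraction))
  invisible(x)
}

# Deterministic per-droplet substream seed: any single droplet of a cohort is
# reproducible without regenerating the rest. Kept below 2^31 - 1.
droplet_seed <- function(master_seed, index) {
  as.integer((as.numeric(master_seed) %% 1048576 * 2039 +
                as.numeric(index) * 7919) %% 2147483629 + 1)
}
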