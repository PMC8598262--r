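#' Compaction kinetics: droplet diameter over culture time
#'
#' Fibroblast-driven compaction is modeled as exponential decay of the
#' equivalent diameter toward a plateau: `d(t) = d_inf + (d0 - d_inf) *
#' exp(-t / tau)`. The plateau `d_inf` depends on whether the tissue is
#' growth-factor activated (activated tissues compact further).
#'
#' @param config A [generator_config()].
#' @param t Culture time in days (vectorized, all >= 0).
#' @param activated Logical; use the activated plateau diameter.
#' @param d_inf Optional explicit plateau diameter (um), overriding the
#'   config's control/activated values (used for drug-attenuated tissues).
#' @return Equivalent diameter(s) in um.
#' @export
simulate_compaction <- function(config, t, activated = FALSE, d_inf = NULL) {
  validate_generator_config(config)
  if (any(t < 0)) stop("culture time t must be non-negative", call. = FALSE)
  if (is.null(d_inf)) {
    d_inf <- if (isTRUE(activated)) config$d_inf_activated else config$d_inf_control
  }
  d_inf + (config$droplet_d0 - d_inf) * exp(-t / config$tau)
}

#' Hill-type drug attenuation of the activated phenotype
#'
#' Returns the residual activation multiplier in `[0, 1]`:
#' `1 - e_max * dose^h / (dose^h + ic50^h)`. At dose 0 the phenotype is fully
#' expressed (multiplier 1); at saturating dose with `e_max = 1` activation is
#' abolished.
#'
#' @param config A [generator_config()].
#' @param dose Drug dose in uM (vectorized, all >= 0).
#' @return Effect multiplier(s) in `[0, 1]`.
#' @export
simulate_dose_effect <- function(config, dose) {
  validate_generator_config(config)
  if (any(dose < 0)) stop("dose must be non-negative", call. = FALSE)
  h <- config$hill
  out <- ifelse(dose == 0, 1,
                1 - config$e_max * dose^h / (dose^h + config$ic50^h))
  unname(out)
}

# Residual-activation multiplier m in [0,1] interpolates the condition
# between control (m = 0) and fully activated (m = 1):
#   marker fold  = 1 + (activated_fold - 1) * m
#   plateau size = d_inf_control - (d_inf_control - d_inf_activated) * m
activation_marker_fold <- function(config, m) {
  1 + (config$activated_fold - 1) * m
}

activation_d_inf <- function(config, m) {
  config$d_inf_control - (config$d_inf_control - config$d_inf_activated) * m
}
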