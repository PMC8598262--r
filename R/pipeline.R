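default_run_config <- function() {
  list(
    manifest = NULL,          # manifest CSV path (quantify input)
    out_dir = "output",       # where tables, QC and config snapshot land
    seed = 1L,
    seg_channel = "marker",
    nucleus_sigma = 2,
    min_area_px = 1000,
    viability_radius = 3,
    metrics = c("area_um2", "normalized_intensity_per_cell"),
    control_level = "control",
    log_level = "info"
  )
}

#' Resolve a run configuration from defaults plus overrides
#'
#' Every parameter has a default; unknown keys are rejected (typo safety).
#' The fully resolved configuration is written as YAML next to the outputs
#' by the run functions.
#'
#' @param overrides Named list, or a path to a YAML file of overrides.
#' @return Resolved configuration list of class `run_config`.
#' @export
run_config <- function(overrides = list()) {
  if (is.character(overrides) && length(overrides) == 1) {
    overrides <- yaml::read_yaml(overrides)
  }
  cfg <- default_run_config()
  unknown <- setdiff(names(overrides), names(cfg))
  if (length(unknown) > 0) {
    stop("unknown config key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  cfg[names(overrides)] <- overrides
  class(cfg) <- "run_config"
  cfg
}

write_config_snapshot <- function(cfg, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  yaml::write_yaml(unclass(cfg)[!vapply(unclass(cfg), is.null, logical(1))],
                   file.path(out_dir, "resolved_config.yaml"))
}

#' Simulate a cohort to disk
#'
#' Thin wrapper over [generate_cohort()]: renders the cohort, writes TIFFs,
#' `manifest.csv` and `ground_truth.csv` under `out_dir`, and snapshots the
#' generator configuration.
#'
#' @param gen_config A [generator_config()].
#' @param design Design table (see [cohort_design()]).
#' @param out_dir Output directory.
#' @param seed Master seed (default from the generator config).
#' @return The [generate_cohort()] result, invisibly.
#' @export
run_simulate <- function(gen_config, design, out_dir,
                         seed = gen_config$seed) {
  res <- generate_cohort(gen_config, design, out_dir = out_dir, seed = seed)
  yaml::write_yaml(unclass(gen_config),
                  file.path(out_dir, "generator_config.yaml"))
  invisible(res)
}

#' Quantify every image in a cohort
#'
#' Runs the full per-image chain ([measure_droplet()]) over a manifest or an
#' in-memory cohort. Unreadable images are skipped and reported in the QC
#' table; the run continues. Deterministic given the inputs and
#' configuration.
#'
#' @param input Either a manifest CSV path, a manifest data.frame (with
#'   `image_path`), or the list returned by [generate_cohort()] (in-memory
#'   images).
#' @param config A [run_config()] (or override list).
#' @param out_dir Optional directory; when given, `measurements.csv`,
#'   `qc_report.csv` and the resolved config snapshot are written.
#' @return List with `measurements` (cohort table) and `qc` (per-image QC
#'   data.frame).
#' @export
run_quantify <- function(input, config = run_config(), out_dir = NULL) {
  if (!inherits(config, "run_config")) config <- run_config(config)
  if (is.character(input) && length(input) == 1) {
    if (!file.exists(input)) stop("manifest not found: ", input, call. = FALSE)
    input <- utils::read.csv(input, stringsAsFactors = FALSE)
  }
  if (is.data.frame(input)) {
    if (nrow(input) == 0) stop("empty manifest", call. = FALSE)
    getter <- function(i) {
      row <- input[i, ]
      if (is.na(row$image_path) || !file.exists(row$image_path)) {
        return(NULL)
      }
      read_microtissue_tiff(
        row$image_path, row$channel_map, pixel_size = row$pixel_size,
        bit_depth = row$bit_depth,
        metadata = as.list(row[c("droplet_id", "condition", "dose_uM",
                                 "timepoint_days", "patient_id",
                                 "replicate")])
      )
    }
    n_items <- nrow(input)
    meta_ids <- input$droplet_id
  } else if (is.list(input) && !is.null(input$images)) {
    images <- input$images
    getter <- function(i) images[[i]]
    n_items <- length(images)
    meta_ids <- names(images)
  } else {
    stop("input must be a manifest path/data.frame or a generated cohort",
         call. = FALSE)
  }

  rows <- list()
  qc <- list()
  for (i in seq_len(n_items)) {
    img <- getter(i)
    if (is.null(img)) {
      qc[[length(qc) + 1L]] <- data.frame(
        droplet_id = meta_ids[i], status = "unreadable_image_skipped",
        stringsAsFactors = FALSE)
      next
    }
    meas <- withCallingHandlers(
      measure_droplet(img, seg_channel = config$seg_channel,
                      nucleus_sigma = config$nucleus_sigma,
                      min_area_px = config$min_area_px,
                      viability_radius = config$viability_radius),
      warning = function(w) {
        qc[[length(qc) + 1L]] <<- data.frame(
          droplet_id = meta_ids[i], status = conditionMessage(w),
          stringsAsFactors = FALSE)
        invokeRestart("muffleWarning")
      }
    )
    if (is.null(meas)) next
    rows[[length(rows) + 1L]] <- meas
  }
  measurements <- build_cohort_table(
    if (length(rows)) do.call(rbind, rows) else NULL
  )
  qc <- if (length(qc)) do.call(rbind, qc) else
    data.frame(droplet_id = character(0), status = character(0))

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(measurements, file.path(out_dir, "measurements.csv"),
                     row.names = FALSE)
    utils::write.csv(qc, file.path(out_dir, "qc_report.csv"),
                     row.names = FALSE)
    write_config_snapshot(config, out_dir)
  }
  list(measurements = measurements, qc = qc)
}

#' Run the statistical battery over a measurement table
#'
#' Applies single-pass 3-SD outlier removal per (metric, condition), then
#' the test battery matching the design: a two-arm study gets a paired t on
#' per-replicate condition means (or a nested t on patient means when
#' `nested = TRUE`); three or more conditions get one-way ANOVA with Tukey
#' post hoc per metric, with every condition also normalized to the control
#' group. P-values are mapped to star codes.
#'
#' @param measurements Cohort table (data.frame).
#' @param metrics Metric column names to analyze.
#' @param control_level Condition label of the control/carrier group
#'   (normalization reference for multi-group designs).
#' @param nested Use the nested (patient-level) t-test for two-arm designs.
#' @param out_dir Optional directory; writes `stats_summary.csv` and
#'   `stats_report.json`.
#' @return data.frame of `StatsResult` rows (one or more per metric), with a
#'   `metric` column.
#' @export
run_stats <- function(measurements, metrics = "normalized_intensity_per_cell",
                      control_level = "control", nested = FALSE,
                      out_dir = NULL) {
  missing_metrics <- setdiff(metrics, names(measurements))
  if (length(missing_metrics) > 0) {
    stop("metric(s) not in measurements: ",
         paste(missing_metrics, collapse = ", "), call. = FALSE)
  }
  if (!"condition" %in% names(measurements)) {
    stop("measurements must carry a condition column", call. = FALSE)
  }
  results <- list()
  for (metric in metrics) {
    df <- measurements[!is.na(measurements[[metric]]), ]
    conditions <- unique(df$condition)
    # outlier filter per (metric, condition), once, before normalization
    kept <- do.call(rbind, lapply(conditions, function(g) {
      sub <- df[df$condition == g, ]
      flt <- remove_outliers(sub[[metric]])
      if (length(flt$removed)) sub <- sub[-flt$removed, ]
      sub
    }))
    if (length(conditions) == 2) {
      res <- if (nested) {
        nested_t_test(kept[[metric]], kept$patient_id, kept$condition)
      } else {
        # pairing unit: the replicate experiment (per-replicate means)
        agg <- stats::aggregate(kept[[metric]],
                                by = list(replicate = kept$replicate,
                                          condition = kept$condition),
                                FUN = mean)
        wide <- split(agg, agg$condition)
        common <- intersect(wide[[1]]$replicate, wide[[2]]$replicate)
        x <- wide[[1]]$x[match(common, wide[[1]]$replicate)]
        y <- wide[[2]]$x[match(common, wide[[2]]$replicate)]
        paired_t_test(x, y, group_names = names(wide))
      }
      res$metric <- metric
      results[[length(results) + 1L]] <- res
    } else if (length(conditions) > 2) {
      kept <- normalize_to_control(kept, metric, control_level)
      groups <- split(kept[[paste0(metric, "_fold")]], kept$condition)
      at <- anova_tukey(groups)
      at$anova$metric <- metric
      at$pairs$metric <- metric
      results[[length(results) + 1L]] <- at$anova
      results[[length(results) + 1L]] <- at$pairs
    } else {
      stop("metric '", metric, "' has fewer than 2 conditions", call. = FALSE)
    }
  }
  out <- do.call(rbind, results)
  rownames(out) <- NULL
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(out, file.path(out_dir, "stats_summary.csv"),
                     row.names = FALSE)
    jsonlite::write_json(out, file.path(out_dir, "stats_report.json"),
                         dataframe = "rows", na = "null", digits = NA,
                         pretty = TRUE)
  }
  out
}

#' Measured-versus-truth recovery report for synthetic cohorts
#'
#' Joins measurements to generator ground truth and summarizes recovery
#' error for projected area, cell count, per-cell normalized intensity, and
#' live fraction, plus per-condition intensity fold-changes
#' (measured vs true).
#'
#' @param measurements Cohort table.
#' @param truth Ground-truth table from [generate_cohort()].
#' @param control_level Condition treated as the fold-change reference.
#' @return List with `per_droplet` (joined table with relative errors) and
#'   `summary` (named numerics: mean relative errors and fold recovery).
#' @export
recovery_report <- function(measurements, truth, control_level = "control") {
  joined <- build_cohort_table(measurements, ground_truth = truth)
  joined$area_rel_err <- joined$area_um2 / joined$true_area_um2 - 1
  joined$count_rel_err <- joined$cell_count / joined$true_cell_count - 1
  joined$intensity_rel_err <- joined$normalized_intensity_per_cell /
    joined$true_normalized_intensity - 1
  conds <- unique(joined$condition)
  fold <- c(measured = NA_real_, true = NA_real_)
  if (control_level %in% conds && length(conds) == 2) {
    other <- setdiff(conds, control_level)
    mfun <- function(col, g) mean(joined[[col]][joined$condition == g],
                                  na.rm = TRUE)
    fold["measured"] <- mfun("normalized_intensity_per_cell", other) /
      mfun("normalized_intensity_per_cell", control_level)
    fold["true"] <- mfun("true_normalized_intensity", other) /
      mfun("true_normalized_intensity", control_level)
  }
  summary <- c(
    mean_abs_area_rel_err = mean(abs(joined$area_rel_err), na.rm = TRUE),
    mean_abs_count_rel_err = mean(abs(joined$count_rel_err), na.rm = TRUE),
    mean_abs_intensity_rel_err = mean(abs(joined$intensity_rel_err),
                                      na.rm = TRUE),
    measured_fold = unname(fold["measured"]),
    true_fold = unname(fold["true"]),
    mean_live_fraction = mean(joined$live_fraction, na.rm = TRUE),
    true_live_fraction = mean(joined$true_live_fraction, na.rm = TRUE)
  )
  list(per_droplet = joined, summary = summary)
}
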