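#' Single-pass 3-SD outlier removal
#'
#' Computes the mean and sample SD (n-1 denominator) of the full input once
#' and drops points more than three SDs above or below the mean. The filter
#' is not re-iterated after removal, and is intended to be applied
#' independently per (metric, group).
#'
#' @param values Numeric vector.
#' @return List with `values` (kept points) and `removed` (integer indices
#'   into the original vector). With fewer than 3 points the filter is
#'   skipped with a warning; zero SD removes nothing.
#' @export
remove_outliers <- function(values) {
  if (length(values) < 3) {
    warning("fewer than 3 values; outlier filter skipped", call. = FALSE)
    return(list(values = values, removed = integer(0)))
  }
  m <- mean(values)
  s <- stats::sd(values)
  if (s == 0) return(list(values = values, removed = integer(0)))
  removed <- which(abs(values - m) > 3 * s)
  list(values = if (length(removed)) values[-removed] else values,
       removed = removed)
}

#' Normalize a metric to a control group's mean, per replicate
#'
#' Divides every droplet's metric by the mean of the designated control
#' group within the same replicate experiment, so the control group's
#' normalized mean is exactly 1 in every replicate. For drug screens the
#' reference is the carrier (e.g. DMSO) control: pass it as `carrier_level`
#' and it takes precedence.
#'
#' @param table A cohort table (data.frame) with the metric and factor
#'   columns.
#' @param metric Name of the metric column.
#' @param control_level Condition label of the control group.
#' @param carrier_level Optional carrier-control label overriding
#'   `control_level`.
#' @param group_col,replicate_col Factor column names.
#' @return The table with an added `<metric>_fold` column.
#' @export
normalize_to_control <- function(table, metric, control_level,
                                 carrier_level = NULL,
                                 group_col = "condition",
                                 replicate_col = "replicate") {
  ref <- if (!is.null(carrier_level)) carrier_level else control_level
  stopifnot(metric %in% names(table), group_col %in% names(table))
  reps <- unique(table[[replicate_col]])
  fold <- rep(NA_real_, nrow(table))
  for (r in reps) {
    in_rep <- table[[replicate_col]] == r
    ctrl <- in_rep & table[[group_col]] == ref
    if (!any(ctrl)) {
      stop("control level '", ref, "' missing in replicate ", r,
           call. = FALSE)
    }
    cm <- mean(table[[metric]][ctrl], na.rm = TRUE)
    if (!is.finite(cm) || cm == 0) {
      stop("control group '", ref, "' has zero or undefined mean in replicate ",
           r, call. = FALSE)
    }
    fold[in_rep] <- table[[metric]][in_rep] / cm
  }
  table[[paste0(metric, "_fold")]] <- fold
  table
}

stats_result <- function(test_name, group1, group2 = NA_character_,
                         n1, n2 = NA_integer_, statistic, df, p_value,
                         ci_low = NA_real_, ci_high = NA_real_,
                         adjusted = FALSE) {
  if (!is.na(p_value) && (p_value < 0 || p_value > 1)) {
    stop("p-value outside [0, 1]", call. = FALSE)
  }
  data.frame(test = test_name, group1 = group1, group2 = group2,
             n1 = n1, n2 = n2, statistic = statistic, df = df,
             p_value = p_value, ci_low = ci_low, ci_high = ci_high,
             adjusted = adjusted, stars = star_code(p_value),
             stringsAsFactors = FALSE)
}

#' Paired Student's t-test
#'
#' Classical paired t on the within-pair differences, two-sided, with the
#' 95% CI of the mean difference. The pairing unit for screen data is the
#' replicate experiment (per-experiment condition means).
#'
#' @param x,y Numeric vectors of equal length, paired by position.
#' @param group_names Labels for the two groups.
#' @return A one-row `StatsResult` data.frame.
#' @export
paired_t_test <- function(x, y, group_names = c("x", "y")) {
  if (length(x) != length(y)) {
    stop("paired samples must have equal length", call. = FALSE)
  }
  if (length(x) < 2) stop("need at least 2 pairs", call. = FALSE)
  d <- x - y
  if (stats::sd(d) == 0) {
    if (mean(d) != 0) {
      stop("paired differences are constant and non-zero; t is undefined",
           call. = FALSE)
    }
    return(stats_result("paired_t", group_names[1], group_names[2],
                        n1 = length(x), n2 = length(y), statistic = 0,
                        df = length(x) - 1, p_value = 1,
                        ci_low = 0, ci_high = 0))
  }
  ht <- stats::t.test(x, y, paired = TRUE)
  stats_result("paired_t", group_names[1], group_names[2],
               n1 = length(x), n2 = length(y),
               statistic = unname(ht$statistic), df = unname(ht$parameter),
               p_value = ht$p.value, ci_low = ht$conf.int[1],
               ci_high = ht$conf.int[2])
}

#' Nested Student's t-test with the patient as the unit of analysis
#'
#' Droplets are technical replicates nested within patients (biological
#' replicates). The test collapses droplet values to per-patient means and
#' runs an equal-variance two-sample Student's t on the patient means — for
#' balanced designs the exact equivalent of the nested mixed model, and
#' immune to droplet-level pseudo-replication by construction. `n` is
#' reported as patient counts.
#'
#' @param values Numeric droplet-level values.
#' @param patient_id Patient label per droplet.
#' @param group Group label per droplet (exactly 2 levels).
#' @return A one-row `StatsResult` data.frame.
#' @export
nested_t_test <- function(values, patient_id, group) {
  stopifnot(length(values) == length(patient_id),
            length(values) == length(group))
  levels <- unique(group)
  if (length(levels) != 2) stop("exactly 2 groups required", call. = FALSE)
  cross <- unique(data.frame(patient_id, group))
  if (anyDuplicated(cross$patient_id)) {
    stop("patient(s) present in both groups: ",
         paste(cross$patient_id[duplicated(cross$patient_id)],
               collapse = ", "), call. = FALSE)
  }
  pm <- stats::aggregate(values,
                         by = list(patient_id = patient_id, group = group),
                         FUN = mean)
  g1 <- pm$x[pm$group == levels[1]]
  g2 <- pm$x[pm$group == levels[2]]
  if (length(g1) < 2 || length(g2) < 2) {
    stop("need at least 2 patients per group", call. = FALSE)
  }
  ht <- stats::t.test(g1, g2, var.equal = TRUE)
  stats_result("nested_t", levels[1], levels[2],
               n1 = length(g1), n2 = length(g2),
               statistic = unname(ht$statistic), df = unname(ht$parameter),
               p_value = ht$p.value, ci_low = ht$conf.int[1],
               ci_high = ht$conf.int[2])
}

#' One-way ANOVA with Tukey HSD post hoc comparisons
#'
#' Fixed-effects one-way ANOVA over the named groups, followed by all
#' pairwise comparisons adjusted via the studentized-range distribution.
#' With exactly two groups the procedure degrades to an equal-variance
#' Student's t-test, with a warning.
#'
#' @param groups Named list of numeric vectors, each of length >= 2.
#' @return List with `anova` (one-row `StatsResult`) and `pairs`
#'   (`StatsResult` rows per pair, `adjusted = TRUE`, CI of the mean
#'   difference at the Tukey family level).
#' @export
anova_tukey <- function(groups) {
  if (is.null(names(groups)) || any(!nzchar(names(groups)))) {
    stop("groups must be a named list", call. = FALSE)
  }
  sizes <- lengths(groups)
  if (any(sizes == 0)) {
    stop("empty group(s): ", paste(names(groups)[sizes == 0], collapse = ", "),
         call. = FALSE)
  }
  if (any(sizes < 2)) {
    stop("every group needs n >= 2", call. = FALSE)
  }
  if (length(groups) < 2) stop("need at least 2 groups", call. = FALSE)
  if (length(groups) == 2) {
    warning("only 2 groups; degrading to a Student's t-test", call. = FALSE)
    ht <- stats::t.test(groups[[1]], groups[[2]], var.equal = TRUE)
    res <- stats_result("student_t", names(groups)[1], names(groups)[2],
                        n1 = sizes[1], n2 = sizes[2],
                        statistic = unname(ht$statistic),
                        df = unname(ht$parameter), p_value = ht$p.value,
                        ci_low = ht$conf.int[1], ci_high = ht$conf.int[2])
    return(list(anova = res, pairs = res))
  }
  df <- data.frame(
    value = unlist(groups, use.names = FALSE),
    group = factor(rep(names(groups), sizes), levels = names(groups))
  )
  fit <- stats::aov(value ~ group, data = df)
  tab <- summary(fit)[[1]]
  an <- stats_result("anova_oneway", paste(names(groups), collapse = "|"),
                     n1 = sum(sizes), statistic = tab$`F value`[1],
                     df = tab$Df[1], p_value = tab$`Pr(>F)`[1])
  tuk <- stats::TukeyHSD(fit)$group
  pair_names <- strsplit(rownames(tuk), "-", fixed = TRUE)
  pairs <- do.call(rbind, lapply(seq_len(nrow(tuk)), function(i) {
    g <- pair_names[[i]]
    stats_result("tukey_hsd", g[1], g[2],
                 n1 = sizes[[g[1]]], n2 = sizes[[g[2]]],
                 statistic = tuk[i, "diff"], df = tab$Df[2],
                 p_value = tuk[i, "p adj"], ci_low = tuk[i, "lwr"],
                 ci_high = tuk[i, "upr"], adjusted = TRUE)
  }))
  list(anova = an, pairs = pairs)
}

#' Mean with its 95% confidence interval
#'
#' `mean +/- t(0.975, n-1) * SD / sqrt(n)`.
#'
#' @param values Numeric vector, n >= 2.
#' @return Named numeric vector `c(mean, low, high)`.
#' @export
mean_ci95 <- function(values) {
  n <- length(values)
  if (n < 2) stop("need at least 2 values for a CI", call. = FALSE)
  m <- mean(values)
  half <- stats::qt(0.975, n - 1) * stats::sd(values) / sqrt(n)
  c(mean = m, low = m - half, high = m + half)
}

#' Significance star codes
#'
#' `ns` for p >= 0.05, then `*` (< 0.05), `**` (< 0.01), `***` (< 0.001),
#' `****` (< 0.0001); boundaries are strict.
#'
#' @param p P-value(s) in `[0, 1]` (NA allowed, mapped to NA).
#' @return Character vector of star codes.
#' @export
star_code <- function(p) {
  if (any(!is.na(p) & (p < 0 | p > 1))) {
    stop("p-value outside [0, 1]", call. = FALSE)
  }
  vapply(p, function(pi) {
    if (is.na(pi)) return(NA_character_)
    if (pi < 1e-4) "****"
    else if (pi < 1e-3) "***"
    else if (pi < 1e-2) "**"
    else if (pi < 0.05) "*"
    else "ns"
  }, character(1))
}
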