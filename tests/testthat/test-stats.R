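test_that("3-SD outlier filter is single-pass and matches enumeration", {
  # {0,0,0,0,100}: mean 20, SD sqrt(2000) ~ 44.7; 80 < 3 SD -> keep all
  res <- remove_outliers(c(0, 0, 0, 0, 100))
  expect_length(res$removed, 0)
  expect_equal(res$values, c(0, 0, 0, 0, 100))

  # a point exceeding 3 SD of the full set (by the filter's own definition)
  # is the only removal
  base <- rep(10, 30)
  x <- c(base, 60)
  stopifnot(abs(60 - mean(x)) > 3 * stats::sd(x))
  res <- remove_outliers(x)
  expect_equal(res$removed, 31L)
  expect_equal(res$values, base)

  # exhaustive check of the criterion on random samples
  set.seed(42)
  for (i in 1:20) {
    x <- stats::rt(40, df = 3) * 10
    res <- remove_outliers(x)
    brute <- which(abs(x - mean(x)) > 3 * stats::sd(x))
    expect_identical(res$removed, brute)
  }

  expect_equal(remove_outliers(rep(4, 10))$removed, integer(0))
  expect_warning(remove_outliers(c(1, 2)), "skipped")
})

test_that("control normalization yields unit control mean per replicate", {
  tab <- data.frame(
    condition = rep(c("ctrl", "drug"), c(3, 2)),
    replicate = 1L,
    y = c(2, 2, 2, 4, 4)
  )
  out <- normalize_to_control(tab, "y", control_level = "ctrl")
  expect_equal(out$y_fold[out$condition == "drug"], c(2, 2))
  expect_equal(mean(out$y_fold[out$condition == "ctrl"]), 1)
  # carrier level takes precedence for drug studies
  tab$condition[1] <- "dmso"
  out2 <- normalize_to_control(tab, "y", control_level = "ctrl",
                               carrier_level = "dmso")
  expect_equal(out2$y_fold, tab$y / 2)
  # missing carrier in a replicate is named explicitly
  tab2 <- rbind(tab, data.frame(condition = "drug", replicate = 2L, y = 1))
  expect_error(normalize_to_control(tab2, "y", control_level = "dmso"),
               "replicate 2")
})

test_that("paired t matches the closed-form oracle", {
  # differences {1,2,3}: t = 2*sqrt(3), df 2, p = 0.0741799
  res <- paired_t_test(c(11, 22, 33), c(10, 20, 30))
  expect_equal(res$statistic, 2 * sqrt(3), tolerance = 1e-10)
  expect_equal(res$df, 2)
  expect_equal(res$p_value, 0.0741799, tolerance = 1e-6)
  expect_equal(res$stars, "ns")
  # identical samples: t = 0, p = 1
  same <- paired_t_test(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$statistic, 0)
  expect_equal(same$p_value, 1)
  # antisymmetric differences
  anti <- paired_t_test(c(5, 5), c(5 + 2, 5 - 2))
  expect_equal(anti$statistic, 0)
  expect_error(paired_t_test(1:3, 1:4), "equal length")
})

test_that("nested t uses patients, not droplets, as the unit of analysis", {
  # patient means {1,2,3} vs {4,5,6}: t = -3.674235, df 4, p = 0.02131
  vals <- c(1, 2, 3, 4, 5, 6)
  pats <- paste0("P", 1:6)
  grp <- rep(c("a", "b"), each = 3)
  res <- nested_t_test(vals, pats, grp)
  expect_equal(res$statistic, -3 / sqrt(2 / 3), tolerance = 1e-10)
  expect_equal(res$df, 4)
  expect_equal(res$p_value, 0.02131164, tolerance = 1e-6)
  expect_equal(res$n1, 3)

  # massive pseudo-replication cannot change the result
  vals_rep <- rep(vals, each = 250)
  pats_rep <- rep(pats, each = 250)
  grp_rep <- rep(grp, each = 250)
  res_rep <- nested_t_test(vals_rep, pats_rep, grp_rep)
  expect_equal(res_rep$statistic, res$statistic)
  expect_equal(res_rep$p_value, res$p_value)
  expect_equal(res_rep$df, 4)  # still patients
  expect_equal(res_rep$n1, 3)

  # identical patient means -> p = 1
  null <- nested_t_test(c(1, 2, 1, 2), paste0("Q", 1:4),
                        rep(c("a", "b"), each = 2))
  expect_equal(null$p_value, 1)

  # a patient cannot sit in both groups
  expect_error(nested_t_test(1:4, c("P1", "P1", "P2", "P2"),
                             c("a", "b", "a", "b")),
               "both groups")
})

test_that("ANOVA + Tukey match the hand-computed reference to 4 decimals", {
  g <- list(a = c(1, 2, 3), b = c(2, 3, 4), c = c(7, 8, 9))
  res <- anova_tukey(g)
  # reference: SSB/SSW computed by enumeration, p from the F and
  # studentized-range distributions
  expect_equal(res$anova$statistic, 31, tolerance = 1e-10)
  expect_equal(res$anova$p_value, 0.000686953, tolerance = 1e-4)
  pr <- res$pairs
  expect_equal(nrow(pr), 3)
  get_p <- function(g1, g2) {
    pr$p_value[(pr$group1 == g1 & pr$group2 == g2) |
                 (pr$group1 == g2 & pr$group2 == g1)]
  }
  expect_equal(get_p("b", "a"), 0.4827273, tolerance = 1e-4)
  expect_equal(get_p("c", "a"), 0.0007942179, tolerance = 1e-4)
  expect_equal(get_p("c", "b"), 0.002101241, tolerance = 1e-4)
  expect_true(all(pr$adjusted))

  # Tukey-adjusted p can only exceed the unadjusted pairwise comparison on
  # the same pooled error (MSE, N - k df)
  mse <- sum(vapply(g, function(x) sum((x - mean(x))^2), numeric(1))) / 6
  for (pair in list(c("a", "b"), c("a", "c"), c("b", "c"))) {
    tstat <- abs(mean(g[[pair[1]]]) - mean(g[[pair[2]]])) /
      sqrt(mse * (1 / 3 + 1 / 3))
    raw <- 2 * stats::pt(-tstat, 6)
    expect_gte(get_p(pair[1], pair[2]) + 1e-12, raw)
  }

  # identical groups: F ~ 0, adjusted p ~ 1
  same <- anova_tukey(list(a = c(1, 2, 3), b = c(1, 2, 3), c = c(1, 2, 3)))
  expect_lt(same$anova$statistic, 1e-10)
  expect_true(all(same$pairs$p_value > 0.999))

  expect_warning(two <- anova_tukey(list(a = 1:3, b = 4:6)), "t-test")
  expect_equal(two$anova$test, "student_t")
  expect_error(anova_tukey(list(a = 1:3, b = numeric(0))), "empty")
})

test_that("95% CI matches the t-quantile oracle and contains the mean", {
  ci <- mean_ci95(1:5)
  expect_equal(unname(ci), c(3, 1.036757, 4.963243), tolerance = 1e-6)
  const <- mean_ci95(rep(2, 8))
  expect_equal(unname(const), c(2, 2, 2))
  # width shrinks as 1/sqrt(n)
  set.seed(1)
  x <- stats::rnorm(400)
  w1 <- diff(mean_ci95(x[1:100])[c("low", "high")])
  w2 <- diff(mean_ci95(x)[c("low", "high")])
  expect_equal(unname(w2 / w1), 0.5, tolerance = 0.25)
  expect_error(mean_ci95(1), "at least 2")
})

test_that("star codes follow the strict-inequality mapping", {
  expect_equal(star_code(0.04), "*")
  expect_equal(star_code(0.05), "ns")
  expect_equal(star_code(5e-5), "****")
  expect_equal(star_code(c(0.2, 0.009, 0.0009, 0.00009, 1e-4, 1e-3, 1e-2)),
               c("ns", "**", "***", "****", "***", "**", "*"))
  expect_error(star_code(1.5), "\\[0, 1\\]")
  expect_error(star_code(-0.1), "\\[0, 1\\]")
})
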