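test_that("one-way ANOVA matches hand-computed sums of squares", {
  # {1,2,3}, {4,5,6}, {7,8,9}: SSB = 54 (df 2), SSW = 6 (df 6), F = 27
  res <- anova_oneway(list(1:3, 4:6, 7:9))
  expect_equal(res$F, 27, tolerance = 1e-12)
  expect_equal(res$df_between, 2)
  expect_equal(res$df_within, 6)
  expect_equal(res$p, stats::pf(27, 2, 6, lower.tail = FALSE), tolerance = 1e-12)
  expect_equal(unname(res$group_means), c(2, 5, 8))

  ident <- anova_oneway(list(c(1, 2, 3), c(1, 2, 3)))
  expect_equal(ident$F, 0)
  expect_equal(ident$p, 1)

  expect_error(anova_oneway(list(1:3)), "two groups")
  expect_error(anova_oneway(list(1:3, 5)), "two values")
})

test_that("the ANOVA p-value is monotone decreasing in F at fixed df", {
  ps <- stats::pf(c(1, 3, 9, 27), 2, 6, lower.tail = FALSE)
  expect_true(all(diff(ps) < 0))
})

test_that("ICC(2,1) equals the independent mean-squares oracle on a fixed toy", {
  x <- c(9, 6, 8, 7, 10, 6)   # rater/method 1
  y <- c(2, 1, 4, 1, 5, 2)    # rater/method 2
  res <- icc_agreement(x, y)

  # oracle: two-way layout mean squares from raw sums of squares
  n <- 6; k <- 2
  dat <- c(x, y)
  grand <- mean(dat)
  row_means <- (x + y) / 2
  col_means <- c(mean(x), mean(y))
  ss_rows <- k * sum((row_means - grand)^2)
  ss_cols <- n * sum((col_means - grand)^2)
  ss_tot <- sum((dat - grand)^2)
  ss_err <- ss_tot - ss_rows - ss_cols
  msr <- ss_rows / (n - 1); msc <- ss_cols / (k - 1)
  mse <- ss_err / ((n - 1) * (k - 1))
  icc_oracle <- (msr - mse) / (msr + (k - 1) * mse + k * (msc - mse) / n)
  expect_equal(res$icc, icc_oracle, tolerance = 1e-12)
  expect_true(res$ci[1] <= res$icc && res$icc <= res$ci[2])
})

test_that("ICC is 1 for identical inputs and below 1 under constant offset", {
  x <- c(10, 20, 30, 40, 55)
  expect_equal(icc_agreement(x, x)$icc, 1, tolerance = 1e-9)
  off <- icc_agreement(x, x + 10)
  expect_lt(off$icc, 1)   # absolute agreement penalizes bias
  expect_gt(off$icc, 0)
  expect_error(icc_agreement(1:2, 2:3), "at least 3")
  expect_true(is.na(icc_agreement(rep(1, 5), rep(1, 5))$icc))
})

test_that("Bland-Altman matches hand arithmetic", {
  ba0 <- bland_altman(1:5, 1:5)
  expect_equal(ba0$bias, 0)
  expect_equal(ba0$loa_low, 0)
  expect_equal(ba0$loa_high, 0)

  ba2 <- bland_altman(3:7, 3:7 - 2)
  expect_equal(ba2$bias, 2)
  expect_equal(c(ba2$loa_low, ba2$loa_high), c(2, 2))

  x <- c(10, 12, 14); y <- c(11, 11, 15)
  ba <- bland_altman(x, y)
  expect_equal(ba$bias, -1 / 3, tolerance = 1e-12)
  s <- sd(c(-1, 1, -1))
  expect_equal(ba$loa_low, -1 / 3 - 1.96 * s, tolerance = 1e-12)
  expect_equal(ba$loa_high, -1 / 3 + 1.96 * s, tolerance = 1e-12)
  expect_error(bland_altman(1, 2), "at least 2")
})

test_that("limits of agreement cover about 95% of large normal samples", {
  set.seed(2024)
  x <- rnorm(10000, 50, 5)
  y <- x + rnorm(10000, 0.5, 2)
  ba <- bland_altman(x, y)
  cover <- mean(ba$diffs >= ba$loa_low & ba$diffs <= ba$loa_high)
  expect_gte(cover, 0.93)
  expect_lte(cover, 0.97)
})

make_records <- function(n, means, feature_levels, metric_sd = 0.05, seed = 1) {
  set.seed(seed)
  lev <- rep(names(means), length.out = n)
  data.frame(case_id = sprintf("c%03d", seq_len(n)),
             dsc = rnorm(n, unlist(means)[lev], metric_sd),
             hd95_mm = rnorm(n, 4, 1),
             stringsAsFactors = FALSE)
}

test_that("subgroup analysis groups, tests, and reports untestable designs", {
  n <- 40
  meta <- data.frame(case_id = sprintf("c%03d", 1:n),
                     composition = rep(c("cystic", "solid"), 20),
                     lobulated = rep(c(TRUE, FALSE), each = 20))
  rec <- make_records(n, c(cystic = 0.7, solid = 0.9), seed = 3)
  res <- subgroup_analysis(rec, meta, "dsc", "composition")
  expect_true(res$testable)
  expect_lt(res$p, 0.05)
  expect_equal(unname(res$group_sizes), c(20L, 20L))

  same <- data.frame(case_id = meta$case_id, composition = "cystic")
  res2 <- subgroup_analysis(rec, same, "dsc", "composition")
  expect_false(res2$testable)
  expect_true(is.na(res2$p))
})

test_that("undefined metric values are excluded with a reported count", {
  meta <- data.frame(case_id = sprintf("c%03d", 1:10),
                     lobulated = rep(c(TRUE, FALSE), 5))
  rec <- make_records(10, c(a = 0.8), seed = 4)
  rec$dsc[c(2, 5)] <- NA
  expect_message(res <- subgroup_analysis(rec, meta, "dsc", "lobulated"),
                 "excluding 2")
  expect_equal(res$n_excluded, 2L)
  expect_equal(sum(res$group_sizes), 8L)
})

test_that("a systematic composition effect is detected at cohort scale", {
  # solid cases given systematically higher DSC by construction; 60 per group
  n <- 120
  meta <- data.frame(case_id = sprintf("c%03d", 1:n),
                     composition = rep(c("cystic", "solid"), each = 60))
  set.seed(6)
  rec <- data.frame(case_id = meta$case_id,
                    dsc = c(rnorm(60, 0.78, 0.06), rnorm(60, 0.86, 0.06)))
  res <- subgroup_analysis(rec, meta, "dsc", "composition")
  expect_lt(res$p, 0.05)
  expect_gt(res$group_means[["solid"]], res$group_means[["cystic"]])
})

test_that("the full subgroup grid mirrors the metric-by-feature layout", {
  n <- 24
  meta <- data.frame(case_id = sprintf("c%03d", 1:n),
                     composition = rep(c("cystic", "solid", "mixed"), 8),
                     lobulated = rep(c(TRUE, FALSE), 12),
                     ica_contact = rep(c(TRUE, FALSE), each = 12),
                     sinus_invasion = rep(c(TRUE, TRUE, FALSE), 8))
  rec <- data.frame(case_id = meta$case_id, dsc = runif(n, 0.7, 0.9),
                    jaccard = runif(n, 0.5, 0.8), tpr = runif(n, 0.7, 1),
                    fpr = runif(n, 0, 1e-3), hd95_mm = runif(n, 2, 8))
  grid <- subgroup_grid(rec, meta)
  expect_equal(nrow(grid), 5L * 4L)
  expect_true(all(grid$testable))
  expect_true(all(grid$p >= 0 & grid$p <= 1))
})
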