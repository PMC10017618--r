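#' Classic one-way ANOVA
#'
#' Between/within mean-square F statistic with its F-distribution p-value
#' (equal-variance one-way ANOVA, via `stats::oneway.test`).
#'
#' @param groups List of numeric vectors, >= 2 groups with >= 2 values each.
#' @return `list(F = , p = , df_between = , df_within = , group_means = ,
#'   group_sizes = )`.
#' @export
anova_oneway <- function(groups) {
  if (!is.list(groups) || length(groups) < 2L)
    stop("need at least two groups")
  groups <- lapply(groups, function(g) as.numeric(g[!is.na(g)]))
  sizes <- lengths(groups)
  if (any(sizes < 2L)) stop("every group needs at least two values")
  values <- unlist(groups)
  fac <- factor(rep(seq_along(groups), sizes))
  ow <- stats::oneway.test(values ~ fac, var.equal = TRUE)
  list(F = unname(ow$statistic), p = unname(ow$p.value),
       df_between = unname(ow$parameter[1]), df_within = unname(ow$parameter[2]),
       group_means = vapply(groups, mean, numeric(1)),
       group_sizes = as.integer(sizes))
}

#' Intraclass correlation for method agreement: ICC(2,1)
#'
#' Two-way random-effects, absolute-agreement, single-measurement intraclass
#' correlation between paired volume measurements (e.g. manual vs automatic),
#' with an F-based 95% confidence interval. Absolute agreement penalizes a
#' systematic offset between methods, so `y = x + c` with `c != 0` scores
#' below 1.
#'
#' @param x,y Equal-length paired measurements, `n >= 3`.
#' @param conf Confidence level for the interval.
#' @return `list(icc = , ci = c(lo, hi), n = )`; `icc` is `NA` with zero
#'   total variance.
#' @export
icc_agreement <- function(x, y, conf = 0.95) {
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(x) != length(y)) stop("x and y must be paired")
  ok <- !(is.na(x) | is.na(y))
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3L) stop("need at least 3 pairs")
  k <- 2L
  dat <- data.frame(score = c(x, y),
                    subject = factor(rep(seq_len(n), 2L)),
                    rater = factor(rep(1:2, each = n)))
  if (stats::var(dat$score) < 1e-24) return(list(icc = NA_real_, ci = c(NA, NA), n = n))
  ms <- summary(stats::aov(score ~ subject + rater, data = dat))[[1]][["Mean Sq"]]
  msr <- ms[1]; msc <- ms[2]; mse <- ms[3]
  icc <- (msr - mse) / (msr + (k - 1) * mse + k * (msc - mse) / n)
  # F-based CI (McGraw & Wong, case A,1) with Satterthwaite denominator df
  alpha <- 1 - conf
  if (mse < 1e-24 || icc >= 1 - 1e-12) {
    ci <- c(lo = icc, hi = icc)
  } else {
    a <- (k * icc) / (n * (1 - icc))
    b <- 1 + (k * icc * (n - 1)) / (n * (1 - icc))
    v <- (a * msc + b * mse)^2 /
      ((a * msc)^2 / (k - 1) + (b * mse)^2 / ((n - 1) * (k - 1)))
    fl <- stats::qf(1 - alpha / 2, n - 1, v)
    fu <- stats::qf(1 - alpha / 2, v, n - 1)
    lo <- n * (msr - fl * mse) /
      (fl * (k * msc + (k * n - k - n) * mse) + n * msr)
    hi <- n * (fu * msr - mse) /
      (k * msc + (k * n - k - n) * mse + n * fu * msr)
    ci <- c(lo = max(-1, lo), hi = min(1, hi))
  }
  list(icc = icc, ci = ci, n = n)
}

#' Bland-Altman agreement analysis
#'
#' Bias is `mean(x - y)`; the 95% limits of agreement are
#' `bias +/- 1.96 sd(x - y)` with the sample (n-1) standard deviation.
#'
#' @param x,y Paired measurements, `n >= 2`.
#' @return `list(bias = , loa_low = , loa_high = , means = , diffs = , n = )`.
#' @export
bland_altman <- function(x, y) {
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(x) != length(y)) stop("x and y must be paired")
  ok <- !(is.na(x) | is.na(y))
  x <- x[ok]; y <- y[ok]
  if (length(x) < 2L) stop("need at least 2 pairs")
  d <- x - y
  bias <- mean(d)
  s <- stats::sd(d)
  list(bias = bias, loa_low = bias - 1.96 * s, loa_high = bias + 1.96 * s,
       means = (x + y) / 2, diffs = d, n = length(x))
}

#' Subgroup analysis of per-case metrics against a radiological feature
#'
#' Joins the metrics table with case metadata on `case_id`, groups the chosen
#' metric by the feature (three composition groups, two groups for boolean
#' features) and runs [anova_oneway()]. Cases with an undefined (NA) metric
#' are excluded, with the count reported. A feature where any group has fewer
#' than two usable cases is reported as untestable rather than an error.
#'
#' @param records Per-case metrics `data.frame` (see [evaluate_case()]).
#' @param meta Case metadata with `case_id` and the feature columns.
#' @param metric Metric column name, e.g. `"dsc"` or `"hd95_mm"`.
#' @param feature One of `"composition"`, `"lobulated"`, `"ica_contact"`,
#'   `"sinus_invasion"`.
#' @return `list(feature, metric, group_means, group_sizes, F, p, testable,
#'   n_excluded)`.
#' @export
subgroup_analysis <- function(records, meta, metric = "dsc",
                              feature = "composition") {
  if (!metric %in% names(records)) stop(sprintf("no metric column '%s'", metric))
  if (!feature %in% names(meta)) stop(sprintf("no feature column '%s'", feature))
  df <- merge(records[, c("case_id", metric)], meta[, c("case_id", feature)],
              by = "case_id")
  keep <- !is.na(df[[metric]])
  n_excluded <- sum(!keep)
  if (n_excluded > 0)
    message(sprintf("subgroup_analysis: excluding %d case(s) with undefined %s",
                    n_excluded, metric))
  df <- df[keep, ]
  groups <- split(df[[metric]], df[[feature]])
  groups <- groups[lengths(groups) > 0]
  out <- list(feature = feature, metric = metric,
              group_means = vapply(groups, mean, numeric(1)),
              group_sizes = lengths(groups),
              F = NA_real_, p = NA_real_, testable = FALSE,
              n_excluded = n_excluded)
  if (length(groups) >= 2L && all(lengths(groups) >= 2L)) {
    an <- anova_oneway(groups)
    out$F <- an$F; out$p <- an$p; out$testable <- TRUE
  }
  out
}

#' Full subgroup grid: every metric by every radiological feature
#'
#' Convenience wrapper running [subgroup_analysis()] for DSC, Jaccard, TPR,
#' FPR and 95HD against composition, lobulated shape, carotid contact and
#' sinus invasion. p-values are reported raw, without multiplicity
#' correction, mirroring how such grids are conventionally reported.
#'
#' @inheritParams subgroup_analysis
#' @param metrics Metric column names to test.
#' @param features Feature column names to group by.
#' @return A `data.frame` with one row per metric x feature pair.
#' @export
subgroup_grid <- function(records, meta,
                          metrics = c("dsc", "jaccard", "tpr", "fpr", "hd95_mm"),
                          features = c("composition", "lobulated",
                                       "ica_contact", "sinus_invasion")) {
  rows <- list()
  for (m in metrics) for (f in features) {
    r <- suppressMessages(subgroup_analysis(records, meta, m, f))
    rows[[length(rows) + 1L]] <- data.frame(
      metric = m, feature = f, F = r$F, p = r$p, testable = r$testable,
      groups = paste(sprintf("%s=%.4g(n=%d)", names(r$group_means),
                             r$group_means, r$group_sizes), collapse = "; "),
      stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}
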