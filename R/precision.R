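#' Paired duplicate measurements
#'
#' Container for per-subject duplicate measurements (scan/re-scan or
#' operator 1 / operator 2).  Rows with missing values are dropped with a
#' warning.
#'
#' @param subject_ids subject identifiers.
#' @param m1,m2 numeric measurement vectors of equal length.
#' @return A `paired_measurements` object.
#' @export
paired_measurements <- function(subject_ids, m1, m2) {
  if (length(m1) != length(m2) || length(subject_ids) != length(m1))
    stop("subject_ids, m1 and m2 must have equal length")
  ok <- is.finite(m1) & is.finite(m2)
  if (!all(ok)) {
    warning(sum(!ok), " row(s) with missing values dropped")
    subject_ids <- subject_ids[ok]; m1 <- m1[ok]; m2 <- m2[ok]
  }
  structure(list(subject_ids = subject_ids, m1 = as.numeric(m1),
                 m2 = as.numeric(m2)),
            class = "paired_measurements")
}

#' @export
print.paired_measurements <- function(x, ...) {
  cat(sprintf("<paired_measurements> %d subject(s)\n", length(x$m1)))
  invisible(x)
}

#' Intraclass correlation, two-way random effects, absolute agreement
#'
#' Single-measure ICC(2,1) from the two-way ANOVA mean squares
#' `(MSR - MSE) / (MSR + (k-1) MSE + k (MSC - MSE) / n)`, with the F-based
#' 95% confidence interval of McGraw & Wong.  Absolute agreement penalizes
#' systematic offsets between the two ratings, unlike the consistency
#' form.  The single-measure form is reported because individual scans or
#' operators are being compared, not their average.
#'
#' @param pm a [paired_measurements] object (k = 2 raters, n >= 3
#'   subjects).
#' @param conf_level confidence level for the interval.
#' @return List `icc`, `ci95 = c(lo, hi)`, `rating` (see [icc_rating()]),
#'   `ms` (the mean squares).
#' @export
icc_two_way_random_absolute <- function(pm, conf_level = 0.95) {
  stopifnot(inherits(pm, "paired_measurements"))
  n <- length(pm$m1)
  if (n < 3) stop("ICC needs at least 3 subjects")
  k <- 2
  x <- cbind(pm$m1, pm$m2)
  if (var(as.vector(x)) == 0) stop("degenerate data: zero total variance")
  grand <- mean(x)
  row_means <- rowMeans(x)
  col_means <- colMeans(x)
  ssr <- k * sum((row_means - grand)^2)
  ssc <- n * sum((col_means - grand)^2)
  sst <- sum((x - grand)^2)
  sse <- sst - ssr - ssc
  msr <- ssr / (n - 1)
  msc <- ssc / (k - 1)
  mse <- sse / ((n - 1) * (k - 1))
  icc <- (msr - mse) / (msr + (k - 1) * mse + k * (msc - mse) / n)

  # McGraw & Wong CI for ICC(A,1)
  alpha <- 1 - conf_level
  a <- k * icc / (n * (1 - icc))
  b <- 1 + k * icc * (n - 1) / (n * (1 - icc))
  vdf <- (a * msc + b * mse)^2 /
    ((a * msc)^2 / (k - 1) + (b * mse)^2 / ((n - 1) * (k - 1)))
  f1 <- qf(1 - alpha / 2, n - 1, vdf)
  f2 <- qf(1 - alpha / 2, vdf, n - 1)
  lo <- n * (msr - f1 * mse) /
    (f1 * (k * msc + (k * n - k - n) * mse) + n * msr)
  hi <- n * (f2 * msr - mse) /
    (k * msc + (k * n - k - n) * mse + n * f2 * msr)
  list(icc = icc, ci95 = c(lo, hi), rating = icc_rating(icc),
       ms = c(msr = msr, msc = msc, mse = mse))
}

#' Qualitative ICC rating
#'
#' Bands: `< 0.40` poor, `0.40-0.60` fair, `0.60-0.75` good, `0.75-1.00`
#' excellent.  Boundary values are assigned to the higher band (0.60 is
#' good, 0.75 is excellent).
#'
#' @param icc ICC value (`<= 1`; negative estimates are rated poor).
#' @return One of `"poor"`, `"fair"`, `"good"`, `"excellent"`.
#' @export
icc_rating <- function(icc) {
  stopifnot(is.numeric(icc), icc <= 1 + 1e-12)
  vapply(icc, function(v) {
    if (v < 0.40) "poor"
    else if (v < 0.60) "fair"
    else if (v < 0.75) "good"
    else "excellent"
  }, character(1))
}

#' RMS precision errors (Gluer)
#'
#' Short-term precision from duplicate measurements: per subject
#' `SD_j = |x1 - x2| / sqrt(2)` and `CV_j = 100 * SD_j / mean_j`;
#' `SD_RMS = sqrt(mean SD_j^2)` and `CV_RMS = sqrt(mean CV_j^2)`.
#' `CV_RMS` is reported `NA` when any subject mean is zero (as for count
#' outcomes, where a coefficient of variation is not applicable).
#'
#' @param pm a [paired_measurements] object.
#' @return List `sd_rms` (input units) and `cv_rms_pct` (percent or `NA`).
#' @export
rms_precision <- function(pm) {
  stopifnot(inherits(pm, "paired_measurements"))
  d <- pm$m1 - pm$m2
  sdj <- abs(d) / sqrt(2)
  means <- (pm$m1 + pm$m2) / 2
  sd_rms <- sqrt(mean(sdj^2))
  cv_rms <- if (any(means == 0)) NA_real_ else
    sqrt(mean((100 * sdj / means)^2))
  list(sd_rms = sd_rms, cv_rms_pct = cv_rms)
}

#' Least significant change
#'
#' `LSC = 1.96 * sqrt(2) * precision`, the smallest change between two
#' measurements exceeding the measurement error at 95% confidence.  Feed
#' it `sd_rms` for the absolute LSC or `cv_rms_pct` for the percentage
#' LSC.
#'
#' @param precision nonnegative precision error (SD_RMS or CV_RMS).
#' @return LSC in the units of the input.
#' @examples
#' lsc(1.5)  # 4.16
#' @export
lsc <- function(precision) {
  if (any(precision < 0, na.rm = TRUE)) stop("precision must be >= 0")
  1.96 * sqrt(2) * precision
}

#' Bland-Altman agreement summary
#'
#' Differences `d = m1 - m2` against their means; limits of agreement at
#' `mean(d) +/- 1.96 * SD(d)`.
#'
#' @param pm a [paired_measurements] object (n >= 2).
#' @return List `mean_diff`, `loa = c(lo, hi)`, `means`, `diffs`.
#' @export
bland_altman <- function(pm) {
  stopifnot(inherits(pm, "paired_measurements"))
  if (length(pm$m1) < 2) stop("need at least 2 pairs")
  d <- pm$m1 - pm$m2
  s <- sd(d)
  list(mean_diff = mean(d),
       loa = c(mean(d) - 1.96 * s, mean(d) + 1.96 * s),
       means = (pm$m1 + pm$m2) / 2, diffs = d)
}

#' Paired t-test on duplicate measurements
#'
#' Two-sided paired t-test (`stats::t.test`) comparing the two
#' measurement occasions.
#'
#' @param pm a [paired_measurements] object.
#' @return List `t`, `p`, `df`.
#' @export
paired_t <- function(pm) {
  stopifnot(inherits(pm, "paired_measurements"))
  if (length(pm$m1) < 2) stop("need at least 2 pairs")
  if (var(pm$m1 - pm$m2) == 0)
    stop("zero variance of differences: paired t undefined")
  tt <- t.test(pm$m1, pm$m2, paired = TRUE)
  list(t = unname(tt$statistic), p = tt$p.value,
       df = unname(tt$parameter))
}

#' Full precision report
#'
#' Combines ICC(2,1) with CI and rating, RMS precision errors, LSC in
#' absolute and percentage terms, Bland-Altman limits and the paired t
#' into one report for a single outcome.
#'
#' @param pm a [paired_measurements] object.
#' @return A `precision_report` list.
#' @export
precision_report <- function(pm) {
  icc <- icc_two_way_random_absolute(pm)
  rms <- rms_precision(pm)
  structure(list(
    n = length(pm$m1),
    icc = icc$icc, icc_ci95 = icc$ci95, icc_rating = icc$rating,
    sd_rms = rms$sd_rms, cv_rms_pct = rms$cv_rms_pct,
    lsc_sd = lsc(rms$sd_rms),
    lsc_cv_pct = if (is.na(rms$cv_rms_pct)) NA_real_ else
      lsc(rms$cv_rms_pct),
    bland_altman = bland_altman(pm)[c("mean_diff", "loa")],
    paired_t = paired_t(pm)), class = "precision_report")
}

#' @export
print.precision_report <- function(x, ...) {
  cat(sprintf("<precision_report> n = %d\n", x$n))
  cat(sprintf("  ICC %.3f (95%% CI %.3f - %.3f), %s\n", x$icc,
              x$icc_ci95[1], x$icc_ci95[2], x$icc_rating))
  cat(sprintf("  SD_RMS %.4g, LSC_SD %.4g; CV_RMS %s, LSC_CV%% %s\n",
              x$sd_rms, x$lsc_sd,
              ifelse(is.na(x$cv_rms_pct), "n.a.",
                     sprintf("%.4g%%", x$cv_rms_pct)),
              ifelse(is.na(x$lsc_cv_pct), "n.a.",
                     sprintf("%.4g%%", x$lsc_cv_pct))))
  cat(sprintf("  Bland-Altman mean diff %.4g, LoA [%.4g, %.4g]\n",
              x$bland_altman$mean_diff, x$bland_altman$loa[1],
              x$bland_altman$loa[2]))
  cat(sprintf("  paired t = %.3f (df %g), p = %.4g\n", x$paired_t$t,
              x$paired_t$df, x$paired_t$p))
  invisible(x)
}

#' Motion-grade stack and joint exclusion
#'
#' Every stack is visually graded 1-5 for motion artifacts on each scan;
#' a stack is excluded when its grade exceeds `grade_max` (default 3) on
#' the first and/or the second scan (union counting: a stack poor on both
#' scans is excluded once).  A joint is excluded when all of its stacks
#' are excluded.
#'
#' @param grades data.frame with columns `joint_id`, then per-stack grade
#'   columns for scan 1 (`s1_g1`, `s1_g2`, ...) and scan 2 (`s2_g1`,
#'   ...), one row per joint.
#' @param grade_max largest acceptable grade.
#' @return List `excluded_stacks` (data.frame `joint_id`, `stack`),
#'   `n_excluded_stacks`, `n_total_stacks`, `excluded_pct`,
#'   `excluded_joints`, `included_joints`.
#' @export
apply_exclusions <- function(grades, grade_max = 3L) {
  if (!is.data.frame(grades) || !"joint_id" %in% names(grades))
    stop("grades must be a data.frame with a joint_id column")
  g1_cols <- grep("^s1_g", names(grades), value = TRUE)
  g2_cols <- grep("^s2_g", names(grades), value = TRUE)
  if (length(g1_cols) == 0 || length(g1_cols) != length(g2_cols))
    stop("malformed grade table: need matching s1_g*/s2_g* columns")
  g1 <- as.matrix(grades[g1_cols])
  g2 <- as.matrix(grades[g2_cols])
  if (any(is.na(g1)) || any(is.na(g2)) ||
      any(g1 < 1 | g1 > 5) || any(g2 < 1 | g2 > 5))
    stop("grades must be integers in 1..5")
  bad <- g1 > grade_max | g2 > grade_max
  idx <- which(bad, arr.ind = TRUE)
  excluded_stacks <- data.frame(
    joint_id = grades$joint_id[idx[, 1]],
    stack = idx[, 2])
  excluded_stacks <- excluded_stacks[order(idx[, 1], idx[, 2]), ,
                                     drop = FALSE]
  all_bad <- rowSums(bad) == ncol(bad)
  list(excluded_stacks = excluded_stacks,
       n_excluded_stacks = sum(bad),
       n_total_stacks = length(bad),
       excluded_pct = 100 * sum(bad) / length(bad),
       excluded_joints = grades$joint_id[all_bad],
       included_joints = grades$joint_id[!all_bad])
}
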