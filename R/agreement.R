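#' Paired per-subject measurements
#'
#' One value per subject from each of two sources: two measurement systems
#' (concurrent validity) or two sessions (test-retest reliability).
#'
#' @param value_a,value_b numeric vectors of equal length >= 3.
#' @param label_a,label_b names of the two sources.
#' @param subject_id optional subject identifiers.
#' @return A data.frame of class `paired_table`.
#' @export
paired_table <- function(value_a, value_b,
                         label_a = "A", label_b = "B", subject_id = NULL) {
  n <- length(value_a)
  if (length(value_b) != n)
    stop("paired_table: columns must have equal length")
  if (n < 3) stop("paired_table: need at least 3 subjects")
  if (any(!is.finite(value_a)) || any(!is.finite(value_b)))
    stop("paired_table: values must be finite")
  if (is.null(subject_id)) subject_id <- seq_len(n)
  out <- data.frame(subject_id = subject_id,
                    value_a = value_a, value_b = value_b)
  attr(out, "labels") <- c(label_a, label_b)
  class(out) <- c("paired_table", "data.frame")
  out
}

#' Interpretation band for a correlation coefficient
#'
#' Cut-points: below 0.50 low, 0.50-0.69 moderate, 0.70-0.89 high,
#' 0.90 and above very high.
#'
#' @param r correlation coefficient.
#' @return One of `"low"`, `"moderate"`, `"high"`, `"very high"`.
#' @export
correlation_band <- function(r) {
  a <- abs(r)
  if (a < 0.50) "low"
  else if (a < 0.70) "moderate"
  else if (a < 0.90) "high"
  else "very high"
}

#' Interpretation band for an intraclass correlation
#'
#' Cut-points: below 0.50 poor, 0.50-0.69 moderate, 0.70-0.89 good,
#' 0.90 and above excellent.
#'
#' @param icc intraclass correlation coefficient.
#' @return One of `"poor"`, `"moderate"`, `"good"`, `"excellent"`.
#' @export
icc_band <- function(icc) {
  if (icc < 0.50) "poor"
  else if (icc < 0.70) "moderate"
  else if (icc < 0.90) "good"
  else "excellent"
}

#' Pearson correlation with interpretation band
#'
#' Sample Pearson r between the two columns, with a two-sided p-value from
#' the t transform on n - 2 degrees of freedom, and the conventional
#' interpretation band.
#'
#' @param table a [paired_table()].
#' @return A list of class `validity_result`: `r`, `p_value`, `n`, `band`.
#' @export
pearson_validity <- function(table) {
  stopifnot(inherits(table, "paired_table"))
  if (stats::sd(table$value_a) == 0 || stats::sd(table$value_b) == 0)
    stop("undefined correlation: a column has zero variance")
  ct <- stats::cor.test(table$value_a, table$value_b, method = "pearson")
  r <- unname(ct$estimate)
  structure(list(r = r, p_value = ct$p.value, n = nrow(table),
                 band = correlation_band(r)),
            class = "validity_result")
}

# Two-way (subjects x measurements) ANOVA mean squares for a complete table.
.anova_ms <- function(m) {
  n <- nrow(m); k <- ncol(m)
  grand <- mean(m)
  ssr <- k * sum((rowMeans(m) - grand)^2)
  ssc <- n * sum((colMeans(m) - grand)^2)
  sst <- sum((m - grand)^2)
  list(msr = ssr / (n - 1),
       msc = ssc / (k - 1),
       mse = (sst - ssr - ssc) / ((n - 1) * (k - 1)),
       n = n, k = k)
}

#' Intraclass correlation ICC(3,k) for two-session reliability
#'
#' Two-way mixed-effects, average-measures intraclass correlation with k = 2
#' sessions. The default `"consistency"` definition,
#' `ICC = (MS_subjects - MS_error) / MS_subjects`, ignores a systematic
#' session offset; `"agreement"` penalises it. The 95% confidence interval
#' and p-value follow the classical F-distribution construction
#' (Shrout-Fleiss / McGraw-Wong).
#'
#' @param table a [paired_table()] (columns are the two sessions).
#' @param type `"consistency"` (default) or `"agreement"`.
#' @param conf confidence level (default 0.95).
#' @return A list of class `reliability_result`: `icc`, `ci_low`, `ci_high`,
#'   `p_value`, `n`, `k`, `type`, `band`.
#' @export
icc_3_2 <- function(table, type = c("consistency", "agreement"), conf = 0.95) {
  stopifnot(inherits(table, "paired_table"))
  type <- match.arg(type)
  ms <- .anova_ms(cbind(table$value_a, table$value_b))
  n <- ms$n; k <- ms$k
  if (ms$msr <= 0)
    stop("undefined icc: no between-subject variance")
  alpha <- 1 - conf
  df1 <- n - 1; df2 <- (n - 1) * (k - 1)
  f0 <- ms$msr / ms$mse
  p <- stats::pf(f0, df1, df2, lower.tail = FALSE)
  if (type == "consistency") {
    icc <- (ms$msr - ms$mse) / ms$msr
    fl <- f0 / stats::qf(1 - alpha / 2, df1, df2)
    fu <- f0 * stats::qf(1 - alpha / 2, df2, df1)
    lo <- 1 - 1 / fl
    hi <- 1 - 1 / fu
  } else {
    icc1 <- (ms$msr - ms$mse) /
      (ms$msr + (k - 1) * ms$mse + k * (ms$msc - ms$mse) / n)
    icc <- (ms$msr - ms$mse) / (ms$msr + (ms$msc - ms$mse) / n)
    fj <- ms$msc / ms$mse
    vn <- (k - 1) * (n - 1) *
      (k * icc1 * fj + n * (1 + (k - 1) * icc1) - k * icc1)^2
    vd <- (n - 1) * k^2 * icc1^2 * fj^2 +
      (n * (1 + (k - 1) * icc1) - k * icc1)^2
    v <- vn / vd
    fu_ <- stats::qf(1 - alpha / 2, n - 1, v)
    fl_ <- stats::qf(1 - alpha / 2, v, n - 1)
    l1 <- n * (ms$msr - fu_ * ms$mse) /
      (fu_ * (k * ms$msc + (k * n - k - n) * ms$mse) + n * ms$msr)
    u1 <- n * (fl_ * ms$msr - ms$mse) /
      (k * ms$msc + (k * n - k - n) * ms$mse + n * fl_ * ms$msr)
    lo <- l1 * k / (1 + l1 * (k - 1))
    hi <- u1 * k / (1 + u1 * (k - 1))
  }
  structure(list(icc = icc, ci_low = min(lo, icc), ci_high = max(hi, icc),
                 p_value = p, n = n, k = k, type = type,
                 band = icc_band(icc)),
            class = "reliability_result")
}

#' Bland-Altman limits of agreement
#'
#' Per-subject differences `a - b` and means `(a + b)/2`; limits of agreement
#' are the mean difference plus/minus 1.96 sample standard deviations of the
#' differences, with the count of subjects falling strictly outside.
#'
#' @param table a [paired_table()].
#' @return A list of class `bland_altman_result`: `mean_diff`, `sd_diff`,
#'   `loa_low`, `loa_high`, `n`, `n_outside`, `pct_outside`, plus the
#'   per-subject `diffs` data.frame (`subject_id`, `mean_ab`, `diff`).
#' @export
bland_altman <- function(table) {
  stopifnot(inherits(table, "paired_table"))
  d <- table$value_a - table$value_b
  m <- (table$value_a + table$value_b) / 2
  md <- mean(d)
  sdd <- stats::sd(d)
  lo <- md - 1.96 * sdd
  hi <- md + 1.96 * sdd
  outside <- d < lo | d > hi
  structure(list(mean_diff = md, sd_diff = sdd, loa_low = lo, loa_high = hi,
                 n = length(d), n_outside = sum(outside),
                 pct_outside = 100 * mean(outside),
                 diffs = data.frame(subject_id = table$subject_id,
                                    mean_ab = m, diff = d)),
            class = "bland_altman_result")
}

#' @export
print.validity_result <- function(x, ...) {
  cat(sprintf("Pearson r = %.3f (%s), p = %.3g, n = %d\n",
              x$r, x$band, x$p_value, x$n))
  invisible(x)
}

#' @export
print.reliability_result <- function(x, ...) {
  cat(sprintf("ICC(3,%d) [%s] = %.3f (95%% CI %.3f-%.3f, %s), p = %.3g, n = %d\n",
              x$k, x$type, x$icc, x$ci_low, x$ci_high, x$band, x$p_value, x$n))
  invisible(x)
}

#' @export
print.bland_altman_result <- function(x, ...) {
  cat(sprintf("Bland-Altman: mean diff %.4f, LOA [%.4f, %.4f], %d/%d outside (%.1f%%)\n",
              x$mean_diff, x$loa_low, x$loa_high, x$n_outside, x$n, x$pct_outside))
  invisible(x)
}
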