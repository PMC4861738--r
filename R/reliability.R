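# Test-retest agreement and effect sizes over repeated-session metric values.

#' Intraclass correlation, two-way model, absolute agreement, single measure
#'
#' McGraw-Wong ICC(A,1): subjects are rows, sessions (test, retest, ...) are
#' columns. Mean squares come from the standard two-way decomposition; the
#' absolute-agreement form penalizes systematic session shifts, unlike the
#' consistency form ICC(C,1) available via `type = "consistency"`.
#'
#' The estimate is
#' `(MS_rows - MS_err) / (MS_rows + (k-1) MS_err + (k/n) (MS_cols - MS_err))`
#' with `n` subjects and `k` sessions.
#'
#' @param data Numeric matrix, subjects x sessions, no missing cells, with
#'   at least 2 rows and 2 columns.
#' @param type `"agreement"` (default, ICC(A,1)) or `"consistency"`
#'   (ICC(C,1)).
#' @return The ICC estimate; `NA` sentinel when total variance is zero.
#'   Negative estimates are returned as computed.
#' @export
icc_a1 <- function(data, type = c("agreement", "consistency")) {
  type <- match.arg(type)
  data <- as.matrix(data)
  n <- nrow(data)
  k <- ncol(data)
  if (n < 2L || k < 2L) {
    bench_abort("ICC needs >= 2 subjects and >= 2 sessions", "eegbench_parameter_error")
  }
  if (anyNA(data)) {
    bench_abort("ICC input must have no missing cells", "eegbench_parameter_error")
  }
  grand <- mean(data)
  if (sum((data - grand)^2) == 0) return(NA_real_)
  row_m <- rowMeans(data)
  col_m <- colMeans(data)
  ss_rows <- k * sum((row_m - grand)^2)
  ss_cols <- n * sum((col_m - grand)^2)
  ss_err <- sum((data - outer(row_m, col_m, "+") + grand)^2)
  ms_rows <- ss_rows / (n - 1)
  ms_cols <- ss_cols / (k - 1)
  ms_err <- ss_err / ((n - 1) * (k - 1))
  denom <- if (type == "agreement") {
    ms_rows + (k - 1) * ms_err + (k / n) * (ms_cols - ms_err)
  } else {
    ms_rows + (k - 1) * ms_err
  }
  if (denom == 0) return(NA_real_)
  (ms_rows - ms_err) / denom
}

#' Cohen's d effect size
#'
#' Mean difference over the pooled standard deviation (pooled with
#' `n_x + n_y - 2` degrees of freedom).
#'
#' @param x,y Numeric samples, each of length >= 2.
#' @return The effect size; `NA` sentinel when the pooled sd is zero.
#'   Antisymmetric: `cohens_d(x, y) == -cohens_d(y, x)`.
#' @export
cohens_d <- function(x, y) {
  nx <- length(x)
  ny <- length(y)
  if (nx < 2L || ny < 2L) {
    bench_abort("each sample needs n >= 2", "eegbench_parameter_error")
  }
  sp2 <- ((nx - 1) * stats::var(x) + (ny - 1) * stats::var(y)) / (nx + ny - 2)
  if (sp2 == 0) return(NA_real_)
  (mean(x) - mean(y)) / sqrt(sp2)
}

#' Classify an ICC value
#'
#' Poor below 0.4, good above 0.7, moderate in between (both boundaries fall
#' in "moderate": the reliability bands are stated as strict inequalities for
#' poor and good).
#'
#' @param value ICC estimate in \[-1, 1\], or `NA`.
#' @return `"poor"`, `"moderate"`, `"good"`, or `NA_character_`.
#' @export
classify_icc <- function(value) {
  vapply(value, function(v) {
    if (is.na(v)) return(NA_character_)
    if (v < 0.4) "poor" else if (v > 0.7) "good" else "moderate"
  }, character(1))
}

#' Test-retest reliability table for a metric
#'
#' Convenience wrapper: given two metric tables from repeated sessions,
#' computes per-channel ICC(A,1) across subjects for one metric, with the
#' median and IQR summaries used to describe reliability distributions.
#'
#' @param test,retest [metric_table()]s with matching
#'   (subject, system, condition, channel) keys.
#' @param metric Metric name to extract (e.g. `"PSN"`).
#' @param type Passed to [icc_a1()].
#' @return A list with `per_channel` data.frame (`channel`, `icc`, `label`)
#'   and `summary` (median, IQR).
#' @export
reliability_table <- function(test, retest, metric, type = "agreement") {
  a <- test[test$metric == metric, ]
  b <- retest[retest$metric == metric, ]
  key <- function(df) paste(df$subject, df$system, df$condition, df$channel, sep = "\r")
  b <- b[match(key(a), key(b)), ]
  if (anyNA(b$value) && nrow(a) != nrow(b)) {
    bench_abort("test and retest tables do not align", "eegbench_alignment_error")
  }
  channels <- unique(a$channel)
  icc <- vapply(channels, function(ch) {
    sel <- a$channel == ch
    icc_a1(cbind(a$value[sel], b$value[sel]), type = type)
  }, numeric(1))
  per_channel <- data.frame(channel = channels, icc = icc,
                            label = classify_icc(icc))
  list(per_channel = per_channel,
       summary = c(median = stats::median(icc, na.rm = TRUE),
                   iqr = stats::IQR(icc, na.rm = TRUE)))
}
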