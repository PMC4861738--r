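# Amplitude-based epoch rejection: sliding-window peak-to-peak statistic,
# single-threshold rejection, threshold sweep, amplitude histogram, and
# matched-count rejection across conditions.

#' Sliding-window peak-to-peak amplitude per trial
#'
#' For every trial and channel, the range (max minus min) is computed inside
#' sliding windows of `win` ms advanced by `step` ms (200/100 ms defaults,
#' i.e. 100 ms overlap) and maximized over windows; the per-trial statistic is
#' the maximum over channels. Partial windows at the epoch tail are still
#' evaluated. Invariant to constant offsets.
#'
#' @param epochs An [epoch_set()].
#' @param win Window length in ms (default 200).
#' @param step Window step in ms (default 100).
#' @return Numeric vector, one peak-to-peak value (uV) per trial (all trials,
#'   kept or not). The per-trial, per-channel matrix is attached as attribute
#'   `"per_channel"`.
#' @export
epoch_p2p <- function(epochs, win = 200, step = 100) {
  d <- dim(epochs$tensor)
  win_s <- max(2L, round(win / 1000 * epochs$rate))
  step_s <- max(1L, round(step / 1000 * epochs$rate))
  if (win_s > d[3]) {
    bench_abort("peak-to-peak window exceeds epoch length", "eegbench_parameter_error")
  }
  if (step <= 0) bench_abort("`step` must be > 0", "eegbench_parameter_error")
  starts <- seq.int(1L, d[3], by = step_s)
  starts <- starts[starts < d[3]]       # length-1 tail windows carry no range
  per_channel <- matrix(0, d[1], d[2])
  for (s in starts) {
    idx <- s:min(s + win_s - 1L, d[3])
    seg <- epochs$tensor[, , idx, drop = FALSE]
    rng <- apply(seg, c(1, 2), function(x) max(x) - min(x))
    per_channel <- pmax(per_channel, rng)
  }
  out <- apply(per_channel, 1, max)
  attr(out, "per_channel") <- per_channel
  out
}

#' Reject epochs exceeding a peak-to-peak threshold
#'
#' Clears the keep-mask of every currently kept trial whose sliding-window
#' peak-to-peak amplitude exceeds `thr` on any channel. 75 uV is the
#' traditional stationary-EEG threshold.
#'
#' @param epochs An [epoch_set()] (behavioral rejection, if any, first).
#' @param thr Threshold in uV (> 0). `Inf` is the identity.
#' @param win,step Passed to [epoch_p2p()].
#' @return The [epoch_set()] with an updated keep-mask; attribute
#'   `"rejection_rate"` holds rejected / eligible, where eligible counts the
#'   trials kept on entry.
#' @export
reject_threshold <- function(epochs, thr = 75, win = 200, step = 100) {
  if (!is.numeric(thr) || length(thr) != 1L || is.na(thr) || thr <= 0) {
    bench_abort("`thr` must be a single positive number", "eegbench_parameter_error")
  }
  p2p <- epoch_p2p(epochs, win, step)
  eligible <- epochs$keep_mask
  out <- epochs
  out$keep_mask <- eligible & p2p <= thr
  attr(out, "event_index") <- attr(epochs, "event_index")
  attr(out, "p2p") <- as.numeric(p2p)
  attr(out, "rejection_rate") <-
    if (sum(eligible)) sum(eligible & p2p > thr) / sum(eligible) else NA_real_
  out
}

#' Rejection-rate curve over a threshold sweep
#'
#' Fraction of eligible (kept-on-entry) trials whose peak-to-peak amplitude
#' exceeds each threshold. The default grid spans 75-400 uV in 25 uV steps
#' (14 thresholds). The curve is non-increasing in the threshold by
#' construction.
#'
#' @param epochs An [epoch_set()].
#' @param thresholds Numeric vector of thresholds in uV.
#' @param win,step Passed to [epoch_p2p()].
#' @return A `data.frame` of class `eeg_rejection_curve` with columns
#'   `threshold`, `rejection_rate`, `n_total`.
#' @export
threshold_sweep <- function(epochs, thresholds = seq(75, 400, by = 25),
                            win = 200, step = 100) {
  if (!length(thresholds) || any(thresholds <= 0)) {
    bench_abort("`thresholds` must be non-empty and positive", "eegbench_parameter_error")
  }
  p2p <- epoch_p2p(epochs, win, step)[epochs$keep_mask]
  n <- length(p2p)
  rate <- vapply(thresholds, function(thr) {
    if (n) mean(p2p > thr) else 0
  }, numeric(1))
  structure(
    data.frame(threshold = thresholds, rejection_rate = rate, n_total = n),
    class = c("eeg_rejection_curve", "data.frame")
  )
}

#' Peak-to-peak amplitude histogram
#'
#' Fraction of kept trials per amplitude bin `(k*w, (k+1)*w]` (the first bin
#' includes 0), mirroring the 25 uV binning used to describe single-epoch
#' amplitude distributions.
#'
#' @param epochs An [epoch_set()].
#' @param bin_width Bin width in uV (default 25).
#' @param win,step Passed to [epoch_p2p()].
#' @return A `data.frame` with `lower`, `upper`, `fraction`; fractions sum to
#'   1 over the observed range.
#' @export
amplitude_histogram <- function(epochs, bin_width = 25, win = 200, step = 100) {
  if (bin_width <= 0) bench_abort("`bin_width` must be > 0", "eegbench_parameter_error")
  p2p <- epoch_p2p(epochs, win, step)[epochs$keep_mask]
  if (!length(p2p)) {
    return(data.frame(lower = numeric(0), upper = numeric(0), fraction = numeric(0)))
  }
  nbin <- max(1L, ceiling(max(p2p) / bin_width))
  breaks <- bin_width * (0:nbin)
  counts <- table(cut(p2p, breaks = breaks, include.lowest = TRUE, right = TRUE))
  data.frame(lower = breaks[-length(breaks)], upper = breaks[-1],
             fraction = as.numeric(counts) / length(p2p))
}

#' Match rejected-epoch counts across two conditions
#'
#' For a fair seated-vs-walking comparison both conditions must contribute
#' equally many trials: after thresholding, extra trials are removed from the
#' less-rejected set -- highest peak-to-peak amplitude first, later trial
#' index first on ties -- until both sets have rejected the same number.
#' Never resurrects a rejected epoch.
#'
#' @param epochs_a,epochs_b Thresholded [epoch_set()]s with equal trial
#'   counts.
#' @param win,step Passed to [epoch_p2p()] for the removal ordering.
#' @return List with elements `a` and `b`, both with equal rejected counts.
#' @export
match_rejection <- function(epochs_a, epochs_b, win = 200, step = 100) {
  na <- dim(epochs_a$tensor)[1]
  nb <- dim(epochs_b$tensor)[1]
  rej_a <- na - sum(epochs_a$keep_mask)
  rej_b <- nb - sum(epochs_b$keep_mask)
  if (rej_a == rej_b) return(list(a = epochs_a, b = epochs_b))
  if (rej_a > rej_b) {
    epochs_b <- drop_most_extreme(epochs_b, rej_a - rej_b, win, step)
  } else {
    epochs_a <- drop_most_extreme(epochs_a, rej_b - rej_a, win, step)
  }
  list(a = epochs_a, b = epochs_b)
}

drop_most_extreme <- function(epochs, n_drop, win, step) {
  survivors <- which(epochs$keep_mask)
  if (length(survivors) < n_drop) {
    bench_abort(sprintf(
      "cannot match rejection: need to drop %d but only %d survivors remain",
      n_drop, length(survivors)
    ), "eegbench_matching_error")
  }
  p2p <- epoch_p2p(epochs, win, step)[survivors]
  drop <- survivors[order(-p2p, -survivors)][seq_len(n_drop)]
  epochs$keep_mask[drop] <- FALSE
  epochs
}
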