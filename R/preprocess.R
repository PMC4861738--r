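# Continuous-data conditioning and epoching.

#' High-pass filter a recording
#'
#' Zero-phase (forward-backward) 4th-order Butterworth high-pass, applied per
#' channel. The 1 Hz default removes DC drift and slow motion-related trends
#' before epoching; zero-phase application avoids latency shifts that would
#' displace the P300.
#'
#' @param rec An [recording()].
#' @param cutoff Cutoff frequency in Hz (default 1).
#' @param order Butterworth order of each pass (default 4).
#' @return Filtered [recording()].
#' @export
highpass <- function(rec, cutoff = 1, order = 4) {
  coef <- butter_highpass(order, cutoff, rec$rate)
  # drift time constants scale with 1/cutoff; pad accordingly
  pad <- min(ncol(rec$data) - 1L, max(3L * order, ceiling(2 * rec$rate / cutoff)))
  apply_filter_rec(rec, coef, pad = pad)
}

#' Notch filter line noise
#'
#' Zero-phase biquad notch at the mains frequency plus optional harmonics.
#' Stands in for regression-based line removal: the contract is >= 20 dB
#' suppression at the line frequency with < 1 dB ripple 5 Hz outside the
#' notch width.
#'
#' @param rec An [recording()].
#' @param line_freq Mains frequency in Hz (default 60).
#' @param width -3 dB notch width in Hz (default 2).
#' @param harmonics Number of harmonics to notch in addition to the
#'   fundamental (default 1, i.e. also 2 x line_freq when below Nyquist).
#' @return Filtered [recording()].
#' @export
notch <- function(rec, line_freq = 60, width = 2, harmonics = 1) {
  freqs <- line_freq * seq_len(1 + harmonics)
  if (freqs[1] >= rec$rate / 2) {
    bench_abort("notch frequency is at or above Nyquist", "eegbench_parameter_error")
  }
  freqs <- freqs[freqs < rec$rate / 2]
  for (f in freqs) {
    rec <- apply_filter_rec(rec, design_notch(f, width, rec$rate))
  }
  rec
}

#' Interpolate bad channels
#'
#' Replaces each bad channel by the inverse-distance-weighted (power 2)
#' average of the good channels, using Euclidean distances between the
#' montage's unit-sphere positions. With only 12 electrodes, spherical-spline
#' fitting is ill-conditioned; distance weighting is the stable choice and the
#' weighting scheme is isolated here should a spline variant be wanted.
#'
#' @param rec An [recording()] whose channels are a subset of `mont`.
#' @param bad Character vector of bad channel labels (possibly empty).
#' @param mont An [montage()] providing positions.
#' @param power Inverse-distance exponent (default 2).
#' @return An [recording()] with bad channels reconstructed, good channels
#'   untouched.
#' @export
interpolate_channels <- function(rec, bad, mont = montage(), power = 2) {
  if (!length(bad)) return(rec)
  bad_idx <- match_channel(bad, rec$channel_labels)
  if (anyNA(bad_idx)) {
    bench_abort(sprintf("bad channel(s) not in recording: %s",
                        paste(bad[is.na(bad_idx)], collapse = ", ")),
                "eegbench_lookup_error")
  }
  pos_idx <- match_channel(rec$channel_labels, mont$names)
  if (anyNA(pos_idx)) {
    bench_abort("recording channels missing from montage positions",
                "eegbench_lookup_error")
  }
  pos <- mont$positions[pos_idx, , drop = FALSE]
  good_idx <- setdiff(seq_len(nrow(rec$data)), bad_idx)
  if (length(good_idx) < 3L) {
    bench_abort("fewer than 3 good channels remain; cannot interpolate",
                "eegbench_interpolation_error")
  }
  out <- rec$data
  for (bi in bad_idx) {
    d <- sqrt(rowSums((pos[good_idx, , drop = FALSE] -
                         matrix(pos[bi, ], length(good_idx), 3, byrow = TRUE))^2))
    w <- 1 / d^power
    w <- w / sum(w)
    out[bi, ] <- as.vector(w %*% rec$data[good_idx, , drop = FALSE])
  }
  recording(out, rec$rate, rec$channel_labels, rec$meta)
}

#' Extract stimulus-locked epochs
#'
#' Cuts `[t_min, t_max)` second windows around each event onset. Slicing is
#' bit-exact: no filtering or baseline correction happens here. Events whose
#' window would cross a recording edge are dropped with a warning (and removed
#' from the labels), never an error.
#'
#' @param rec An [recording()].
#' @param events An [event_list()] with 0-based onsets into `rec`.
#' @param window Length-2 numeric, seconds relative to onset; default
#'   `c(-0.3, 0.8)`.
#' @return An [epoch_set()]. With 500 Hz data and the default window each
#'   epoch has 550 samples and the onset falls at 0-based sample 150.
#' @export
extract_epochs <- function(rec, events, window = c(-0.3, 0.8)) {
  if (window[1] >= window[2]) {
    bench_abort("epoch window must satisfy t_min < t_max", "eegbench_parameter_error")
  }
  pre <- round(window[1] * rec$rate)
  post <- round(window[2] * rec$rate)
  nsamp_epoch <- post - pre
  nsamp <- ncol(rec$data)
  # 0-based sample window [onset + pre, onset + post)
  start0 <- events$onsets + pre
  end0 <- events$onsets + post - 1
  ok <- start0 >= 0 & end0 <= nsamp - 1
  if (any(!ok)) {
    warning(sprintf("dropped %d event(s) too close to a recording edge", sum(!ok)))
  }
  kept <- which(ok)
  tensor <- array(0, dim = c(length(kept), nrow(rec$data), nsamp_epoch))
  for (i in seq_along(kept)) {
    idx <- (start0[kept[i]] + 1):(end0[kept[i]] + 1)   # to 1-based
    tensor[i, , ] <- rec$data[, idx, drop = FALSE]
  }
  es <- epoch_set(
    tensor,
    epoch_times = (seq_len(nsamp_epoch) - 1 + pre) / rec$rate,
    labels = events$labels[kept],
    rate = rec$rate,
    channel_labels = rec$channel_labels
  )
  attr(es, "event_index") <- kept
  es
}

#' Reject behaviorally invalid trials
#'
#' Clears the keep-mask for false positives (non-target followed by a button
#' press) and false negatives (target not followed by a press). A press is
#' attributed to an event when it falls in `(onset, onset + response_window]`;
#' the 1.4 s default sits below the minimum stimulus onset asynchrony
#' (0.4 s stimulus + 1.42 s ISI), so attribution is unambiguous.
#'
#' @param epochs An [epoch_set()] made from `events` (one epoch per surviving
#'   event, as produced by [extract_epochs()]).
#' @param events The [event_list()] the epochs were cut from.
#' @param response_window Seconds after onset in which a press counts
#'   (default 1.4).
#' @return The [epoch_set()] with an updated keep-mask; counts are attached as
#'   attributes `"n_false_positive"` and `"n_false_negative"`.
#' @export
behavioral_reject <- function(epochs, events, response_window = 1.4) {
  ev_idx <- attr(epochs, "event_index") %||% seq_along(events$onsets)
  if (length(ev_idx) != dim(epochs$tensor)[1]) {
    bench_abort("epochs do not align one-to-one with events", "eegbench_alignment_error")
  }
  onsets <- events$onsets[ev_idx]
  win <- response_window * epochs$rate
  answered <- vapply(onsets, function(o) {
    any(events$responses > o & events$responses <= o + win)
  }, logical(1))
  labels <- epochs$labels
  fp <- labels == "non-target" & answered
  fn <- labels == "target" & !answered
  out <- epochs
  out$keep_mask <- epochs$keep_mask & !fp & !fn
  attr(out, "event_index") <- ev_idx
  attr(out, "n_false_positive") <- sum(fp & epochs$keep_mask)
  attr(out, "n_false_negative") <- sum(fn & epochs$keep_mask)
  out
}
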