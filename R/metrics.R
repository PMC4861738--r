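# Quality metrics computed from kept epochs: pre-stimulus noise, band power
# and walking/seated ratios, P300 SNR, single-trial coefficient of variation,
# and scalar-product ERP similarity with Fisher-domain averaging.

kept_index <- function(epochs, label = NULL) {
  m <- epochs$keep_mask
  if (!is.null(label)) m <- m & epochs$labels == label
  which(m)
}

time_window_index <- function(epoch_times, window, name = "window") {
  idx <- which(epoch_times >= window[1] & epoch_times < window[2])
  if (!length(idx)) {
    bench_abort(sprintf("`%s` [%g, %g) selects no samples", name, window[1], window[2]),
                "eegbench_parameter_error")
  }
  idx
}

#' Pre-stimulus noise (PSN)
#'
#' Root-mean-square amplitude of each kept trial over the pre-stimulus window
#' (-300 to 0 ms by default), per channel; averaged over trials per channel,
#' and over channels for the grand mean. PSN quantifies the noise floor the
#' ERP must rise above.
#'
#' @param epochs An [epoch_set()].
#' @param window Length-2 numeric, seconds; default `c(-0.3, 0)` (half-open,
#'   excludes the onset sample).
#' @param label Optional class restriction (e.g. `"target"`).
#' @return An object of class `eeg_psn`: list with `per_trial` (kept trials x
#'   channels matrix, uV), `channel_mean` (named vector), `grand_mean`.
#' @export
psn <- function(epochs, window = c(-0.3, 0), label = NULL) {
  keep <- kept_index(epochs, label)
  if (!length(keep)) {
    bench_abort("no kept epochs to compute PSN from", "eegbench_empty_input_error")
  }
  idx <- time_window_index(epochs$epoch_times, window, "psn window")
  seg <- epochs$tensor[keep, , idx, drop = FALSE]
  per_trial <- sqrt(apply(seg^2, c(1, 2), mean))
  channel_mean <- colMeans(per_trial)
  names(channel_mean) <- epochs$channel_labels
  colnames(per_trial) <- epochs$channel_labels
  structure(
    list(per_trial = per_trial, channel_mean = channel_mean,
         grand_mean = mean(channel_mean), n_trials = length(keep)),
    class = "eeg_psn"
  )
}

#' @export
print.eeg_psn <- function(x, ...) {
  cat(sprintf("<eeg_psn> %d trials, grand mean %.3f uV\n", x$n_trials, x$grand_mean))
  invisible(x)
}

# one-sided segment-averaged periodogram (Hamming window, zero-padded
# segments), density scaling -> uV^2/Hz
welch_psd <- function(x, rate, seglen = 128, nfft = 256, overlap = 0) {
  n <- length(x)
  if (n < seglen) {
    bench_abort("signal shorter than the PSD segment length", "eegbench_parameter_error")
  }
  w <- 0.54 - 0.46 * cos(2 * pi * (0:(seglen - 1)) / (seglen - 1))
  starts <- seq.int(1L, n - seglen + 1L, by = seglen - overlap)
  acc <- numeric(nfft %/% 2 + 1)
  for (s in starts) {
    seg <- x[s:(s + seglen - 1)] * w
    sp <- abs(stats::fft(c(seg, numeric(nfft - seglen))))^2
    acc <- acc + sp[1:(nfft %/% 2 + 1)]
  }
  p <- acc / (length(starts) * rate * sum(w^2))
  p[2:(nfft %/% 2)] <- 2 * p[2:(nfft %/% 2)]    # fold negative frequencies
  list(freq = (0:(nfft %/% 2)) * rate / nfft, psd = p)
}

#' Band power from epoched data
#'
#' Per-epoch, per-channel power spectral density by segment-averaged
#' periodogram (128-sample Hamming segments zero-padded to a 256-point FFT by
#' default), averaged over kept epochs per channel and then over channels.
#' Band power is the mean PSD over frequency bins falling in each half-open
#' band `(lower, upper]`. Linear power (uV^2/Hz), not dB.
#'
#' @param epochs An [epoch_set()].
#' @param bands An [band_set()].
#' @param nfft FFT length (default 256).
#' @param seglen Segment length in samples (default 128).
#' @param overlap Segment overlap in samples (default 0).
#' @param label Optional class restriction.
#' @return An object of class `eeg_band_power`: list with `per_channel`
#'   (bands x channels matrix), `average` (named per-band vector), `freq`,
#'   `psd` (channels x frequency matrix), `bands`.
#' @export
band_power <- function(epochs, bands = band_set(), nfft = 256, seglen = 128,
                       overlap = 0, label = NULL) {
  for (nm in names(bands)) {
    if (bands[[nm]][2] > epochs$rate / 2) {
      bench_abort(sprintf("band '%s' extends above Nyquist", nm),
                  "eegbench_parameter_error")
    }
  }
  keep <- kept_index(epochs, label)
  if (!length(keep)) {
    bench_abort("no kept epochs to compute band power from", "eegbench_empty_input_error")
  }
  d <- dim(epochs$tensor)
  freq <- (0:(nfft %/% 2)) * epochs$rate / nfft
  psd <- matrix(0, d[2], length(freq))
  for (tr in keep) {
    for (ch in seq_len(d[2])) {
      psd[ch, ] <- psd[ch, ] +
        welch_psd(epochs$tensor[tr, ch, ], epochs$rate, seglen, nfft, overlap)$psd
    }
  }
  psd <- psd / length(keep)
  rownames(psd) <- epochs$channel_labels
  per_channel <- matrix(0, length(bands), d[2],
                        dimnames = list(names(bands), epochs$channel_labels))
  for (nm in names(bands)) {
    b <- bands[[nm]]
    bins <- which(freq > b[1] & freq <= b[2])
    per_channel[nm, ] <- rowMeans(psd[, bins, drop = FALSE])
  }
  structure(
    list(per_channel = per_channel, average = rowMeans(per_channel),
         freq = freq, psd = psd, bands = bands, n_trials = length(keep)),
    class = "eeg_band_power"
  )
}

#' @export
print.eeg_band_power <- function(x, ...) {
  cat("<eeg_band_power> channel-averaged power (uV^2/Hz):\n")
  print(round(x$average, 4))
  invisible(x)
}

#' Walking/seated band-power ratio (Ratio W/S)
#'
#' Per-band ratio of channel-averaged absolute power, walking over seated,
#' computed on linear power. Values above 1 mean more power while walking --
#' with matched neural activity, a marker of motion-related contamination.
#'
#' @param walk,seat [band_power()] results sharing the same band set.
#' @return Named numeric vector, one ratio per band.
#' @export
ratio_ws <- function(walk, seat) {
  if (!identical(names(walk$average), names(seat$average))) {
    bench_abort("walking and seated results use different band sets",
                "eegbench_parameter_error")
  }
  if (any(seat$average <= 0)) {
    bench_abort("seated power is zero in some band; ratio undefined",
                "eegbench_division_error")
  }
  walk$average / seat$average
}

#' Average kept epochs of one class into an ERP
#'
#' @param epochs An [epoch_set()].
#' @param label Stimulus class to average (`"target"` or `"non-target"`).
#' @return An [erp_waveform()] with `n_epochs` set to the count averaged.
#' @export
average_erp <- function(epochs, label = "target") {
  keep <- kept_index(epochs, label)
  if (!length(keep)) {
    bench_abort(sprintf("no kept epochs with label '%s'", label),
                "eegbench_empty_input_error")
  }
  avg <- apply(epochs$tensor[keep, , , drop = FALSE], c(2, 3), mean)
  erp_waveform(avg, n_epochs = length(keep), label = label,
               epoch_times = epochs$epoch_times,
               channel_labels = epochs$channel_labels)
}

#' P300 signal-to-noise ratio
#'
#' Per channel: the signed maximum of the averaged target ERP inside the P300
#' window (300-500 ms) divided by that channel's trial-averaged pre-stimulus
#' noise. The P300 is a positive deflection, so the signed (not absolute)
#' maximum is used. The PSN denominator is computed from target epochs, the
#' trials that produced the numerator.
#'
#' @param erp_target Averaged target [erp_waveform()].
#' @param psn_result An `eeg_psn` from the same (target) epochs.
#' @param p300_window Length-2 numeric, seconds; default `c(0.3, 0.5)`
#'   (inclusive of both ends).
#' @return Named per-channel numeric vector of SNR values (unitless), with
#'   attribute `"peak"` holding the per-channel peak amplitudes.
#' @export
snr <- function(erp_target, psn_result, p300_window = c(0.3, 0.5)) {
  idx <- which(erp_target$epoch_times >= p300_window[1] &
                 erp_target$epoch_times <= p300_window[2])
  if (!length(idx)) {
    bench_abort("P300 window selects no samples", "eegbench_parameter_error")
  }
  peak <- apply(erp_target$data[, idx, drop = FALSE], 1, max)
  denom <- psn_result$channel_mean
  if (!identical(names(denom), erp_target$channel_labels)) {
    denom <- denom[match_channel(erp_target$channel_labels, names(denom))]
  }
  if (any(!is.finite(denom)) || any(denom <= 0)) {
    bench_abort("PSN is zero or undefined on some channel; SNR undefined",
                "eegbench_division_error")
  }
  out <- peak / denom
  names(out) <- erp_target$channel_labels
  attr(out, "peak") <- stats::setNames(peak, erp_target$channel_labels)
  out
}

#' Single-trial coefficient of variation
#'
#' Ratio of the standard deviation (sample sd, n-1) to the mean of one
#' trial's samples inside the P300 window. A mean of exactly zero yields
#' `NA`, the undefined-value sentinel excluded from averaging.
#'
#' @param x Numeric vector: one trial's samples within the window, uV.
#' @param use_variance If `TRUE`, use the variance instead of the sd in the
#'   numerator (non-default reading of the defining ratio).
#' @return Unitless CV, or `NA` when the mean is 0.
#' @export
cv_trial <- function(x, use_variance = FALSE) {
  if (!length(x)) bench_abort("empty window", "eegbench_parameter_error")
  m <- mean(x)
  if (m == 0) return(NA_real_)
  num <- if (use_variance) stats::var(x) else stats::sd(x)
  num / m
}

#' Trial-averaged coefficient of variation (CV_ERP)
#'
#' Mean over kept trials of the per-trial CV within the P300 window,
#' per channel, plus the channel-averaged value. Trials with undefined CV
#' (window mean exactly 0) are excluded; their count is reported.
#'
#' @param epochs An [epoch_set()].
#' @param window Length-2 numeric, seconds; default `c(0.3, 0.5)`.
#' @param label Optional class restriction (default `"target"`).
#' @param use_variance Passed to [cv_trial()].
#' @return List of class `eeg_cv`: `per_channel` named vector, `overall`
#'   mean over channels, `n_undefined` per channel.
#' @export
cv_erp <- function(epochs, window = c(0.3, 0.5), label = "target",
                   use_variance = FALSE) {
  keep <- kept_index(epochs, label)
  if (!length(keep)) {
    bench_abort("no kept epochs for CV_ERP", "eegbench_empty_input_error")
  }
  idx <- which(epochs$epoch_times >= window[1] & epochs$epoch_times <= window[2])
  if (length(idx) < 2L) {
    bench_abort("CV window selects fewer than 2 samples", "eegbench_parameter_error")
  }
  nchan <- dim(epochs$tensor)[2]
  per_channel <- numeric(nchan)
  n_undef <- integer(nchan)
  for (ch in seq_len(nchan)) {
    cvs <- vapply(keep, function(tr) {
      cv_trial(epochs$tensor[tr, ch, idx], use_variance)
    }, numeric(1))
    n_undef[ch] <- sum(is.na(cvs))
    if (all(is.na(cvs))) {
      bench_abort(sprintf("all trial CVs undefined on channel %s",
                          epochs$channel_labels[ch]),
                  "eegbench_empty_input_error")
    }
    per_channel[ch] <- mean(cvs, na.rm = TRUE)
  }
  names(per_channel) <- epochs$channel_labels
  names(n_undef) <- epochs$channel_labels
  structure(list(per_channel = per_channel, overall = mean(per_channel),
                 n_undefined = n_undef),
            class = "eeg_cv")
}

#' @export
print.eeg_cv <- function(x, ...) {
  cat(sprintf("<eeg_cv> overall CV_ERP %.4f (%d undefined trials excluded)\n",
              x$overall, sum(x$n_undefined)))
  invisible(x)
}

#' Scalar-product similarity of two ERP waveforms
#'
#' Dot product of the two per-channel waveforms after mean-centering and
#' unit-norm scaling -- exactly the Pearson correlation over time, bounded in
#' \[-1, 1\]. Quantifies shape agreement of an ERP across conditions
#' irrespective of amplitude scaling. With `center = FALSE` the raw
#' normalized dot product (cosine similarity) is returned instead.
#'
#' @param erp_a,erp_b [erp_waveform()]s on the same time axis and channels.
#' @param channel Optional single channel label; when `NULL`, all channels.
#' @param center Mean-center before normalizing (default `TRUE`).
#' @return Named numeric vector of r values per requested channel; `NA`
#'   sentinel where a waveform has zero variance.
#' @export
scalar_similarity <- function(erp_a, erp_b, channel = NULL, center = TRUE) {
  if (ncol(erp_a$data) != ncol(erp_b$data)) {
    bench_abort("ERP waveforms have different lengths", "eegbench_alignment_error")
  }
  chans <- if (is.null(channel)) erp_a$channel_labels else channel
  ia <- match_channel(chans, erp_a$channel_labels)
  ib <- match_channel(chans, erp_b$channel_labels)
  if (anyNA(ia) || anyNA(ib)) {
    bench_abort("requested channel absent from an ERP", "eegbench_lookup_error")
  }
  r <- vapply(seq_along(chans), function(i) {
    a <- erp_a$data[ia[i], ]
    b <- erp_b$data[ib[i], ]
    if (center) {
      a <- a - mean(a)
      b <- b - mean(b)
    }
    na <- sqrt(sum(a^2))
    nb <- sqrt(sum(b^2))
    if (na == 0 || nb == 0) return(NA_real_)
    sum(a * b) / (na * nb)
  }, numeric(1))
  stats::setNames(r, chans)
}

#' Average correlations in the Fisher-z domain
#'
#' Correlation-like scores are averaged as `tanh(mean(atanh(r)))`, which
#' respects the bounded, skewed sampling distribution of r. Values at
#' exactly +/-1 are clipped to `1 - 1e-7` in magnitude with a warning.
#'
#' @param r_values Numeric vector of r values in \[-1, 1\]; `NA`s are dropped.
#' @return The back-transformed average.
#' @export
fisher_average <- function(r_values) {
  r <- r_values[!is.na(r_values)]
  if (!length(r)) {
    bench_abort("no defined r values to average", "eegbench_empty_input_error")
  }
  if (any(abs(r) > 1)) {
    bench_abort("r values must lie in [-1, 1]", "eegbench_parameter_error")
  }
  if (any(abs(r) == 1)) {
    warning("r values at +/-1 clipped before Fisher transform")
    r <- pmin(pmax(r, -1 + 1e-7), 1 - 1e-7)
  }
  tanh(mean(atanh(r)))
}
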