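#' Continuous multi-channel EEG recording
#'
#' The core container for continuous EEG. Data are always stored in microvolts
#' (uV); readers convert at ingest so every downstream threshold (e.g. the
#' 75-400 uV rejection sweep) applies directly.
#'
#' @param data Numeric matrix, channels x samples, in uV.
#' @param rate Sampling rate in Hz (> 0).
#' @param channel_labels Character vector of 10-20 channel names, one per row.
#' @param meta Optional named list of provenance (subject, system, condition).
#' @return An object of class `eeg_recording`: a list with elements `data`,
#'   `rate`, `channel_labels`, `meta`.
#' @examples
#' rec <- recording(matrix(rnorm(1000), 2), rate = 500, channel_labels = c("Cz", "Pz"))
#' rec
#' @export
recording <- function(data, rate, channel_labels, meta = list()) {
  data <- as.matrix(data)
  storage.mode(data) <- "double"
  stopifnot_scalar_number(rate, "rate")
  if (rate <= 0) bench_abort("`rate` must be > 0", "eegbench_parameter_error")
  channel_labels <- as.character(channel_labels)
  if (nrow(data) != length(channel_labels)) {
    bench_abort(sprintf(
      "data has %d channel rows but %d labels were given",
      nrow(data), length(channel_labels)
    ), "eegbench_metadata_error")
  }
  if (nrow(data) == 0L) {
    bench_abort("recording must contain at least one channel", "eegbench_metadata_error")
  }
  if (!all(is.finite(data))) {
    bench_abort("recording contains non-finite samples", "eegbench_metadata_error")
  }
  rownames(data) <- channel_labels
  structure(
    list(data = data, rate = rate, channel_labels = channel_labels, meta = meta),
    class = "eeg_recording"
  )
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf(
    "<eeg_recording> %d channels x %d samples @ %g Hz (%.1f s)\n",
    nrow(x$data), ncol(x$data), x$rate, ncol(x$data) / x$rate
  ))
  cat("  channels:", paste(x$channel_labels, collapse = ", "), "\n")
  if (length(x$meta)) {
    cat("  meta:", paste(names(x$meta), unlist(lapply(x$meta, format)),
                         sep = "=", collapse = ", "), "\n")
  }
  invisible(x)
}

#' Stimulus event list for an oddball session
#'
#' Onsets are 0-based sample indices into the parent recording; time 0 of an
#' epoch is the stimulus onset sample. `responses` holds button-press sample
#' indices (0-based), unassigned to stimuli until [behavioral_reject()].
#'
#' @param onsets Integer vector of 0-based onset sample indices, strictly
#'   increasing.
#' @param labels Character vector, one of `"target"`/`"non-target"` per onset.
#' @param responses Integer vector of 0-based button-press sample indices.
#' @return An object of class `eeg_events`.
#' @export
event_list <- function(onsets, labels, responses = integer(0)) {
  onsets <- as.numeric(onsets)
  labels <- as.character(labels)
  responses <- sort(as.numeric(responses))
  if (length(onsets) != length(labels)) {
    bench_abort("`onsets` and `labels` must have equal length", "eegbench_metadata_error")
  }
  if (length(onsets) > 1L && any(diff(onsets) <= 0)) {
    bench_abort("`onsets` must be strictly increasing", "eegbench_metadata_error")
  }
  if (length(onsets) && any(onsets < 0)) {
    bench_abort("`onsets` must be non-negative (0-based)", "eegbench_metadata_error")
  }
  bad <- setdiff(unique(labels), c("target", "non-target"))
  if (length(bad)) {
    bench_abort(sprintf("unknown event labels: %s", paste(bad, collapse = ", ")),
                "eegbench_metadata_error")
  }
  structure(list(onsets = onsets, labels = labels, responses = responses),
            class = "eeg_events")
}

#' @export
print.eeg_events <- function(x, ...) {
  cat(sprintf("<eeg_events> %d events (%d targets), %d button presses\n",
              length(x$onsets), sum(x$labels == "target"), length(x$responses)))
  invisible(x)
}

#' Set of epoched single trials
#'
#' Trials x channels x samples tensor with a mutable `keep_mask`: rejection
#' stages clear mask entries, they never delete trials, so counts and
#' provenance stay auditable.
#'
#' @param tensor 3-d numeric array, trials x channels x samples, uV.
#' @param epoch_times Numeric vector of sample times in seconds relative to
#'   stimulus onset (length = dim 3).
#' @param labels Per-trial class labels.
#' @param rate Sampling rate in Hz.
#' @param channel_labels Channel names (length = dim 2).
#' @param keep_mask Logical per-trial mask; defaults to all `TRUE`.
#' @return An object of class `eeg_epochs`.
#' @export
epoch_set <- function(tensor, epoch_times, labels, rate, channel_labels,
                      keep_mask = rep(TRUE, dim(tensor)[1])) {
  tensor <- as.array(tensor)
  if (length(dim(tensor)) != 3L) {
    bench_abort("`tensor` must be trials x channels x samples", "eegbench_metadata_error")
  }
  d <- dim(tensor)
  if (length(epoch_times) != d[3]) {
    bench_abort("`epoch_times` length must equal the sample dimension", "eegbench_metadata_error")
  }
  if (length(labels) != d[1] || length(keep_mask) != d[1]) {
    bench_abort("`labels` and `keep_mask` must have one entry per trial", "eegbench_metadata_error")
  }
  if (length(channel_labels) != d[2]) {
    bench_abort("`channel_labels` length must equal the channel dimension", "eegbench_metadata_error")
  }
  structure(
    list(tensor = tensor, epoch_times = as.numeric(epoch_times),
         labels = as.character(labels), keep_mask = as.logical(keep_mask),
         rate = rate, channel_labels = as.character(channel_labels)),
    class = "eeg_epochs"
  )
}

#' @export
print.eeg_epochs <- function(x, ...) {
  d <- dim(x$tensor)
  cat(sprintf(
    "<eeg_epochs> %d trials (%d kept) x %d channels x %d samples, t = [%.3f, %.3f] s\n",
    d[1], sum(x$keep_mask), d[2], d[3],
    min(x$epoch_times), max(x$epoch_times)
  ))
  invisible(x)
}

#' Number of kept trials in an epoch set
#' @param epochs An `eeg_epochs` object.
#' @param label Optional class restriction (`"target"` or `"non-target"`).
#' @return Integer count.
#' @export
n_kept <- function(epochs, label = NULL) {
  m <- epochs$keep_mask
  if (!is.null(label)) m <- m & epochs$labels == label
  sum(m)
}

#' Averaged ERP waveform for one stimulus class
#'
#' @param data Channels x samples matrix of the average, uV.
#' @param n_epochs Number of trials averaged (>= 1).
#' @param label Stimulus class the average belongs to.
#' @param epoch_times Seconds relative to stimulus onset.
#' @param channel_labels Channel names.
#' @return An object of class `eeg_erp`.
#' @export
erp_waveform <- function(data, n_epochs, label, epoch_times, channel_labels) {
  data <- as.matrix(data)
  if (n_epochs < 1L) bench_abort("`n_epochs` must be >= 1", "eegbench_empty_input_error")
  if (!all(is.finite(data))) bench_abort("ERP contains non-finite values", "eegbench_metadata_error")
  rownames(data) <- channel_labels
  structure(
    list(data = data, n_epochs = as.integer(n_epochs), label = label,
         epoch_times = as.numeric(epoch_times),
         channel_labels = as.character(channel_labels)),
    class = "eeg_erp"
  )
}

#' @export
print.eeg_erp <- function(x, ...) {
  cat(sprintf("<eeg_erp> '%s' average of %d epochs, %d channels x %d samples\n",
              x$label, x$n_epochs, nrow(x$data), ncol(x$data)))
  invisible(x)
}

# Unit-sphere positions for the 12-channel benchmark montage (x right,
# y anterior, z up; spherical-head convention).
.benchmark_positions <- rbind(
  Fpz = c(0.000,  1.000, 0.000),
  F3  = c(-0.545, 0.673, 0.500),
  Fz  = c(0.000,  0.707, 0.707),
  F4  = c(0.545,  0.673, 0.500),
  C3  = c(-0.707, 0.000, 0.707),
  Cz  = c(0.000,  0.000, 1.000),
  C4  = c(0.707,  0.000, 0.707),
  P3  = c(-0.545, -0.673, 0.500),
  Pz  = c(0.000, -0.707, 0.707),
  P4  = c(0.545, -0.673, 0.500),
  O1  = c(-0.309, -0.951, 0.000),
  O2  = c(0.309, -0.951, 0.000)
)

#' Benchmark electrode montage
#'
#' The 12-channel 10-20 subset common to the benchmarked systems (Fpz, F3, Fz,
#' F4, C3, Cz, C4, P3, Pz, P4, O1, O2) with unit-sphere positions used for
#' bad-channel interpolation weights.
#'
#' @param names Channel names; defaults to the 12 benchmark labels.
#' @param positions Numeric matrix (length(names) x 3) of unit-sphere
#'   coordinates; defaults to spherical-head 10-20 positions for the
#'   benchmark labels.
#' @return An object of class `eeg_montage` with elements `names`, `positions`.
#' @export
montage <- function(names = rownames(.benchmark_positions),
                    positions = NULL) {
  names <- as.character(names)
  if (is.null(positions)) {
    known <- match_channel(names, rownames(.benchmark_positions))
    if (anyNA(known)) {
      bench_abort(sprintf(
        "no stored position for channel(s): %s; supply `positions`",
        paste(names[is.na(known)], collapse = ", ")
      ), "eegbench_lookup_error")
    }
    positions <- .benchmark_positions[known, , drop = FALSE]
  }
  positions <- as.matrix(positions)
  if (nrow(positions) != length(names) || ncol(positions) != 3L) {
    bench_abort("`positions` must be a names x 3 matrix", "eegbench_metadata_error")
  }
  nrm <- sqrt(rowSums(positions^2))
  positions <- positions / ifelse(nrm > 0, nrm, 1)
  rownames(positions) <- names
  structure(list(names = names, positions = positions), class = "eeg_montage")
}

#' @export
print.eeg_montage <- function(x, ...) {
  cat(sprintf("<eeg_montage> %d channels: %s\n", length(x$names),
              paste(x$names, collapse = ", ")))
  invisible(x)
}

# case-insensitive 10-20 label matching (FPz == Fpz etc.)
match_channel <- function(wanted, have) {
  match(toupper(trimws(wanted)), toupper(trimws(have)))
}

#' Named EEG frequency bands
#'
#' Default bands are delta 1-4, theta 4-8, alpha 8-13, beta 13-30 and gamma
#' 30-80 Hz. Intervals are half-open `(lower, upper]` so adjacent bands never
#' share a frequency bin.
#'
#' @param ... Named length-2 numeric vectors, `name = c(lower, upper)` in Hz.
#'   When empty, the default five bands are returned.
#' @return An object of class `eeg_bands`: a named list of `c(lower, upper)`.
#' @examples
#' band_set()
#' band_set(theta = c(5, 8), alpha = c(9, 13))
#' @export
band_set <- function(...) {
  bands <- list(...)
  if (!length(bands)) {
    bands <- list(delta = c(1, 4), theta = c(4, 8), alpha = c(8, 13),
                  beta = c(13, 30), gamma = c(30, 80))
  }
  if (is.null(names(bands)) || any(names(bands) == "")) {
    bench_abort("every band must be named", "eegbench_parameter_error")
  }
  for (nm in names(bands)) {
    b <- bands[[nm]]
    if (length(b) != 2L || !all(is.finite(b)) || b[1] >= b[2] || b[1] < 0) {
      bench_abort(sprintf("band '%s' must be c(lower, upper) with 0 <= lower < upper", nm),
                  "eegbench_parameter_error")
    }
  }
  # pairwise overlap check on the half-open intervals
  nm <- names(bands)
  for (i in seq_along(bands)) {
    for (j in seq_along(bands)) {
      if (i < j) {
        a <- bands[[i]]; b <- bands[[j]]
        if (max(a[1], b[1]) < min(a[2], b[2])) {
          bench_abort(sprintf("bands '%s' and '%s' overlap", nm[i], nm[j]),
                      "eegbench_parameter_error")
        }
      }
    }
  }
  structure(bands, class = "eeg_bands")
}

#' @export
print.eeg_bands <- function(x, ...) {
  cat("<eeg_bands>\n")
  for (nm in names(x)) cat(sprintf("  %-6s (%g, %g] Hz\n", nm, x[[nm]][1], x[[nm]][2]))
  invisible(x)
}

#' Long-format metric table
#'
#' One row per (subject, system, condition, channel, metric) with a single
#' numeric value. Units by metric: PSN uV; SNR, CV_ERP, scalar products
#' unitless; band power uV^2/Hz.
#'
#' @param subject,system,condition,channel,metric Character keys (recycled).
#' @param value Numeric values.
#' @return A `data.frame` with class `eeg_metric_table` prepended.
#' @export
metric_table <- function(subject = character(), system = character(),
                         condition = character(), channel = character(),
                         metric = character(), value = numeric()) {
  df <- data.frame(subject = as.character(subject),
                   system = as.character(system),
                   condition = as.character(condition),
                   channel = as.character(channel),
                   metric = as.character(metric),
                   value = as.numeric(value),
                   stringsAsFactors = FALSE)
  key <- do.call(paste, c(df[c("subject", "system", "condition", "channel", "metric")],
                          sep = "\r"))
  if (anyDuplicated(key)) {
    bench_abort("duplicate (subject, system, condition, channel, metric) keys",
                "eegbench_metadata_error")
  }
  class(df) <- c("eeg_metric_table", class(df))
  df
}

#' Combine metric tables
#' @param ... `eeg_metric_table` objects.
#' @return A single `eeg_metric_table`.
#' @export
bind_metric_tables <- function(...) {
  parts <- lapply(list(...), function(x) as.data.frame(unclass(x)))
  out <- do.call(rbind, parts)
  metric_table(out$subject, out$system, out$condition, out$channel,
               out$metric, out$value)
}
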