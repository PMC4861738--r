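# File readers/writers. CSV dialect: header row of channel labels, one row
# per sample, sidecar JSON (<base>.json) carrying the sampling rate and
# optional events. EDF (16-bit) and BDF (24-bit, Biosemi) are written and read
# directly against the published format layout: 256-byte fixed header,
# 256 bytes per signal, then data records of little-endian integers scaled
# between the digital and physical ranges. Records are 1 s long; the true
# sample count is stored in the first signal's reserved field so padding added
# to complete the last record can be trimmed on read.

pad_field <- function(x, width) {
  s <- sprintf("%-*s", width, as.character(x))
  substr(s, 1L, width)
}

#' Read a continuous EEG recording
#'
#' @param path Path to a `.csv`, `.edf` or `.bdf` file.
#' @param format One of `"auto"` (by extension), `"csv"`, `"edf"`, `"bdf"`.
#' @return An [recording()] object in uV. For CSV, the sampling rate comes
#'   from the sidecar JSON (`<base>.json`); events stored there are attached
#'   as attribute `"events"`.
#' @export
read_recording <- function(path, format = c("auto", "csv", "edf", "bdf")) {
  format <- match.arg(format)
  if (!file.exists(path)) {
    bench_abort(sprintf("file not found: %s", path), "eegbench_format_error")
  }
  if (format == "auto") {
    format <- switch(tolower(tools::file_ext(path)),
      csv = "csv", edf = "edf", bdf = "bdf",
      bench_abort(sprintf("cannot infer format from extension of %s", path),
                  "eegbench_format_error")
    )
  }
  if (format == "csv") read_recording_csv(path) else read_edf_like(path, format)
}

read_recording_csv <- function(path) {
  df <- tryCatch(utils::read.csv(path, check.names = FALSE),
                 error = function(e) {
                   bench_abort(sprintf("cannot parse %s as CSV: %s",
                                       path, conditionMessage(e)),
                               "eegbench_format_error")
                 })
  if (ncol(df) == 0L) {
    bench_abort("CSV recording has zero channels", "eegbench_metadata_error")
  }
  sidecar <- paste0(tools::file_path_sans_ext(path), ".json")
  if (!file.exists(sidecar)) {
    bench_abort(sprintf("missing sidecar JSON with sampling rate: %s", sidecar),
                "eegbench_metadata_error")
  }
  side <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
  if (is.null(side$rate)) {
    bench_abort("sidecar JSON lacks a `rate` field", "eegbench_metadata_error")
  }
  rec <- recording(t(as.matrix(df)), rate = as.numeric(side$rate),
                   channel_labels = colnames(df),
                   meta = if (is.null(side$meta)) list() else as.list(side$meta))
  if (!is.null(side$events)) {
    attr(rec, "events") <- event_list(
      onsets = as.numeric(side$events$onsets),
      labels = as.character(side$events$labels),
      responses = as.numeric(side$events$responses %||% numeric(0))
    )
  }
  rec
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a recording as CSV plus JSON sidecar
#'
#' @param rec An [recording()].
#' @param path Output `.csv` path; the sidecar is written next to it.
#' @param events Optional [event_list()] stored in the sidecar.
#' @return `path`, invisibly.
#' @export
write_recording_csv <- function(rec, path, events = NULL) {
  df <- as.data.frame(t(rec$data))
  colnames(df) <- rec$channel_labels
  utils::write.csv(df, path, row.names = FALSE)
  side <- list(rate = rec$rate, meta = rec$meta)
  if (!is.null(events)) {
    side$events <- list(onsets = events$onsets, labels = events$labels,
                        responses = events$responses)
  }
  jsonlite::write_json(side, paste0(tools::file_path_sans_ext(path), ".json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Write a recording as EDF (16-bit) or BDF (24-bit)
#'
#' @param rec An [recording()]; the sampling rate must be a whole number of
#'   samples per second (records are 1 s long).
#' @param path Output path.
#' @param format `"bdf"` or `"edf"`.
#' @return `path`, invisibly.
#' @export
write_recording_edf <- function(rec, path, format = c("bdf", "edf")) {
  format <- match.arg(format)
  rate <- rec$rate
  if (abs(rate - round(rate)) > 1e-9) {
    bench_abort("EDF/BDF writing requires an integer sampling rate; use CSV",
                "eegbench_parameter_error")
  }
  rate <- as.integer(round(rate))
  nchan <- nrow(rec$data)
  nsamp <- ncol(rec$data)
  nrec <- ceiling(nsamp / rate)
  padded <- cbind(rec$data, matrix(0, nchan, nrec * rate - nsamp))

  dig_max <- if (format == "bdf") 8388607 else 32767
  dig_min <- -dig_max - 1L
  phys <- max(1, ceiling(max(abs(padded))))
  scale <- (dig_max - dig_min) / (2 * phys)
  dig <- round((padded + phys) * scale) + dig_min

  con <- file(path, "wb")
  on.exit(close(con))
  if (format == "bdf") {
    writeBin(as.raw(0xFF), con)
    writeChar(pad_field("BIOSEMI", 7), con, 7, eos = NULL)
  } else {
    writeChar(pad_field("0", 8), con, 8, eos = NULL)
  }
  hdr <- c(
    pad_field("X X X X", 80),                              # patient id
    pad_field("Startdate X X X X", 80),                    # recording id
    pad_field("01.01.00", 8), pad_field("00.00.00", 8),    # date, time
    pad_field(256 * (nchan + 1), 8),                       # header bytes
    pad_field(if (format == "bdf") "24BIT" else "", 44),
    pad_field(nrec, 8), pad_field(1, 8), pad_field(nchan, 4)
  )
  writeChar(paste(hdr, collapse = ""), con, sum(nchar(hdr)), eos = NULL)
  sig <- c(
    vapply(rec$channel_labels, pad_field, "", width = 16),
    rep(pad_field("", 80), nchan),                          # transducer
    rep(pad_field("uV", 8), nchan),
    rep(pad_field(-phys, 8), nchan), rep(pad_field(phys, 8), nchan),
    rep(pad_field(dig_min, 8), nchan), rep(pad_field(dig_max, 8), nchan),
    rep(pad_field("", 80), nchan),                          # prefilter
    rep(pad_field(rate, 8), nchan),
    c(pad_field(sprintf("NS=%d", nsamp), 32), rep(pad_field("", 32), nchan - 1))
  )
  writeChar(paste(sig, collapse = ""), con, 256L * nchan, eos = NULL)

  # record-major, channel blocks of `rate` samples inside each record
  blocks <- vector("list", nrec)
  for (r in seq_len(nrec)) {
    idx <- ((r - 1) * rate + 1):(r * rate)
    blocks[[r]] <- as.vector(t(dig[, idx, drop = FALSE]))
  }
  v <- unlist(blocks, use.names = FALSE)
  if (format == "edf") {
    writeBin(as.integer(v), con, size = 2L, endian = "little")
  } else {
    u <- v + ifelse(v < 0, 16777216, 0)
    b <- rbind(u %% 256, (u %/% 256) %% 256, u %/% 65536)
    writeBin(as.raw(b), con)
  }
  invisible(path)
}

read_edf_like <- function(path, format) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readBin(con, "raw", 8)
  is_bdf <- magic[1] == as.raw(0xFF)
  if (format == "bdf" && !is_bdf) {
    bench_abort(sprintf("%s lacks the BDF magic byte", path), "eegbench_format_error")
  }
  rd <- function(n) readChar(con, n, useBytes = TRUE)
  rd(80 + 80 + 8 + 8)                     # ids, date, time
  hdr_bytes <- as.integer(rd(8))
  rd(44)
  nrec <- as.integer(rd(8))
  dur <- as.numeric(rd(8))
  nchan <- as.integer(rd(4))
  if (is.na(nchan) || nchan < 1L) {
    bench_abort("file reports zero channels", "eegbench_metadata_error")
  }
  rds <- function(w) vapply(seq_len(nchan), function(i) rd(w), "")
  labels <- trimws(rds(16)); rds(80); rds(8)
  phys_min <- as.numeric(rds(8)); phys_max <- as.numeric(rds(8))
  dig_min <- as.numeric(rds(8)); dig_max <- as.numeric(rds(8))
  rds(80)
  spr <- as.integer(rds(8))
  reserved <- rds(32)
  if (anyNA(spr) || anyNA(phys_min) || is.na(dur) || dur <= 0) {
    bench_abort("malformed EDF/BDF header (missing rate metadata)",
                "eegbench_metadata_error")
  }
  if (length(unique(spr)) != 1L) {
    bench_abort("per-channel sampling rates are not supported", "eegbench_format_error")
  }
  seek(con, hdr_bytes)
  spr1 <- spr[1]
  total <- nrec * spr1 * nchan
  if (is_bdf) {
    b <- as.integer(readBin(con, "raw", total * 3L))
    u <- b[seq(1, length(b), 3)] + 256 * b[seq(2, length(b), 3)] +
      65536 * b[seq(3, length(b), 3)]
    v <- u - ifelse(u >= 8388608, 16777216, 0)
  } else {
    v <- readBin(con, "integer", total, size = 2L, signed = TRUE,
                 endian = "little")
  }
  # unpack record-major layout into channels x samples
  arr <- array(v, dim = c(spr1, nchan, nrec))
  data <- matrix(aperm(arr, c(2, 1, 3)), nrow = nchan)
  gain <- (phys_max - phys_min) / (dig_max - dig_min)
  data <- data * gain + (phys_min - dig_min * gain)
  ns_field <- regmatches(reserved[1], regexpr("NS=[0-9]+", reserved[1]))
  if (length(ns_field)) {
    nsamp <- as.integer(sub("NS=", "", ns_field))
    data <- data[, seq_len(nsamp), drop = FALSE]
  }
  recording(data, rate = spr1 / dur, channel_labels = labels,
            meta = list(source = basename(path)))
}

#' Write an event list as JSON
#' @param events An [event_list()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_events_json <- function(events, path) {
  jsonlite::write_json(
    list(onsets = events$onsets, labels = events$labels,
         responses = events$responses),
    path, auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}

#' Read an event list from JSON
#' @param path Path to a JSON file with `onsets`, `labels`, `responses`.
#' @return An [event_list()].
#' @export
read_events_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  event_list(as.numeric(x$onsets), as.character(x$labels),
             as.numeric(x$responses %||% numeric(0)))
}

#' Restrict a recording to a montage
#'
#' Selects the montage channels (case-insensitive 10-20 matching, so `FPz`
#' finds `Fpz`) and returns them in montage order. Idempotent and
#' order-normalizing.
#'
#' @param rec An [recording()].
#' @param mont An [montage()]; defaults to the 12-channel benchmark montage.
#' @return A [recording()] with channels in montage order.
#' @export
select_montage <- function(rec, mont = montage()) {
  idx <- match_channel(mont$names, rec$channel_labels)
  if (anyNA(idx)) {
    bench_abort(sprintf("channel(s) not present in recording: %s",
                        paste(mont$names[is.na(idx)], collapse = ", ")),
                "eegbench_lookup_error")
  }
  recording(rec$data[idx, , drop = FALSE], rec$rate,
            mont$names, rec$meta)
}

#' Write a metric table as CSV (with JSON schema sidecar)
#' @param table An [metric_table()].
#' @param path Output `.csv` path.
#' @return `path`, invisibly.
#' @export
write_metric_table <- function(table, path) {
  utils::write.csv(as.data.frame(unclass(table)), path, row.names = FALSE)
  schema <- list(
    columns = names(table),
    units = list(PSN = "uV", SNR = "unitless", CV_ERP = "unitless",
                 power = "uV^2/Hz", scalar_product = "[-1, 1]")
  )
  jsonlite::write_json(schema, paste0(tools::file_path_sans_ext(path), ".schema.json"),
                       auto_unbox = TRUE)
  invisible(path)
}

#' Read a metric table CSV
#' @param path Path written by [write_metric_table()].
#' @return An [metric_table()].
#' @export
read_metric_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  metric_table(df$subject, df$system, df$condition, df$channel, df$metric, df$value)
}
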