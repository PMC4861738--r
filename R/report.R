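# End-to-end orchestration: config-driven pipeline runs and condition
# comparison. The stage order is fixed: filter -> interpolate -> epoch ->
# behavioral rejection -> amplitude rejection (-> matched-count rejection
# with two conditions) -> metrics. Every report embeds the full effective
# configuration so a rerun is reproducible from the report alone.

default_config <- function() {
  list(
    subject = "S01", system = "synthetic",
    highpass_hz = 1.0, notch_hz = 60, notch_width = 2, notch_harmonics = 1,
    epoch_window = c(-0.3, 0.8), response_window_s = 1.4,
    threshold_uv = 75, sweep = seq(75, 400, by = 25), hist_bin = 25,
    psn_window = c(-0.3, 0), p300_window = c(0.3, 0.5),
    p2p_win_ms = 200, p2p_step_ms = 100,
    bands = band_set()
  )
}

load_config <- function(config) {
  if (is_string(config)) config <- jsonlite::read_json(config, simplifyVector = TRUE)
  base <- default_config()
  for (nm in names(config)) base[[nm]] <- config[[nm]]
  if (!inherits(base$bands, "eeg_bands")) {
    base$bands <- do.call(band_set, lapply(base$bands, as.numeric))
  }
  base
}

run_condition <- function(name, rec, events, bad, cfg, mont) {
  rec <- select_montage(rec, mont)
  rec <- highpass(rec, cfg$highpass_hz)
  rec <- notch(rec, cfg$notch_hz, cfg$notch_width, cfg$notch_harmonics)
  rec <- interpolate_channels(rec, bad, mont)
  epochs <- extract_epochs(rec, events, cfg$epoch_window)
  epochs <- behavioral_reject(epochs, events, cfg$response_window_s)
  curve <- threshold_sweep(epochs, cfg$sweep, cfg$p2p_win_ms, cfg$p2p_step_ms)
  hist <- amplitude_histogram(epochs, cfg$hist_bin, cfg$p2p_win_ms, cfg$p2p_step_ms)
  epochs <- reject_threshold(epochs, cfg$threshold_uv, cfg$p2p_win_ms, cfg$p2p_step_ms)
  list(name = name, epochs = epochs, curve = curve, histogram = hist,
       n_false_positive = attr(epochs, "n_false_positive") %||% NA,
       behavioral = epochs)
}

condition_metrics <- function(cond, cfg) {
  epochs <- cond$epochs
  psn_t <- psn(epochs, cfg$psn_window, label = "target")
  erp_t <- average_erp(epochs, "target")
  snr_v <- snr(erp_t, psn_t, cfg$p300_window)
  cv <- cv_erp(epochs, cfg$p300_window, label = "target")
  bp <- band_power(epochs, cfg$bands)
  channels <- epochs$channel_labels
  rows <- list(
    metric_table(cfg$subject, cfg$system, cond$name, channels, "PSN",
                 psn_t$channel_mean),
    metric_table(cfg$subject, cfg$system, cond$name, channels, "SNR", snr_v),
    metric_table(cfg$subject, cfg$system, cond$name, channels, "CV_ERP",
                 cv$per_channel)
  )
  for (nm in names(cfg$bands)) {
    rows[[length(rows) + 1L]] <- metric_table(
      cfg$subject, cfg$system, cond$name, channels,
      paste0("power_", nm), bp$per_channel[nm, ]
    )
  }
  list(table = do.call(bind_metric_tables, rows),
       erp_target = erp_t, erp_nontarget = tryCatch(
         average_erp(epochs, "non-target"), error = function(e) NULL),
       band_power = bp, psn = psn_t)
}

#' Run the full benchmark pipeline
#'
#' Executes filtering, epoching, behavioral and amplitude rejection and the
#' metric suite for one or two conditions, plus matched-count rejection, the
#' Ratio W/S and scalar-product ERP similarity when two conditions (e.g.
#' seated and walking) are given.
#'
#' @param config Named list or path to a JSON config. Recognized keys (with
#'   defaults): `subject`, `system`, `highpass_hz` (1), `notch_hz` (60),
#'   `notch_width` (2), `notch_harmonics` (1), `epoch_window` (`c(-0.3, 0.8)`),
#'   `response_window_s` (1.4), `threshold_uv` (75), `sweep` (75-400 by 25),
#'   `hist_bin` (25), `psn_window`, `p300_window`, `bands`, and `conditions`:
#'   a list of entries with `name`, `recording` (path), `events` (path) and
#'   optional `bad_channels`.
#' @param sessions Optional named list of in-memory sessions
#'   (`list(recording =, events =, bad_channels =)`) overriding the config's
#'   file paths; names become condition names.
#' @param mont An [montage()].
#' @return An object of class `eeg_benchmark`: list with `metrics`
#'   ([metric_table()]), `curves`, `histograms`, `similarity`, `ratio_ws`,
#'   `erps`, `epochs`, and `log` (the effective configuration and rejection
#'   bookkeeping).
#' @export
run_benchmark <- function(config = list(), sessions = NULL, mont = montage()) {
  cfg <- load_config(config)
  if (is.null(sessions)) {
    if (is.null(cfg$conditions)) {
      bench_abort("config must name input conditions (or pass `sessions`)",
                  "eegbench_parameter_error")
    }
    conds <- cfg$conditions
    if (is.data.frame(conds)) conds <- split(conds, seq_len(nrow(conds)))
    sessions <- lapply(conds, function(cn) {
      rec <- read_recording(cn$recording)
      ev <- if (!is.null(cn$events)) read_events_json(cn$events)
            else attr(rec, "events")
      if (is.null(ev)) {
        bench_abort(sprintf("condition '%s' has no events", cn$name),
                    "eegbench_metadata_error")
      }
      list(recording = rec, events = ev,
           bad_channels = as.character(cn$bad_channels %||% character(0)),
           name = cn$name)
    })
    names(sessions) <- vapply(sessions, `[[`, "", "name")
  }
  if (!length(sessions) || length(sessions) > 2L) {
    bench_abort("run_benchmark handles one or two conditions", "eegbench_parameter_error")
  }

  conds <- lapply(names(sessions), function(nm) {
    s <- sessions[[nm]]
    tryCatch(
      run_condition(nm, s$recording, s$events,
                    s$bad_channels %||% character(0), cfg, mont),
      error = function(e) {
        stop(sprintf("[condition %s] %s", nm, conditionMessage(e)), call. = FALSE)
      }
    )
  })
  names(conds) <- names(sessions)

  if (length(conds) == 2L) {
    matched <- match_rejection(conds[[1]]$epochs, conds[[2]]$epochs,
                               cfg$p2p_win_ms, cfg$p2p_step_ms)
    conds[[1]]$epochs <- matched$a
    conds[[2]]$epochs <- matched$b
  }

  per_cond <- lapply(conds, function(cn) {
    tryCatch(condition_metrics(cn, cfg), error = function(e) {
      stop(sprintf("[condition %s, metrics] %s", cn$name, conditionMessage(e)),
           call. = FALSE)
    })
  })
  metrics <- do.call(bind_metric_tables, lapply(per_cond, `[[`, "table"))

  similarity <- NULL
  ratio <- NULL
  if (length(conds) == 2L) {
    sim_rows <- list()
    for (cls in c("target", "non-target")) {
      ea <- if (cls == "target") per_cond[[1]]$erp_target else per_cond[[1]]$erp_nontarget
      eb <- if (cls == "target") per_cond[[2]]$erp_target else per_cond[[2]]$erp_nontarget
      if (is.null(ea) || is.null(eb)) next
      r <- scalar_similarity(ea, eb)
      sim_rows[[cls]] <- data.frame(
        class = cls, channel = names(r), r = as.numeric(r),
        z = atanh(pmin(pmax(as.numeric(r), -1 + 1e-7), 1 - 1e-7))
      )
    }
    similarity <- do.call(rbind, sim_rows)
    rownames(similarity) <- NULL
    attr(similarity, "fisher_average") <- fisher_average(similarity$r)
    ratio <- ratio_ws(per_cond[[2]]$band_power, per_cond[[1]]$band_power)
  }

  structure(
    list(
      metrics = metrics,
      curves = stats::setNames(lapply(conds, `[[`, "curve"), names(conds)),
      histograms = stats::setNames(lapply(conds, `[[`, "histogram"), names(conds)),
      similarity = similarity,
      ratio_ws = ratio,
      erps = lapply(per_cond, function(p) list(target = p$erp_target,
                                               nontarget = p$erp_nontarget)),
      epochs = lapply(conds, `[[`, "epochs"),
      log = list(
        config = cfg[setdiff(names(cfg), "conditions")],
        conditions = names(conds),
        kept = vapply(conds, function(cn) sum(cn$epochs$keep_mask), 0),
        total = vapply(conds, function(cn) dim(cn$epochs$tensor)[1], 0)
      )
    ),
    class = "eeg_benchmark"
  )
}

#' @export
print.eeg_benchmark <- function(x, ...) {
  cat(sprintf("<eeg_benchmark> conditions: %s\n",
              paste(x$log$conditions, collapse = ", ")))
  cat(sprintf("  kept epochs: %s of %s\n",
              paste(x$log$kept, collapse = "/"),
              paste(x$log$total, collapse = "/")))
  if (!is.null(x$similarity)) {
    cat(sprintf("  ERP similarity (Fisher-averaged r): %.3f\n",
                attr(x$similarity, "fisher_average")))
  }
  invisible(x)
}

#' Write a benchmark report to disk
#'
#' Long-format CSVs plus a JSON run log holding the effective configuration.
#' Output is byte-stable under identical inputs and seeds.
#'
#' @param report An `eeg_benchmark` from [run_benchmark()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_benchmark <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_metric_table(report$metrics, file.path(dir, "metrics.csv"))
  for (nm in names(report$curves)) {
    utils::write.csv(as.data.frame(report$curves[[nm]]),
                     file.path(dir, sprintf("rejection_%s.csv", nm)),
                     row.names = FALSE)
    utils::write.csv(report$histograms[[nm]],
                     file.path(dir, sprintf("histogram_%s.csv", nm)),
                     row.names = FALSE)
  }
  if (!is.null(report$similarity)) {
    utils::write.csv(report$similarity, file.path(dir, "similarity.csv"),
                     row.names = FALSE)
  }
  if (!is.null(report$ratio_ws)) {
    utils::write.csv(data.frame(band = names(report$ratio_ws),
                                ratio_ws = as.numeric(report$ratio_ws)),
                     file.path(dir, "ratio_ws.csv"), row.names = FALSE)
  }
  log <- report$log
  log$config$bands <- lapply(unclass(log$config$bands), as.numeric)
  jsonlite::write_json(log, file.path(dir, "run_log.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Percent change between two metric tables
#'
#' `100 * |a - b| / a` per (channel, metric) pair, plus a channel-averaged
#' summary per metric -- the absolute-percent-change view of a
#' seated-vs-walking contrast. Division by a zero baseline yields `Inf`.
#'
#' @param table_a Baseline [metric_table()] (e.g. seated).
#' @param table_b Comparison [metric_table()] (e.g. walking).
#' @return List with `per_channel` data.frame (`channel`, `metric`,
#'   `pct_change`) and `summary` (named per-metric means).
#' @export
compare_conditions <- function(table_a, table_b) {
  key <- function(df) paste(df$channel, df$metric, sep = "\r")
  ka <- key(table_a)
  kb <- key(table_b)
  if (!setequal(ka, kb) || length(ka) != length(kb)) {
    bench_abort("metric tables do not share (channel, metric) keys",
                "eegbench_alignment_error")
  }
  b <- table_b[match(ka, kb), ]
  pct <- 100 * abs(table_a$value - b$value) / table_a$value
  per_channel <- data.frame(channel = table_a$channel, metric = table_a$metric,
                            pct_change = pct)
  summary <- tapply(pct, table_a$metric, mean)
  list(per_channel = per_channel, summary = summary)
}
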