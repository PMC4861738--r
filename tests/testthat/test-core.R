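test_that("recording enforces its invariants", {
  expect_error(recording(matrix(1, 2, 10), 500, "onlyone"),
               class = "eegbench_metadata_error")
  expect_error(recording(matrix(c(1, NA), 1, 2), 500, "Cz"),
               class = "eegbench_metadata_error")
  expect_error(recording(matrix(1, 1, 5), -1, "Cz"),
               class = "eegbench_parameter_error")
  expect_error(recording(matrix(numeric(0), 0, 0), 500, character(0)),
               class = "eegbench_metadata_error")
})

test_that("event_list enforces ordering and label vocabulary", {
  expect_error(event_list(c(10, 5), c("target", "target")),
               class = "eegbench_metadata_error")
  expect_error(event_list(c(5, 10), c("target", "oops")),
               class = "eegbench_metadata_error")
  expect_error(event_list(5, c("target", "non-target")),
               class = "eegbench_metadata_error")
  ev <- event_list(c(5, 10), c("target", "non-target"), responses = c(30, 8))
  expect_equal(ev$responses, c(8, 30))  # stored sorted
})

test_that("select_montage downselects to 12 channels in canonical order", {
  mont <- montage()
  extra <- c("EXG1", "M1")
  labels <- c(extra, sample(toupper(mont$names)))   # shuffled, wrong case
  set.seed(1)
  rec <- recording(matrix(rnorm(14 * 100), 14, 100), 500, labels)
  out <- select_montage(rec, mont)
  expect_identical(out$channel_labels, mont$names)
  expect_equal(nrow(out$data), 12L)
  # rows really moved with their labels
  src <- match(toupper(mont$names), labels)
  expect_equal(unname(out$data), unname(rec$data[src, ]))
  # idempotent / order-normalizing
  again <- select_montage(out, mont)
  expect_identical(again$data, out$data)
  bad_mont <- montage(c("Cz", "XX9"),
                      positions = matrix(c(0, 0, 1, 1, 0, 0), 2, 3, byrow = TRUE))
  expect_error(select_montage(rec, bad_mont), class = "eegbench_lookup_error")
})

test_that("CSV recordings round-trip with rate and events", {
  set.seed(42)
  rec <- recording(matrix(rnorm(2 * 1000), 2, 1000), 500, c("Cz", "Pz"))
  ev <- event_list(c(100, 400, 700), c("target", "non-target", "target"),
                   responses = 350)
  path <- file.path(tempdir(), "roundtrip.csv")
  write_recording_csv(rec, path, events = ev)
  back <- read_recording(path)
  expect_equal(dim(back$data), c(2L, 1000L))
  expect_equal(back$rate, 500)
  expect_equal(unname(back$data), unname(rec$data), tolerance = 1e-12)
  ev2 <- attr(back, "events")
  expect_equal(ev2$onsets, ev$onsets)
  expect_equal(ev2$labels, ev$labels)
})

test_that("BDF and EDF writing round-trips within one quantization step", {
  set.seed(7)
  rec <- recording(matrix(rnorm(3 * 1234, sd = 40), 3, 1234), 500,
                   c("Cz", "Pz", "Fz"))
  for (fmt in c("bdf", "edf")) {
    path <- file.path(tempdir(), paste0("rt.", fmt))
    write_recording_edf(rec, path, fmt)
    back <- read_recording(path)
    expect_identical(back$channel_labels, rec$channel_labels)
    expect_equal(back$rate, 500)
    expect_equal(ncol(back$data), 1234L)   # padding trimmed
    phys <- max(1, ceiling(max(abs(rec$data))))
    lsb <- 2 * phys / (if (fmt == "bdf") 2^24 - 1 else 2^16 - 1)
    expect_lt(max(abs(back$data - rec$data)), lsb)
  }
})

test_that("degenerate recording files raise format/metadata errors", {
  empty <- file.path(tempdir(), "empty.csv")
  writeLines("", empty)
  expect_error(read_recording(empty), class = "eegbench_error")
  noside <- file.path(tempdir(), "nosidecar.csv")
  utils::write.csv(data.frame(Cz = 1:5), noside, row.names = FALSE)
  expect_error(read_recording(noside), class = "eegbench_metadata_error")
  expect_error(read_recording(file.path(tempdir(), "nothere.bdf")),
               class = "eegbench_format_error")
})

test_that("band_set validates and defaults include gamma 30-80 Hz", {
  b <- band_set()
  expect_named(b, c("delta", "theta", "alpha", "beta", "gamma"))
  expect_equal(b$gamma, c(30, 80))
  expect_error(band_set(a = c(1, 10), b = c(5, 15)),
               class = "eegbench_parameter_error")
  expect_error(band_set(a = c(10, 5)), class = "eegbench_parameter_error")
  expect_error(band_set(c(1, 4)), class = "eegbench_parameter_error")
})

test_that("metric tables reject duplicate keys and round-trip as CSV", {
  expect_error(
    metric_table(subject = c("s", "s"), system = c("x", "x"),
                 condition = c("seated", "seated"), channel = c("Cz", "Cz"),
                 metric = c("PSN", "PSN"), value = c(1, 2)),
    class = "eegbench_metadata_error"
  )
  tb <- metric_table("s1", "wet", "seated", c("Cz", "Pz"), "PSN", c(4.5, 5.5))
  path <- file.path(tempdir(), "metrics.csv")
  write_metric_table(tb, path)
  back <- read_metric_table(path)
  expect_equal(back$value, tb$value)
  expect_equal(back$channel, tb$channel)
})

test_that("events JSON round-trips", {
  ev <- event_list(c(0, 500, 1000), c("target", "non-target", "target"),
                   responses = c(250, 1200))
  path <- file.path(tempdir(), "events.json")
  write_events_json(ev, path)
  back <- read_events_json(path)
  expect_equal(back$onsets, ev$onsets)
  expect_equal(back$labels, ev$labels)
  expect_equal(back$responses, ev$responses)
})
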