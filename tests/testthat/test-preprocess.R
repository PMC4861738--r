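test_that("high-pass removes DC and matches its designed response", {
  rate <- 500
  # constant 50 uV -> essentially zero out
  rec <- recording(matrix(50, 2, 5 * rate), rate, c("Cz", "Pz"))
  out <- highpass(rec)
  trim <- (rate + 1):(4 * rate)
  expect_lt(max(abs(out$data[, trim])), 0.1)

  # frequency-response oracle: 0.1 Hz lands ~1e-4 down per pass, 10 Hz passes
  co <- butter_highpass(4, 1, rate)
  expect_lt(abs(filter_response(co, 0.1, rate)), 1e-3)
  expect_gt(abs(filter_response(co, 10, rate)), 0.999)
  expect_equal(abs(filter_response(co, 1, rate)), sqrt(0.5), tolerance = 1e-6)

  t <- (0:(60 * rate - 1)) / rate
  slow <- recording(matrix(10 * sin(2 * pi * 0.1 * t), 1, length(t)), rate, "Cz")
  fast <- recording(matrix(10 * sin(2 * pi * 10 * t), 1, length(t)), rate, "Cz")
  trim <- (5 * rate):(55 * rate)
  rms <- function(x) sqrt(mean(x^2))
  ratio <- rms(highpass(slow)$data[1, trim]) / rms(highpass(fast)$data[1, trim])
  expect_lt(ratio, 0.1)
  expect_error(highpass(rec, cutoff = 300), class = "eegbench_parameter_error")
})

test_that("notch suppresses the line frequency and spares neighbors", {
  rate <- 500
  t <- (0:(20 * rate - 1)) / rate
  rms <- function(x) sqrt(mean(x^2))
  trim <- (2 * rate):(18 * rate)

  line <- recording(matrix(20 * sin(2 * pi * 60 * t), 1, length(t)), rate, "Cz")
  out <- notch(line, 60)
  expect_lt(rms(out$data[1, trim]) / rms(line$data[1, trim]), 0.1)

  alpha <- recording(matrix(20 * sin(2 * pi * 10 * t), 1, length(t)), rate, "Cz")
  out <- notch(alpha, 60)
  expect_lt(abs(rms(out$data[1, trim]) / rms(alpha$data[1, trim]) - 1), 0.02)

  # response contract: >= 20 dB at line freq, < 1 dB at +/- 5 Hz outside width
  co <- design_notch(60, 2, rate)
  att <- function(f) -20 * log10(abs(filter_response(co, f, rate))^2)  # two passes
  expect_gt(att(60), 20)
  expect_lt(att(66), 1)
  expect_lt(att(54), 1)

  expect_error(notch(line, 300), class = "eegbench_parameter_error")
})

test_that("filtering is linear", {
  rate <- 500
  set.seed(11)
  x <- rnorm(4000)
  y <- rnorm(4000)
  f <- function(v) highpass(recording(matrix(v, 1, length(v)), rate, "Cz"))$data[1, ]
  lhs <- f(2 * x - 3 * y)
  rhs <- 2 * f(x) - 3 * f(y)
  expect_equal(lhs, rhs, tolerance = 1e-8)
})

test_that("interpolation reconstructs from inverse-distance weights", {
  mont <- montage()
  rec <- make_sine_recording()

  # identical signals on every channel -> bad channel reproduced exactly
  same <- recording(matrix(rep(rec$data[1, ], 12), 12, ncol(rec$data),
                           byrow = TRUE), rec$rate, mont$names)
  out <- interpolate_channels(same, "Cz", mont)
  expect_equal(out$data["Cz", ], same$data["Pz", ], tolerance = 1e-12)

  # empty bad list is the identity
  expect_identical(interpolate_channels(rec, character(0), mont)$data, rec$data)

  # hand-computed weights from the stored positions (independent oracle)
  out <- interpolate_channels(rec, "Pz", mont)
  good <- setdiff(mont$names, "Pz")
  d <- sqrt(rowSums((mont$positions[good, ] -
                       matrix(mont$positions["Pz", ], 11, 3, byrow = TRUE))^2))
  w <- (1 / d^2) / sum(1 / d^2)
  expect_equal(out$data["Pz", ], as.vector(w %*% rec$data[good, ]),
               tolerance = 1e-12)
  # good channels untouched
  expect_identical(out$data["Cz", ], rec$data["Cz", ])

  expect_error(interpolate_channels(rec, mont$names[1:10], mont),
               class = "eegbench_interpolation_error")
})

test_that("epoch extraction uses the half-open sample window", {
  rate <- 500
  nsamp <- 4000
  rec <- recording(matrix(seq_len(2 * nsamp), 2, nsamp, byrow = TRUE),
                   rate, c("Cz", "Pz"))
  ev <- event_list(c(500, 1500), c("target", "non-target"))
  ep <- extract_epochs(rec, ev)
  expect_equal(dim(ep$tensor), c(2L, 2L, 550L))
  expect_equal(ep$epoch_times[151], 0)          # onset sample at 0-based 150
  expect_equal(ep$epoch_times[1], -0.3)
  expect_equal(max(ep$epoch_times), 0.8 - 1 / rate)
  # pure slicing, bit-exact: epoch 1 channel 1 starts at 0-based 500-150=350
  expect_identical(ep$tensor[1, 1, ], rec$data[1, 351:900])
  expect_identical(ep$tensor[2, 2, ], rec$data[2, 1351:1900])

  # zero events
  ep0 <- extract_epochs(rec, event_list(numeric(0), character(0)))
  expect_equal(dim(ep0$tensor)[1], 0L)

  # edge events dropped with a warning, not an error
  ev_edge <- event_list(c(100, 1500, 3900), rep("target", 3))
  expect_warning(ep2 <- extract_epochs(rec, ev_edge), "edge")
  expect_equal(dim(ep2$tensor)[1], 1L)
})

test_that("behavioral rejection drops false positives and false negatives", {
  rate <- 500
  rec <- recording(matrix(0, 1, 10000), rate, "Cz")
  onsets <- c(1000, 2000, 3000, 4000)
  labels <- c("target", "non-target", "target", "non-target")
  # presses after trials 1 and 2 only -> trial 3 is a missed target (FN),
  # trial 2 a false press (FP); keep = {1, 4}
  ev <- event_list(onsets, labels, responses = c(1200, 2200))
  ep <- behavioral_reject(extract_epochs(rec, ev), ev)
  expect_equal(ep$keep_mask, c(TRUE, FALSE, FALSE, TRUE))
  expect_equal(attr(ep, "n_false_positive"), 1L)
  expect_equal(attr(ep, "n_false_negative"), 1L)

  # all targets answered, no spurious presses -> unchanged
  ev_ok <- event_list(onsets, labels, responses = c(1200, 3300))
  ep_ok <- behavioral_reject(extract_epochs(rec, ev_ok), ev_ok)
  expect_true(all(ep_ok$keep_mask))

  # never increases the kept count (property over random response sets)
  set.seed(5)
  for (i in 1:10) {
    ev_r <- event_list(onsets, labels,
                       responses = sort(sample(500:9000, sample(0:5, 1))))
    before <- extract_epochs(rec, ev_r)
    before$keep_mask[1] <- FALSE
    after <- behavioral_reject(before, ev_r)
    expect_lte(sum(after$keep_mask), sum(before$keep_mask))
    expect_false(any(after$keep_mask & !before$keep_mask))
  }
})
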