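test_that("PSN closed forms hold", {
  rate <- 500
  nsamp <- 550
  t <- -0.3 + (seq_len(nsamp) - 1) / rate

  zero <- make_epochs(list(matrix(0, 2, nsamp)))
  expect_equal(psn(zero)$grand_mean, 0)

  const <- make_epochs(list(matrix(5, 2, nsamp)))
  expect_equal(psn(const)$grand_mean, 5)
  expect_equal(unname(psn(const)$channel_mean), c(5, 5))

  # sinusoid of amplitude a over the pre-stimulus window -> a / sqrt(2)
  a <- 12
  sine <- make_epochs(list(matrix(a * sin(2 * pi * 10 * t), 1, nsamp)))
  expect_equal(psn(sine)$grand_mean, a / sqrt(2), tolerance = 0.02 * a)

  empty <- zero
  empty$keep_mask[] <- FALSE
  expect_error(psn(empty), class = "eegbench_empty_input_error")
})

test_that("band power concentrates, scales quadratically, stays non-negative", {
  rate <- 500
  nsamp <- 550
  t <- (seq_len(nsamp) - 1) / rate
  waves <- lapply(1:4, function(i) matrix(20 * sin(2 * pi * 10 * t + i), 1, nsamp))
  bp <- band_power(make_epochs(waves))
  # the 128-sample default window resolves ~4 Hz, so with the defaults the
  # 10 Hz tone dominates but leaks into theta; alpha still wins every band
  expect_true(all(bp$average["alpha"] > bp$average[c("delta", "theta", "beta", "gamma")]))
  expect_true(all(bp$average >= 0))

  # with an adequately resolved estimator the tone concentrates >= 10x
  long_t <- (seq_len(1000) - 1) / rate
  long <- lapply(1:4, function(i) matrix(20 * sin(2 * pi * 10 * long_t + i), 1, 1000))
  bp_hi <- band_power(make_epochs(long), seglen = 500, nfft = 1024)
  expect_gt(bp_hi$average["alpha"],
            10 * max(bp_hi$average[c("delta", "theta", "beta", "gamma")]))

  doubled <- band_power(make_epochs(lapply(waves, `*`, 2)))
  expect_equal(unname(doubled$average / bp$average), rep(4, 5), tolerance = 0.01)

  # band above Nyquist rejected
  slow <- make_epochs(waves, rate = 100)
  expect_error(band_power(slow), class = "eegbench_parameter_error")

  # white-noise PSD is flat across bands (160 epochs, fixed seed)
  set.seed(61)
  wn <- make_epochs(lapply(1:160, function(i) matrix(rnorm(nsamp, sd = 10), 1, nsamp)))
  bpw <- band_power(wn)
  expect_lt(max(bpw$average) / min(bpw$average), 2)
})

test_that("Ratio W/S is a linear power ratio", {
  rate <- 500
  set.seed(62)
  waves <- lapply(1:6, function(i) matrix(rnorm(550, sd = 10), 1, 550))
  seat <- band_power(make_epochs(waves))
  expect_equal(unname(ratio_ws(seat, seat)), rep(1, 5))
  walk <- band_power(make_epochs(lapply(waves, function(w) w * sqrt(2))))
  expect_equal(unname(ratio_ws(walk, seat)), rep(2, 5), tolerance = 1e-9)
})

test_that("ERP averaging is the pointwise mean of kept trials", {
  set.seed(63)
  x <- matrix(rnorm(550), 1, 550)
  single <- average_erp(make_epochs(list(x)), "target")
  expect_equal(single$data[1, ], x[1, ])
  expect_equal(single$n_epochs, 1L)

  sym <- average_erp(make_epochs(list(x, -x)), "target")
  expect_equal(max(abs(sym$data)), 0)

  # averaging N noisy copies of a template shrinks the error ~ sigma/sqrt(N)
  template <- 10 * exp(-0.5 * ((1:550 - 350) / 30)^2)
  err <- vapply(c(10, 40, 160), function(n) {
    waves <- lapply(seq_len(n), function(i) {
      matrix(template + rnorm(550, sd = 8), 1, 550)
    })
    max(abs(average_erp(make_epochs(waves), "target")$data[1, ] - template))
  }, numeric(1))
  expect_true(all(diff(err) < 0))
  expect_lt(err[3], err[1] / 2)

  expect_error(average_erp(make_epochs(list(x)), "non-target"),
               class = "eegbench_empty_input_error")
})

test_that("SNR divides the P300 peak by the trial-averaged PSN", {
  rate <- 500
  nsamp <- 550
  t <- -0.3 + (seq_len(nsamp) - 1) / rate
  bump <- function(peak) peak * exp(-0.5 * ((t - 0.4) / 0.05)^2) * (t > 0)
  pre <- as.numeric(t < 0)

  # trial = constant 10 uV pre-stimulus noise + bump of 10 -> SNR 1
  w <- matrix(bump(10) + 10 * pre, 1, nsamp)
  ep <- make_epochs(list(w, w))
  s <- snr(average_erp(ep, "target"), psn(ep, label = "target"))
  expect_equal(as.numeric(s), 1, tolerance = 1e-6)

  # peak 20, PSN 5 -> SNR 4
  w2 <- matrix(bump(20) + 5 * pre, 1, nsamp)
  ep2 <- make_epochs(list(w2))
  s2 <- snr(average_erp(ep2, "target"), psn(ep2, label = "target"))
  expect_equal(as.numeric(s2), 4, tolerance = 1e-6)

  # the signed peak is read inside 300-500 ms only
  outside <- matrix(bump(10) + 50 * exp(-0.5 * ((t - 0.1) / 0.02)^2) * (t > 0) +
                      10 * pre, 1, nsamp)
  ep3 <- make_epochs(list(outside))
  s3 <- snr(average_erp(ep3, "target"), psn(ep3, label = "target"))
  expect_equal(as.numeric(s3), 1, tolerance = 1e-6)

  # zero PSN -> division error
  ep4 <- make_epochs(list(matrix(bump(10), 1, nsamp)))
  expect_error(snr(average_erp(ep4, "target"), psn(ep4, label = "target")),
               class = "eegbench_division_error")
})

test_that("cv_trial and cv_erp follow the sd/mean definition", {
  expect_equal(cv_trial(rep(4, 20)), 0)
  expect_equal(cv_trial(c(1, 3)), sqrt(2) / 2, tolerance = 1e-10)  # sd n-1
  expect_true(is.na(cv_trial(c(-1, 1))))
  expect_equal(cv_trial(c(1, 3), use_variance = TRUE), 1)

  # two trials with CVs 0.2 and 0.4 -> CV_ERP 0.3 (exact construction)
  two_sample <- function(mean, cv) {
    h <- cv * mean / sqrt(2)
    c(mean - h, mean + h)
  }
  ep <- make_epochs(list(matrix(two_sample(10, 0.2), 1, 2),
                         matrix(two_sample(10, 0.4), 1, 2)),
                    rate = 10, t0 = 0.35)
  cv <- cv_erp(ep, window = c(0.3, 0.5))
  expect_equal(cv$overall, 0.3, tolerance = 1e-10)

  # identical trials -> CV_ERP equals the single-trial CV
  ep1 <- make_epochs(rep(list(matrix(c(1, 3), 1, 2)), 3), rate = 10, t0 = 0.35)
  expect_equal(cv_erp(ep1, c(0.3, 0.5))$overall, sqrt(2) / 2, tolerance = 1e-10)

  # undefined trials are excluded and counted
  ep2 <- make_epochs(list(matrix(c(-1, 1), 1, 2), matrix(c(1, 3), 1, 2)),
                     rate = 10, t0 = 0.35)
  cv2 <- cv_erp(ep2, c(0.3, 0.5))
  expect_equal(sum(cv2$n_undefined), 1L)
  expect_equal(cv2$overall, sqrt(2) / 2, tolerance = 1e-10)

  # rising noise at a fixed template raises CV_ERP (fixed seed, 3 levels)
  set.seed(64)
  cvs <- vapply(c(1, 3, 6), function(sd) {
    waves <- lapply(1:80, function(i) matrix(10 + rnorm(101, sd = sd), 1, 101))
    cv_erp(make_epochs(waves, rate = 500, t0 = 0.3), c(0.3, 0.5))$overall
  }, numeric(1))
  expect_true(all(diff(cvs) > 0))
})

test_that("scalar similarity is Pearson r on the waveforms", {
  mk <- function(v, label = "target") {
    erp_waveform(matrix(v, 1), 1, label, seq_along(v), "Cz")
  }
  expect_equal(unname(scalar_similarity(mk(c(1, 5, 2, 8)), mk(c(1, 5, 2, 8)))), 1)
  expect_equal(unname(scalar_similarity(mk(c(1, 5, 2, 8)), mk(-c(1, 5, 2, 8)))), -1)
  expect_equal(unname(scalar_similarity(mk(c(1, 2, 3)), mk(c(1, 2, 4)))),
               0.9819805, tolerance = 1e-6)

  # symmetry and positive-scale invariance
  set.seed(65)
  a <- mk(rnorm(50)); b <- mk(rnorm(50))
  expect_equal(scalar_similarity(a, b), scalar_similarity(b, a))
  b3 <- mk(3.7 * b$data[1, ])
  expect_equal(scalar_similarity(a, b), scalar_similarity(a, b3), tolerance = 1e-12)
  expect_true(abs(scalar_similarity(a, b)) <= 1)

  # zero-variance waveform -> NA sentinel
  expect_true(is.na(scalar_similarity(mk(rep(2, 5)), mk(c(1, 2, 3, 4, 5)))))
  expect_error(scalar_similarity(mk(1:4), mk(1:5)), class = "eegbench_alignment_error")
})

test_that("fisher_average back-transforms the mean z", {
  expect_equal(fisher_average(0.62), 0.62)
  expect_equal(fisher_average(rep(0, 5)), 0)
  expect_equal(fisher_average(c(0.5, 0.5)), 0.5)
  expect_equal(fisher_average(c(0, 0.8)), tanh(atanh(0.8) / 2), tolerance = 1e-12)
  expect_warning(r1 <- fisher_average(c(1, 0)), "clipped")
  expect_lt(r1, 1)
  # monotone in each argument
  expect_gt(fisher_average(c(0.3, 0.6)), fisher_average(c(0.2, 0.6)))
  expect_error(fisher_average(NA_real_), class = "eegbench_empty_input_error")
})
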