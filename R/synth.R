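# Synthetic auditory-oddball session generator. Emulates the benchmark
# design: blocks of trials with an exact target fraction, jittered
# inter-stimulus intervals, a P300-like evoked bump on target trials over a
# 1/f background with an alpha rhythm, an optional gait-locked periodic
# artifact (~1.2 Hz) for walking conditions, and optional blinks. Everything
# is deterministic under the stated seeds.

#' Oddball session design
#'
#' Defaults reproduce the benchmark protocol: 4 blocks of 160 trials, target
#' probability 0.25, 400 ms stimuli with a 1420-1580 ms inter-stimulus
#' interval.
#'
#' @param n_blocks Number of blocks (default 4).
#' @param trials_per_block Trials per block (default 160).
#' @param p_target Target probability in (0, 1) (default 0.25).
#' @param isi_range_ms Length-2 ISI range in ms (default `c(1420, 1580)`).
#' @param stim_ms Stimulus duration in ms (default 400).
#' @param rate Sampling rate in Hz (default 500).
#' @param seed Integer seed for the schedule.
#' @return An object of class `eeg_design`.
#' @export
session_design <- function(n_blocks = 4, trials_per_block = 160,
                           p_target = 0.25, isi_range_ms = c(1420, 1580),
                           stim_ms = 400, rate = 500, seed = 1L) {
  if (p_target < 0 || p_target >= 1) {
    bench_abort("`p_target` must lie in [0, 1)", "eegbench_parameter_error")
  }
  if (isi_range_ms[1] > isi_range_ms[2]) {
    bench_abort("`isi_range_ms` must be c(lower, upper)", "eegbench_parameter_error")
  }
  structure(
    list(n_blocks = as.integer(n_blocks),
         trials_per_block = as.integer(trials_per_block),
         p_target = p_target, isi_range_ms = as.numeric(isi_range_ms),
         stim_ms = stim_ms, rate = rate, seed = as.integer(seed)),
    class = "eeg_design"
  )
}

# per-channel gain profiles for the benchmark montage
.p300_topography <- c(
  Fpz = 0.4, F3 = 0.5, Fz = 0.5, F4 = 0.5, C3 = 0.75, Cz = 0.9, C4 = 0.75,
  P3 = 0.85, Pz = 1.0, P4 = 0.85, O1 = 0.4, O2 = 0.4
)
.gait_gains <- c(
  Fpz = 0.3, F3 = 0.4, Fz = 0.4, F4 = 0.4, C3 = 0.6, Cz = 0.6, C4 = 0.6,
  P3 = 0.8, Pz = 0.8, P4 = 0.8, O1 = 1.0, O2 = 1.0
)
.blink_gains <- c(
  Fpz = 1.0, F3 = 0.5, Fz = 0.5, F4 = 0.5, C3 = 0.2, Cz = 0.2, C4 = 0.2,
  P3 = 0.1, Pz = 0.1, P4 = 0.1, O1 = 0.05, O2 = 0.05
)

#' Signal model for the session simulator
#'
#' Parameterizes what the simulator injects. Amplitudes are in uV. Presets
#' bundle the calibrations used by the test fixtures: `"wet_seated"` /
#' `"wet_walking"` emulate a research-grade wet-electrode system,
#' `"dry_seated"` / `"dry_walking"` a noisier dry-electrode system whose
#' walking data is dominated by a large gait-locked artifact (near-total
#' rejection at the traditional 75 uV threshold).
#'
#' @param p300_amp P300 peak amplitude at the topography maximum (default 10).
#' @param p300_latency_ms Peak latency after onset (default 400, inside the
#'   300-500 ms window).
#' @param p300_width_ms Gaussian sd of the bump in ms (default 55).
#' @param topography Named per-channel gain in \[0, 1\]; default
#'   central-parietal maximum (Pz 1.0, Cz 0.9, frontal 0.5, occipital 0.4).
#' @param noise_sd Time-domain sd of the 1/f background (default 9).
#' @param noise_exponent Spectral exponent of the background (default 1).
#' @param alpha_amp,alpha_hz Alpha oscillation amplitude and frequency
#'   (defaults 4 uV, 10 Hz).
#' @param gait_amp,gait_hz Gait artifact fundamental amplitude and stride
#'   frequency (defaults 0 uV -- seated -- and 1.2 Hz); two harmonics at half
#'   and quarter amplitude are added, occiput-weighted.
#' @param blink_rate Blinks per minute (default 0: the pipeline assumes
#'   blink-cleaned input).
#' @param blink_amp Blink amplitude at Fpz (default 100).
#' @param response_accuracy Probability a target gets a button press; a
#'   non-target draws a spurious press with probability
#'   `(1 - response_accuracy) / 10` (default 0.98).
#' @param seed Integer seed for all signal randomness.
#' @param preset Optional preset name overriding the noise/gait defaults.
#' @return An object of class `eeg_signal_model`.
#' @export
signal_model <- function(p300_amp = 10, p300_latency_ms = 400,
                         p300_width_ms = 55, topography = .p300_topography,
                         noise_sd = 9, noise_exponent = 1,
                         alpha_amp = 4, alpha_hz = 10,
                         gait_amp = 0, gait_hz = 1.2,
                         blink_rate = 0, blink_amp = 100,
                         response_accuracy = 0.98, seed = 1L,
                         preset = NULL) {
  if (!is.null(preset)) {
    preset <- match.arg(preset, c("wet_seated", "wet_walking",
                                  "dry_seated", "dry_walking"))
    over <- switch(preset,
      wet_seated  = list(noise_sd = 16, gait_amp = 0),
      wet_walking = list(noise_sd = 16, gait_amp = 10),
      dry_seated  = list(noise_sd = 17, gait_amp = 0),
      dry_walking = list(noise_sd = 22, gait_amp = 120)
    )
    call_args <- as.list(match.call())[-1]
    for (nm in names(over)) {
      if (!nm %in% names(call_args)) assign(nm, over[[nm]])
    }
  }
  if (p300_amp < 0 || noise_sd < 0 || alpha_amp < 0 || gait_amp < 0) {
    bench_abort("amplitudes must be >= 0", "eegbench_parameter_error")
  }
  if (gait_hz <= 0) bench_abort("`gait_hz` must be > 0", "eegbench_parameter_error")
  if (response_accuracy < 0 || response_accuracy > 1) {
    bench_abort("`response_accuracy` must lie in [0, 1]", "eegbench_parameter_error")
  }
  structure(
    list(p300_amp = p300_amp, p300_latency_ms = p300_latency_ms,
         p300_width_ms = p300_width_ms, topography = topography,
         noise_sd = noise_sd, noise_exponent = noise_exponent,
         alpha_amp = alpha_amp, alpha_hz = alpha_hz,
         gait_amp = gait_amp, gait_hz = gait_hz,
         blink_rate = blink_rate, blink_amp = blink_amp,
         response_accuracy = response_accuracy, seed = as.integer(seed)),
    class = "eeg_signal_model"
  )
}

#' Generate the stimulus schedule for a session
#'
#' Each block receives exactly `round(p_target * trials_per_block)` targets in
#' seeded-shuffled order (exact-count oddball construction, so the default
#' 0.25 fraction is exact, not merely expected). Onsets are spaced by the
#' stimulus duration plus a uniform ISI draw; a 1 s lead-in precedes the
#' first stimulus.
#'
#' @param design An [session_design()].
#' @return An [event_list()] with 0-based onset samples and labels (no
#'   responses; [simulate_session()] adds those).
#' @export
schedule <- function(design) {
  n_t_exact <- design$p_target * design$trials_per_block
  n_t <- round(n_t_exact)
  if (abs(n_t - n_t_exact) > 1e-9) {
    warning(sprintf("p_target * trials_per_block = %g is not integral; using %d targets per block",
                    n_t_exact, n_t))
  }
  with_seed(design$seed, {
    labels <- unlist(lapply(seq_len(design$n_blocks), function(b) {
      sample(c(rep("target", n_t),
               rep("non-target", design$trials_per_block - n_t)))
    }))
    n_ev <- length(labels)
    isi <- stats::runif(n_ev, design$isi_range_ms[1], design$isi_range_ms[2])
    gaps <- round((design$stim_ms + isi) / 1000 * design$rate)
    onsets <- design$rate + cumsum(c(0, gaps[-n_ev]))   # 1 s lead-in
    event_list(onsets, labels)
  })
}

# seeded 1/f^exponent noise by spectral shaping, scaled to unit sd. The FFT
# runs on the next 2-3-5-smooth length >= n (R's mixed-radix FFT is
# quadratic in the largest prime factor); the tail is discarded.
pink_noise <- function(n, exponent) {
  m <- stats::nextn(n, c(2, 3, 5))
  x <- stats::rnorm(m)
  if (exponent == 0) return(x[seq_len(n)] / stats::sd(x[seq_len(n)]))
  sp <- stats::fft(x)
  k <- 0:(m - 1)
  f <- pmin(k, m - k)
  shape <- c(0, 1 / f[-1]^(exponent / 2))
  y <- Re(stats::fft(sp * shape, inverse = TRUE))[seq_len(n)] / m
  y / stats::sd(y)
}

#' Simulate a continuous oddball session
#'
#' Builds a 12-channel continuous recording: 1/f background scaled to
#' `noise_sd`, alpha sinusoid, gait-locked artifact (fundamental plus two
#' harmonics, occiput-weighted, random per-channel phases) when
#' `gait_amp > 0`, a Gaussian P300 bump on every target trial
#' (`amp * topography`, peaking at `p300_latency_ms`), and optional
#' stereotyped blinks. Button presses follow targets with probability
#' `response_accuracy` at a 300-700 ms reaction time; non-targets draw
#' spurious presses with probability `(1 - response_accuracy) / 10`.
#' Identical seeds give bit-identical output.
#'
#' @param design An [session_design()].
#' @param model An [signal_model()].
#' @param mont An [montage()] (default: 12-channel benchmark montage).
#' @param events Optional pre-built [event_list()] (e.g. to share a schedule
#'   across conditions); default `schedule(design)`.
#' @return List with elements `recording` ([recording()]) and `events`
#'   ([event_list()] including responses).
#' @export
simulate_session <- function(design, model, mont = montage(),
                             events = schedule(design)) {
  rate <- design$rate
  labels <- mont$names
  nchan <- length(labels)
  topo <- model$topography[match_channel(labels, names(model$topography))]
  if (anyNA(topo)) {
    bench_abort("`topography` must name every montage channel", "eegbench_parameter_error")
  }
  n_ev <- length(events$onsets)
  tail_samp <- round((design$stim_ms + design$isi_range_ms[2]) / 1000 * rate)
  n_samp <- events$onsets[n_ev] + tail_samp + rate

  with_seed(model$seed, {
    data <- matrix(0, nchan, n_samp)
    t_sec <- (seq_len(n_samp) - 1) / rate
    for (ch in seq_len(nchan)) {
      row <- pink_noise(n_samp, model$noise_exponent) * model$noise_sd
      if (model$alpha_amp > 0) {
        row <- row + model$alpha_amp *
          sin(2 * pi * model$alpha_hz * t_sec + stats::runif(1, 0, 2 * pi))
      }
      if (model$gait_amp > 0) {
        g <- .gait_gains[match_channel(labels[ch], names(.gait_gains))]
        if (is.na(g)) g <- 0.6
        for (h in 1:3) {
          row <- row + model$gait_amp * c(1, 0.5, 0.25)[h] * g *
            sin(2 * pi * h * model$gait_hz * t_sec + stats::runif(1, 0, 2 * pi))
        }
      }
      data[ch, ] <- row
    }

    # P300 bump on target trials (0-based onsets -> 1-based sample grid)
    if (model$p300_amp > 0) {
      sd_s <- model$p300_width_ms / 1000 * rate
      half <- ceiling(4 * sd_s)
      for (o in events$onsets[events$labels == "target"]) {
        center <- o + round(model$p300_latency_ms / 1000 * rate) + 1
        idx <- max(1, center - half):min(n_samp, center + half)
        bump <- model$p300_amp * exp(-0.5 * ((idx - center) / sd_s)^2)
        data[, idx] <- data[, idx] + outer(topo, bump)
      }
    }

    if (model$blink_rate > 0) {
      bg <- .blink_gains[match_channel(labels, names(.blink_gains))]
      bg[is.na(bg)] <- 0.1
      n_blinks <- stats::rpois(1, model$blink_rate * n_samp / rate / 60)
      len <- round(0.4 * rate)
      shape <- model$blink_amp *
        c(sin(pi * seq_len(len %/% 2) / (len %/% 2))^2,
          -0.3 * sin(pi * seq_len(len - len %/% 2) / (len - len %/% 2))^2)
      for (b in seq_len(n_blinks)) {
        s <- sample.int(n_samp - len, 1)
        data[, s:(s + len - 1)] <- data[, s:(s + len - 1)] + outer(bg, shape)
      }
    }

    # behavioral responses
    presses <- numeric(0)
    rt <- round(stats::runif(n_ev, 0.3, 0.7) * rate)
    press_draw <- stats::runif(n_ev)
    for (i in seq_len(n_ev)) {
      p_press <- if (events$labels[i] == "target") model$response_accuracy
                 else (1 - model$response_accuracy) / 10
      if (press_draw[i] < p_press) presses <- c(presses, events$onsets[i] + rt[i])
    }

    list(
      recording = recording(data, rate, labels,
                            meta = list(synthetic = TRUE, seed = model$seed)),
      events = event_list(events$onsets, events$labels, presses)
    )
  })
}

#' Build a seated/walking fixture pair
#'
#' Two sessions sharing one design (hence one stimulus schedule and one P300
#' template shape) but differing in their signal models -- typically noise
#' level and gait artifact. This mirrors a within-subject seated-vs-walking
#' contrast and feeds the Ratio W/S and scalar-similarity tests.
#'
#' @param design An [session_design()].
#' @param model_seated,model_walking [signal_model()]s.
#' @param mont An [montage()].
#' @return List with elements `seated` and `walking`, each a
#'   `list(recording, events)`.
#' @export
make_fixture_pair <- function(design, model_seated, model_walking,
                              mont = montage()) {
  ev <- schedule(design)
  list(
    seated = simulate_session(design, model_seated, mont, events = ev),
    walking = simulate_session(design, model_walking, mont, events = ev)
  )
}
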