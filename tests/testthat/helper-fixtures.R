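# Fixture builders shared across the suite. Everything is generated in code;
# no data files.

# epoch set with arbitrary per-trial waveforms: `waves` is a list of
# channels x samples matrices (or vectors for single-channel data)
make_epochs <- function(waves, rate = 500, t0 = -0.3,
                        labels = rep("target", length(waves)),
                        channels = NULL) {
  waves <- lapply(waves, function(w) if (is.matrix(w)) w else matrix(w, nrow = 1))
  nchan <- nrow(waves[[1]])
  nsamp <- ncol(waves[[1]])
  if (is.null(channels)) channels <- paste0("ch", seq_len(nchan))
  tensor <- array(0, c(length(waves), nchan, nsamp))
  for (i in seq_along(waves)) tensor[i, , ] <- waves[[i]]
  epoch_set(tensor, epoch_times = t0 + (seq_len(nsamp) - 1) / rate,
            labels = labels, rate = rate, channel_labels = channels)
}

# epoch set whose per-trial peak-to-peak values are exactly `p2p_values`
# (a single spike on channel 1 inside the first window)
make_p2p_epochs <- function(p2p_values, nsamp = 550, rate = 500) {
  waves <- lapply(p2p_values, function(v) {
    w <- matrix(0, 2, nsamp)
    w[1, 10] <- v
    w
  })
  make_epochs(waves, rate = rate)
}

# small montage-complete recording with deterministic per-channel sinusoids
make_sine_recording <- function(nsamp = 2500, rate = 500) {
  labels <- montage()$names
  t <- (seq_len(nsamp) - 1) / rate
  data <- t(vapply(seq_along(labels), function(i) {
    10 * sin(2 * pi * (4 + i) * t + i)
  }, numeric(nsamp)))
  recording(data, rate, labels)
}

# reduced-size oddball session for fast pipeline tests: 2 blocks x 40 trials
small_design <- function(seed = 7, trials = 40, blocks = 2) {
  session_design(n_blocks = blocks, trials_per_block = trials, seed = seed)
}

# independent brute-force sliding-window peak-to-peak (the oracle for
# epoch_p2p): plain loops, no shared code with the implementation
oracle_p2p <- function(tensor, rate, win_ms = 200, step_ms = 100) {
  d <- dim(tensor)
  win <- round(win_ms / 1000 * rate)
  step <- round(step_ms / 1000 * rate)
  out <- numeric(d[1])
  for (tr in seq_len(d[1])) {
    best <- 0
    for (ch in seq_len(d[2])) {
      s <- 1
      while (s < d[3]) {
        idx <- s:min(s + win - 1, d[3])
        best <- max(best, max(tensor[tr, ch, idx]) - min(tensor[tr, ch, idx]))
        s <- s + step
      }
    }
    out[tr] <- best
  }
  out
}

# independent ICC(A,1) via stats::aov mean squares
oracle_icc_a1 <- function(mat) {
  n <- nrow(mat)
  k <- ncol(mat)
  df <- data.frame(
    y = as.vector(mat),
    subject = factor(rep(seq_len(n), k)),
    session = factor(rep(seq_len(k), each = n))
  )
  ms <- summary(stats::aov(y ~ subject + session, data = df))[[1]][, "Mean Sq"]
  msr <- ms[1]; msc <- ms[2]; mse <- ms[3]
  (msr - mse) / (msr + (k - 1) * mse + (k / n) * (msc - mse))
}
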