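# IIR filter design and zero-phase application. No filter-design dependency is
# available, so the two filters the pipeline needs are designed here from
# first principles: a Butterworth high-pass via the bilinear transform of the
# analog prototype, and a constrained biquad notch. Both are applied
# forward-backward (zero phase), with odd-reflection padding and steady-state
# initial conditions so edge transients stay local.

#' Design a digital Butterworth high-pass filter
#'
#' Bilinear-transform design of an order-`order` Butterworth high-pass.
#' Returned coefficients describe H(z) = B(z^-1)/A(z^-1), normalized to unit
#' gain at Nyquist.
#'
#' @param order Filter order (>= 1).
#' @param cutoff -3 dB cutoff in Hz.
#' @param rate Sampling rate in Hz; `cutoff` must lie in (0, rate/2).
#' @return List with numeric vectors `b` and `a` (increasing powers of z^-1).
#' @export
butter_highpass <- function(order, cutoff, rate) {
  stopifnot_scalar_number(cutoff, "cutoff")
  if (cutoff <= 0 || cutoff >= rate / 2) {
    bench_abort("`cutoff` must lie strictly between 0 and Nyquist",
                "eegbench_parameter_error")
  }
  wc <- tan(pi * cutoff / rate)
  k <- seq_len(order)
  p_lp <- exp(1i * pi * (2 * k + order - 1) / (2 * order))  # unit LP prototype
  p_hp <- wc / p_lp                                          # LP -> HP transform
  zd <- (1 + p_hp) / (1 - p_hp)                              # bilinear poles
  a <- Re(poly_from_roots(zd))
  b0 <- Re(poly_from_roots(rep(1 + 0i, order)))              # zeros at z = 1 (DC)
  sgn <- (-1)^(seq_along(a) - 1)
  g <- sum(a * sgn) / sum(b0 * sgn)                          # unit gain at Nyquist
  list(b = b0 * g, a = a)
}

#' Design a biquad notch filter
#'
#' Second-order IIR notch with a zero pair on the unit circle at `freq` and a
#' -3 dB bandwidth of `width` Hz.
#'
#' @param freq Notch center frequency in Hz.
#' @param width -3 dB bandwidth in Hz.
#' @param rate Sampling rate in Hz; `freq` must be below rate/2.
#' @return List with numeric vectors `b` and `a`.
#' @export
design_notch <- function(freq, width, rate) {
  stopifnot_scalar_number(freq, "freq")
  if (freq <= 0 || freq >= rate / 2) {
    bench_abort("notch `freq` must lie strictly between 0 and Nyquist",
                "eegbench_parameter_error")
  }
  w0 <- 2 * pi * freq / rate
  q <- freq / width
  alpha <- sin(w0) / (2 * q)
  a0 <- 1 + alpha
  list(b = c(1, -2 * cos(w0), 1) / a0,
       a = c(1, -2 * cos(w0) / a0, (1 - alpha) / a0))
}

#' Evaluate a digital filter's frequency response
#'
#' @param coef List with `b`, `a` as returned by the design functions.
#' @param freq Frequencies in Hz at which to evaluate.
#' @param rate Sampling rate in Hz.
#' @return Complex response H(e^{i 2 pi f / rate}) at each frequency.
#' @export
filter_response <- function(coef, freq, rate) {
  vapply(freq, function(f) {
    zi <- exp(-2i * pi * f / rate)^(seq_along(coef$b) - 1)
    za <- exp(-2i * pi * f / rate)^(seq_along(coef$a) - 1)
    sum(coef$b * zi) / sum(coef$a * za)
  }, complex(1))
}

# single forward IIR pass with constant-history initial conditions: filtering
# (x - x[1]) from zero state equals filtering x from the steady state reached
# on an infinite run of x[1]; add back the DC response of that constant.
iir_filter <- function(b, a, x) {
  b <- b / a[1]
  a <- a / a[1]
  x0 <- x[1]
  hdc <- sum(b) / sum(a)
  xs <- x - x0
  nb <- length(b)
  if (nb > 1L) {
    v <- stats::filter(c(rep(0, nb - 1), xs), b, method = "convolution", sides = 1)
    v <- as.numeric(v)[nb:(nb - 1 + length(xs))]
  } else {
    v <- b * xs
  }
  if (length(a) > 1L) {
    v <- as.numeric(stats::filter(v, -a[-1], method = "recursive"))
  }
  v + x0 * hdc
}

# zero-phase forward-backward filtering with odd-reflection padding
filtfilt_vec <- function(coef, x, pad = NULL) {
  n <- length(x)
  nfilt <- max(length(coef$a), length(coef$b))
  if (is.null(pad)) pad <- 3L * (nfilt - 1L)
  pad <- min(pad, n - 1L)
  xp <- if (pad > 0) {
    c(2 * x[1] - x[(pad + 1):2], x, 2 * x[n] - x[(n - 1):(n - pad)])
  } else {
    x
  }
  y <- iir_filter(coef$b, coef$a, xp)
  y <- rev(iir_filter(coef$b, coef$a, rev(y)))
  y[(pad + 1):(pad + n)]
}

apply_filter_rec <- function(rec, coef, pad = NULL) {
  out <- rec$data
  for (ch in seq_len(nrow(out))) {
    out[ch, ] <- filtfilt_vec(coef, out[ch, ], pad = pad)
  }
  recording(out, rec$rate, rec$channel_labels, rec$meta)
}
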