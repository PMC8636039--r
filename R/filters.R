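# Butterworth band-pass design (second-order sections) and zero-phase
# filtering.  Bilinear transform of the analog prototype with frequency
# pre-warping; numerics kept in biquad cascades for stability at narrow
# normalized bands.

#' Design a Butterworth band-pass filter as second-order sections
#'
#' @param order Prototype (half) order; the band-pass has `2 * order` poles.
#' @param f_lo,f_hi Band edges (Hz).
#' @param fs Sampling rate (Hz).
#' @return Matrix `order x 6`, rows `(b0, b1, b2, 1, a1, a2)`, unity gain at
#'   the geometric band center.
#' @export
butter_bandpass_sos <- function(order = 4, f_lo = 2, f_hi = 55, fs = 1000) {
  stopifnot(f_lo > 0, f_hi > f_lo, f_hi < fs / 2)
  # pre-warped analog edges
  w1 <- 2 * fs * tan(pi * f_lo / fs)
  w2 <- 2 * fs * tan(pi * f_hi / fs)
  bw <- w2 - w1
  w0 <- sqrt(w1 * w2)
  # analog low-pass prototype poles (left half plane)
  k <- seq_len(order)
  p_lp <- exp(1i * pi * (2 * k + order - 1) / (2 * order))
  # low-pass -> band-pass: each prototype pole yields two analog poles
  p_bp <- c()
  for (p in p_lp) {
    disc <- sqrt((p * bw)^2 - 4 * w0^2 + 0i)
    p_bp <- c(p_bp, (p * bw + disc) / 2, (p * bw - disc) / 2)
  }
  # bilinear transform
  z_p <- (1 + p_bp / (2 * fs)) / (1 - p_bp / (2 * fs))
  # keep one of each conjugate pair
  z_sel <- z_p[Im(z_p) >= 0]
  if (length(z_sel) != order) z_sel <- z_p[seq(1, 2 * order, by = 2)]
  sos <- t(vapply(z_sel, function(p) {
    c(1, 0, -1, 1, -2 * Re(p), Mod(p)^2)
  }, numeric(6)))
  # normalize gain at the geometric center frequency
  wc <- 2 * pi * sqrt(f_lo * f_hi) / fs
  g <- Mod(sos_response(sos, wc))
  sos[1, 1:3] <- sos[1, 1:3] / g
  sos
}

sos_response <- function(sos, w) {
  z1 <- exp(-1i * w); z2 <- exp(-2i * w)
  h <- 1 + 0i
  for (s in seq_len(nrow(sos)))
    h <- h * (sos[s, 1] + sos[s, 2] * z1 + sos[s, 3] * z2) /
      (sos[s, 4] + sos[s, 5] * z1 + sos[s, 6] * z2)
  h
}

#' Magnitude response of a second-order-section cascade
#' @param sos SOS matrix.
#' @param f Frequencies (Hz).
#' @param fs Sampling rate (Hz).
#' @return Magnitude (linear) per frequency.
#' @export
sos_magnitude <- function(sos, f, fs) {
  vapply(2 * pi * f / fs, function(w) Mod(sos_response(sos, w)), 1.0)
}

#' Zero-phase filtering through a second-order-section cascade
#'
#' Forward-backward application with odd-reflection edge padding.
#'
#' @param sos SOS matrix from [butter_bandpass_sos()].
#' @param x Numeric series.
#' @return Filtered series, same length.
#' @export
sos_filtfilt <- function(sos, x) {
  n <- length(x)
  npad <- min(n - 1, 250)
  pre <- 2 * x[1] - x[(npad + 1):2]
  post <- 2 * x[n] - x[(n - 1):(n - npad)]
  y <- c(pre, x, post)
  y <- sosfilt_cpp(sos, y)
  y <- rev(sosfilt_cpp(sos, rev(y)))
  y[(npad + 1):(npad + n)]
}

#' Detrend and band-pass filter a trial set
#'
#' Per trial and channel: linear detrend, then zero-phase 4th-order
#' Butterworth band-pass (2-55 Hz by default).
#'
#' @param ts A [trial_set()].
#' @param f_lo,f_hi Band edges (Hz).
#' @param order Butterworth half-order.
#' @return The filtered [trial_set()].
#' @export
preprocess <- function(ts, f_lo = 2, f_hi = 55, order = 4) {
  stopifnot(inherits(ts, "trial_set"))
  if (ts$fs <= 2 * f_hi)
    stop("sampling rate ", ts$fs, " Hz too low for the ", f_hi, " Hz band edge")
  sos <- butter_bandpass_sos(order, f_lo, f_hi, ts$fs)
  d <- ts$data
  nsmp <- dim(d)[2]
  tt <- seq_len(nsmp)
  tc <- tt - mean(tt)
  den <- sum(tc^2)
  for (i in seq_len(dim(d)[1])) for (ch in seq_len(dim(d)[3])) {
    x <- d[i, , ch]
    slope <- sum(tc * x) / den
    x <- x - mean(x) - slope * tc
    y <- sos_filtfilt(sos, x)
    # the cascade has exact nulls at DC, but reflection-padding edge
    # transients leave a small residual mean; remove it
    d[i, , ch] <- y - mean(y)
  }
  trial_set(d, ts$labels, ts$fs, ts$session, ts$subject, ts$channels)
}
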