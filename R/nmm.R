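#' Population firing-rate sigmoid
#'
#' `Sigm(v) = 2 e0 / (1 + exp(r (s0 - v)))`.  Strictly increasing, bounded in
#' `(0, 2 e0)`, with `Sigm(s0) = e0` exactly.
#'
#' @param v Membrane potential (mV), finite scalar or vector.
#' @param sp A [sigmoid_params()] object.
#' @return Firing rate(s) in 1/s.
#' @export
sigmoid_rate <- function(v, sp = sigmoid_params()) {
  stopifnot(inherits(sp, "sigmoid_params"))
  if (any(!is.finite(v))) stop("non-finite membrane potential")
  2 * sp$e0 / (1 + exp(sp$r * (sp$s0 - v)))
}

#' Time derivative of the neural mass model state
#'
#' Eight-dimensional first-order form of the four second-order population
#' equations.  The pyramidal drive is `Sigm(C2 y1 - C4 y2 - C7 y3)`; the
#' excitatory population receives the exogenous drive as `p / C2`; the fast
#' inhibitory population is driven by `Sigm(C5 y0 - C6 y2)`, i.e. it sees the
#' slow-inhibitory postsynaptic potential (the original five-state Wendling
#' wiring) rather than the slow cells' firing rate -- see the methods
#' vignette for why the rate-based reading leaves the model quiescent.
#'
#' @param state Numeric vector `(y0, y1, y2, y3, dy0, dy1, dy2, dy3)`.
#' @param pp A [population_params()] object.
#' @param cp A [connectivity_params()] object.
#' @param sp A [sigmoid_params()] object.
#' @param p Exogenous input (1/s).
#' @return Numeric vector of the eight state derivatives.
#' @export
nmm_derivatives <- function(state, pp, cp = connectivity_params(),
                            sp = sigmoid_params(), p = 0) {
  stopifnot(length(state) == 8, all(is.finite(state)), is.finite(p))
  y <- state[1:4]; dy <- state[5:8]
  S <- function(v) sigmoid_rate(v, sp)
  v <- cp$C2 * y[2] - cp$C4 * y[3] - cp$C7 * y[4]
  c(dy,
    pp$A * pp$a * S(v) - 2 * pp$a * dy[1] - pp$a^2 * y[1],
    pp$A * pp$a * (S(cp$C1 * y[1]) + p / cp$C2) - 2 * pp$a * dy[2] - pp$a^2 * y[2],
    pp$B * pp$b * S(cp$C3 * y[1]) - 2 * pp$b * dy[3] - pp$b^2 * y[3],
    pp$G * pp$g * S(cp$C5 * y[1] - cp$C6 * y[3]) - 2 * pp$g * dy[4] - pp$g^2 * y[4])
}

#' Seeded Gaussian exogenous drive
#'
#' @param spec An [exogenous_input_spec()].
#' @return Numeric vector of `spec$n` i.i.d. Gaussian samples with the stated
#'   mean and variance.
#' @export
exogenous_noise <- function(spec) {
  stopifnot(inherits(spec, "exogenous_input_spec"))
  withr_seed(spec$seed, rnorm(spec$n, spec$mean, sqrt(spec$variance)))
}

# Evaluate `expr` under a temporary RNG seed, restoring the caller's RNG state.
withr_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}

#' Integrate one band-tuned population
#'
#' Fixed-step 4th-order Runge-Kutta integration of the population equations
#' under a seeded Gaussian exogenous drive.  The population output is the
#' summed pyramidal input `V(t) = C2 y1 - C4 y2 - C7 y3` (mV).  The noise
#' sample is held constant within each step's four stage evaluations.
#'
#' During the first `ignition` seconds of the burn-in, a constant
#' `ignition_drive` (1/s) is added to the exogenous input.  This deterministic
#' kick selects the active (oscillatory) attractor from the all-zero initial
#' state; the high-band parameter set is bistable and would otherwise remain
#' trapped at its quiescent fixed point.  All burn-in samples are discarded.
#'
#' @param pp A [population_params()] object.
#' @param cp,sp Connectivity and sigmoid parameters.
#' @param input An [exogenous_input_spec()]; `input$n` must cover
#'   `t_total / input$dt` steps (the series is regenerated internally from
#'   the mean/variance/seed fields).
#' @param t_total Total integrated time (s), burn-in included.
#' @param burn_in Discarded initial interval (s).
#' @param state0 Initial state (default all zeros).
#' @param ignition Duration (s) of the ignition drive (clipped to burn-in).
#' @param ignition_drive Added drive (1/s) during ignition.
#' @param blow_threshold Divergence guard on `max(abs(state))`.
#' @return Numeric vector of `(t_total - burn_in) / dt` output samples with
#'   attributes `fs`, `band`, `seed`.
#' @export
integrate_population <- function(pp, cp = connectivity_params(),
                                 sp = sigmoid_params(),
                                 input = exogenous_input_spec(n = 1), t_total,
                                 burn_in = 2, state0 = rep(0, 8),
                                 ignition = 0.5, ignition_drive = 150,
                                 blow_threshold = 1e6) {
  stopifnot(inherits(pp, "population_params"), t_total > burn_in, burn_in >= 0,
            length(state0) == 8)
  dt <- input$dt
  n <- round(t_total / dt)
  spec <- exogenous_input_spec(input$mean, input$variance, n = n, dt = dt,
                               seed = input$seed)
  p <- exogenous_noise(spec)
  n_ig <- min(round(min(ignition, burn_in) / dt), n)
  if (n_ig > 0) p[seq_len(n_ig)] <- p[seq_len(n_ig)] + ignition_drive
  res <- nmm_rk4_cpp(state0, p, dt, pp$A, pp$B, pp$G, pp$a, pp$b, pp$g,
                     unlist(connectivity_vec(cp)), sp$e0, sp$s0, sp$r,
                     blow_threshold)
  if (res$diverged_at > 0)
    stop(sprintf(
      "numerical blow-up at step %d for band '%s' (A=%g B=%g G=%g a=%g b=%g g=%g)",
      res$diverged_at, pp$band, pp$A, pp$B, pp$G, pp$a, pp$b, pp$g))
  out <- res$output[(round(burn_in / dt) + 1):n]
  attr(out, "fs") <- 1 / dt
  attr(out, "band") <- pp$band
  attr(out, "seed") <- spec$seed
  out
}

connectivity_vec <- function(cp) {
  c(cp$C1, cp$C2, cp$C3, cp$C4, cp$C5, cp$C6, cp$C7)
}

#' Mix population outputs into the membrane potential
#'
#' Pointwise weighted sum `V_out = w_L V_L + w_M V_M + w_H V_H`.
#'
#' @param outputs List of three equal-length numeric vectors, ordered
#'   low/medium/high.
#' @param w A [population_weights()] object.
#' @return Numeric vector of the mixed output (mV).
#' @export
mix_populations <- function(outputs, w) {
  stopifnot(length(outputs) == 3, inherits(w, "population_weights"))
  len <- vapply(outputs, length, 1L)
  if (length(unique(len)) != 1)
    stop("population outputs differ in length: ", paste(len, collapse = ", "))
  w$w_low * as.numeric(outputs[[1]]) + w$w_medium * as.numeric(outputs[[2]]) +
    w$w_high * as.numeric(outputs[[3]])
}

#' Welch power spectral density
#'
#' Hann-windowed, mean-detrended, 50%-overlapping segment average.
#'
#' @param x Numeric series.
#' @param fs Sampling rate (Hz).
#' @param seg_len Segment length in samples (default 2 s).
#' @param overlap Fractional overlap in `[0, 1)`.
#' @return List with `freq` (Hz) and `psd` (one-sided, arbitrary scale).
#' @export
welch_psd <- function(x, fs, seg_len = round(2 * fs), overlap = 0.5) {
  stopifnot(seg_len <= length(x), seg_len >= 8)
  step <- max(1L, round(seg_len * (1 - overlap)))
  starts <- seq(1L, length(x) - seg_len + 1L, by = step)
  w <- 0.5 - 0.5 * cos(2 * pi * (0:(seg_len - 1)) / (seg_len - 1))
  acc <- numeric(seg_len)
  for (s in starts) {
    xx <- x[s:(s + seg_len - 1)]
    xx <- (xx - mean(xx)) * w
    acc <- acc + abs(fft(xx))^2
  }
  acc <- acc / (length(starts) * sum(w^2) * fs)
  half <- seq_len(floor(seg_len / 2) + 1)
  psd <- acc[half]
  if (length(half) > 2) psd[2:(length(half) - 1)] <- 2 * psd[2:(length(half) - 1)]
  list(freq = (half - 1) * fs / seg_len, psd = psd)
}

#' Frequency of the dominant spectral peak
#'
#' @param x Numeric series.
#' @param fs Sampling rate (Hz).
#' @param f_range Search range in Hz.
#' @param ... Passed to [welch_psd()].
#' @return Peak frequency (Hz).
#' @export
dominant_peak <- function(x, fs, f_range = c(1, 80), ...) {
  ps <- welch_psd(x, fs, ...)
  sel <- ps$freq >= f_range[1] & ps$freq <= f_range[2]
  ps$freq[sel][which.max(ps$psd[sel])]
}

#' Band-energy population weights from reference recordings
#'
#' For one class of reference trials: the power spectral density is averaged
#' across channels and trials (Welch, 2-s Hann segments, 50% overlap) and each
#' band weight is the band's share of energy over the analysed range
#' `total_band`.  Weights need not sum to one because the analysed range
#' excludes energy below its lower edge.
#'
#' @param reference A [trial_set()] (all trials are pooled; subset by class
#'   upstream for per-class weights).
#' @param bands List of three [band_definition()]s (low/medium/high).
#' @param total_band Analysed range in Hz (default 4-55 Hz).
#' @return A [population_weights()] object; weights are reported rounded to 4
#'   decimals in summaries but stored at full precision.
#' @export
band_weights_from_reference <- function(reference, bands = band_defaults(),
                                        total_band = c(4, 55)) {
  stopifnot(inherits(reference, "trial_set"))
  fs <- reference$fs
  nyq <- fs / 2
  d <- reference$data
  seg <- min(round(2 * fs), dim(d)[2])
  acc <- NULL
  for (i in seq_len(dim(d)[1])) for (ch in seq_len(dim(d)[3])) {
    ps <- welch_psd(d[i, , ch], fs, seg_len = seg)
    acc <- if (is.null(acc)) ps$psd else acc + ps$psd
  }
  freq <- welch_psd(d[1, , 1], fs, seg_len = seg)$freq
  total <- sum(acc[freq >= total_band[1] & freq <= min(total_band[2], nyq)])
  wts <- vapply(bands, function(b) {
    hi <- min(b$f_high, nyq, total_band[2])
    lo <- max(b$f_low, total_band[1])
    if (hi <= lo) stop(sprintf("band '%s' is empty after clipping", b$name))
    sum(acc[freq >= lo & freq < hi]) / total
  }, 1.0)
  population_weights(wts[[1]], wts[[2]], wts[[3]])
}
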