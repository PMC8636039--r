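#' Sigmoid parameters of the neural mass model
#'
#' The static nonlinearity converting a mean membrane potential (mV) into a
#' mean firing rate (1/s): `Sigm(v) = 2 e0 / (1 + exp(r (s0 - v)))`.
#'
#' @param e0 Half of the maximum firing rate (1/s).
#' @param s0 Mean firing threshold (mV).
#' @param r Sigmoid slope (1/mV).  Although sometimes printed in 1/V, the
#'   value 0.56 is interpreted per millivolt for consistency with `s0` and
#'   the Jansen-Rit literature.
#' @return An object of class `sigmoid_params`.
#' @export
sigmoid_params <- function(e0 = 2.5, s0 = 6, r = 0.56) {
  stopifnot(is.finite(e0), is.finite(s0), is.finite(r), e0 > 0, r > 0)
  structure(list(e0 = e0, s0 = s0, r = r), class = "sigmoid_params")
}

#' Connectivity constants of the neural mass model
#'
#' Dimensionless coupling constants between the pyramidal, excitatory and the
#' two inhibitory interneuron subpopulations.
#'
#' @param C1,C2,C3,C4,C5,C6,C7 Nonnegative connectivity constants.
#' @return An object of class `connectivity_params`.
#' @export
connectivity_params <- function(C1 = 135, C2 = 108, C3 = 33.75, C4 = 33.75,
                                C5 = 40.5, C6 = 13.5, C7 = 108) {
  v <- c(C1, C2, C3, C4, C5, C6, C7)
  stopifnot(all(is.finite(v)), all(v >= 0), C2 > 0)
  structure(list(C1 = C1, C2 = C2, C3 = C3, C4 = C4, C5 = C5, C6 = C6, C7 = C7),
            class = "connectivity_params")
}

#' Band-specific synaptic gain and rate parameters
#'
#' One parallel population per spectral band; `A`, `B`, `G` are the average
#' synaptic gains (mV) of the excitatory, slow-inhibitory and fast-inhibitory
#' feedback loops, and `a`, `b`, `g` the corresponding lumped rate constants
#' (1/s).
#'
#' @param band One of `"low"`, `"medium"`, `"high"`.
#' @param A,B,G Synaptic gains (mV), strictly positive.
#' @param a,b,g Rate constants (1/s), strictly positive.
#' @return An object of class `population_params`.
#' @seealso [nmm_band_defaults()] for the shipped per-band values.
#' @export
population_params <- function(band, A, B, G, a, b, g) {
  band <- match.arg(band, c("low", "medium", "high"))
  v <- c(A, B, G, a, b, g)
  stopifnot(all(is.finite(v)), all(v > 0))
  structure(list(band = band, A = A, B = B, G = G, a = a, b = b, g = g),
            class = "population_params")
}

#' Default per-band population parameters
#'
#' The shipped gain/rate sets that place the dominant spectral peak of each
#' population in its designated band (low 4-12 Hz, medium 12-30 Hz,
#' high > 30 Hz) under the default exogenous noise drive.
#'
#' @return Named list of three [population_params()] objects.
#' @export
nmm_band_defaults <- function() {
  list(
    low    = population_params("low",    A = 2.7, B = 3.2, G = 27, a = 40,  b = 20, g = 300),
    medium = population_params("medium", A = 5.2, B = 4.5, G = 43, a = 85,  b = 30, g = 350),
    high   = population_params("high",   A = 5.6, B = 3.8, G = 75, a = 110, b = 40, g = 400)
  )
}

#' Exogenous input specification
#'
#' Gaussian white drive to the excitatory population, sampled once per
#' integration step and held constant within the four stage evaluations of
#' each Runge-Kutta step.
#'
#' @param mean Mean input level (1/s).
#' @param variance Noise variance ((1/s)^2); 0 yields a constant drive.
#' @param n Number of samples.
#' @param dt Step size (s).
#' @param seed Integer RNG seed.
#' @return An object of class `exogenous_input_spec`.
#' @export
exogenous_input_spec <- function(mean = 60, variance = 100, n, dt = 1e-3,
                                 seed = 1L) {
  stopifnot(is.finite(mean), is.finite(variance), variance >= 0,
            n >= 1, dt > 0)
  structure(list(mean = mean, variance = variance, n = as.integer(n),
                 dt = dt, seed = as.integer(seed)),
            class = "exogenous_input_spec")
}

#' Spectral band definitions
#'
#' @param name Band name.
#' @param f_low,f_high Band edges in Hz (`f_high` may be `Inf`).
#' @return An object of class `band_definition`.
#' @export
band_definition <- function(name, f_low, f_high) {
  stopifnot(f_low < f_high)
  structure(list(name = name, f_low = f_low, f_high = f_high),
            class = "band_definition")
}

#' Default band split: low 4-12 Hz, medium 12-30 Hz, high above 30 Hz
#' @param f_max Upper edge substituted for the open-ended high band when a
#'   finite analysis range is required (default 55 Hz, the upper edge of the
#'   preprocessing band-pass).
#' @return List of three [band_definition()] objects.
#' @export
band_defaults <- function(f_max = 55) {
  list(low = band_definition("low", 4, 12),
       medium = band_definition("medium", 12, 30),
       high = band_definition("high", 30, f_max))
}

#' Population mixing weights
#'
#' Nonnegative weights combining the low/medium/high population outputs into
#' the mixed postsynaptic membrane potential.
#'
#' @param w_low,w_medium,w_high Nonnegative weights, not all zero.
#' @return An object of class `population_weights`.
#' @export
population_weights <- function(w_low, w_medium, w_high) {
  w <- c(w_low, w_medium, w_high)
  stopifnot(all(is.finite(w)), all(w >= 0), any(w > 0))
  structure(list(w_low = w_low, w_medium = w_medium, w_high = w_high),
            class = "population_weights")
}

#' Reference per-class population weights
#'
#' Band-energy derived weights for the four microexpression classes
#' (micro raise-brow, furrow-brow, left-smirk, right-smirk), used as the
#' default class structure of the synthetic scenario generator.
#'
#' @return Named list of [population_weights()], one per class label.
#' @export
class_weight_defaults <- function() {
  list(
    mRB = population_weights(0.1190, 0.3332, 0.5478),
    mFB = population_weights(0.0845, 0.0487, 0.0357),
    mLS = population_weights(0.0887, 0.0574, 0.0467),
    mRS = population_weights(0.0996, 0.0550, 0.0509)
  )
}

#' Microexpression class labels
#' @return Character vector of the four class labels.
#' @export
me_classes <- function() c("mRB", "mFB", "mLS", "mRS")
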