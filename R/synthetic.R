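# Synthetic surrogate of the four-class microexpression recording protocol:
# class-specific neural mass sources, dipole projection through the spherical
# three-shell head, and 1/f-shaped sensor noise.  Fully seeded so the GAN and
# augmentation stages are testable without any external data.

#' Recording protocol description
#'
#' Defaults mirror the emulated experiment: 8 subjects, 4 microexpression
#' classes, 4 sessions of 6 trials each, trials of 3 s countdown + 4 s task +
#' 2 s rest, 30 channels at 1000 Hz.
#'
#' @param n_subjects,sessions,trials Counts (all >= 1).
#' @param countdown_s,task_s,rest_s Trial phase durations (s).
#' @param fs Sampling rate (Hz).
#' @param classes Class labels.
#' @return A `recording_protocol`.
#' @export
recording_protocol <- function(n_subjects = 8, sessions = 4, trials = 6,
                               countdown_s = 3, task_s = 4, rest_s = 2,
                               fs = 1000, classes = me_classes()) {
  stopifnot(n_subjects >= 1, sessions >= 1, trials >= 1, fs > 0,
            countdown_s >= 0, task_s > 0, rest_s >= 0)
  structure(list(n_subjects = as.integer(n_subjects),
                 sessions = as.integer(sessions), trials = as.integer(trials),
                 countdown_s = countdown_s, task_s = task_s, rest_s = rest_s,
                 fs = fs, classes = classes), class = "recording_protocol")
}

#' Synthetic scenario configuration
#'
#' The stated world of the generator: per-class dipoles and population
#' weights, sensor signal-to-noise ratio, multiplicative subject jitter on
#' the synaptic gains and weights, and the montage/head model.
#'
#' @param snr_db Sensor SNR (dB) of the additive 1/f + white noise.
#' @param jitter Subject-level multiplicative jitter (fraction, default 0.10).
#' @param seed Master seed; every trial derives its own stream from it.
#' @param class_weights Named list of [population_weights()] per class.
#' @param model A [shell_model()].
#' @param montage An `electrode_montage`.
#' @param amplitude_uV Median per-channel RMS of the projected signal.
#' @param noise_white_frac White fraction of the sensor noise mix.
#' @return A `scenario_config`.
#' @export
scenario_config <- function(snr_db = 10, jitter = 0.10, seed = 1L,
                            class_weights = class_weight_defaults(),
                            model = shell_model(),
                            montage = standard_montage(model),
                            amplitude_uV = 10, noise_white_frac = 0.5) {
  stopifnot(is.finite(snr_db), jitter >= 0)
  structure(list(snr_db = snr_db, jitter = jitter, seed = as.integer(seed),
                 class_weights = class_weights, model = model,
                 montage = montage, amplitude_uV = amplitude_uV,
                 noise_white_frac = noise_white_frac),
            class = "scenario_config")
}

# deterministic sub-seed chain, kept below 2^31
sub_seed <- function(seed, ...) {
  h <- as.double(seed) %% 2147483647
  for (k in c(...)) h <- (h * 48271 + as.double(k)) %% 2147483647
  as.integer(h)
}

# 1/f + white noise, unit variance, seeded
shaped_noise <- function(n, fs, white_frac, seed) {
  withr_seed(seed, {
    w <- rnorm(n)
    sp <- fft(rnorm(n))
    f <- c(1e-3, seq_len(n - 1)) * fs / n
    f <- pmin(f, fs - f)   # mirror for the upper half
    sp <- sp / sqrt(pmax(f, 0.5))
    pink <- Re(fft(sp, inverse = TRUE)) / n
    pink <- pink / sd(pink)
    x <- sqrt(white_frac) * w + sqrt(1 - white_frac) * pink
    x / sd(x)
  })
}

#' Generate surrogate recordings for one subject
#'
#' For every class/session/trial a three-population source is integrated with
#' the subject's jittered gains and the class weights, projected through the
#' class dipole, and buried in shaped sensor noise at the scenario SNR.  Only
#' the task segment is synthesized in detail ([write_edf()] pads the
#' countdown/rest phases with zeros).
#'
#' @param protocol A [recording_protocol()].
#' @param scenario A [scenario_config()].
#' @param subject Subject index (drives the jitter stream).
#' @return A [trial_set()] of `sessions * trials * classes` task segments.
#' @export
generate_subject_recordings <- function(protocol, scenario, subject = 1) {
  stopifnot(inherits(protocol, "recording_protocol"),
            inherits(scenario, "scenario_config"))
  classes <- protocol$classes
  miss <- setdiff(classes, names(scenario$class_weights))
  if (length(miss))
    stop("no class weights for: ", paste(miss, collapse = ", "))
  fs <- protocol$fs
  dt <- 1 / fs
  nsmp <- round(protocol$task_s * fs)
  dips <- lapply(classes, place_dipole, model = scenario$model)
  names(dips) <- classes
  lf <- analytic_leadfield(scenario$model, scenario$montage, dips)
  bands <- nmm_band_defaults()
  # subject-level multiplicative jitter on gains and weights
  jmul <- withr_seed(sub_seed(scenario$seed, 1000 + subject), {
    stats::runif(12, 1 - scenario$jitter, 1 + scenario$jitter)
  })
  for (bi in seq_along(bands)) {
    bands[[bi]]$A <- bands[[bi]]$A * jmul[bi]
    bands[[bi]]$B <- bands[[bi]]$B * jmul[3 + bi]
    bands[[bi]]$G <- bands[[bi]]$G * jmul[6 + bi]
  }
  wjit <- jmul[10:12]
  n_trial <- protocol$sessions * protocol$trials * length(classes)
  nch <- length(scenario$montage$labels)
  data <- array(0, c(n_trial, nsmp, nch))
  labels <- character(n_trial); session <- integer(n_trial)
  k <- 0L
  for (cl_i in seq_along(classes)) {
    cl <- classes[cl_i]
    w0 <- scenario$class_weights[[cl]]
    w <- population_weights(w0$w_low * wjit[1], w0$w_medium * wjit[2],
                            w0$w_high * wjit[3])
    for (se in seq_len(protocol$sessions)) for (tr in seq_len(protocol$trials)) {
      k <- k + 1L
      src <- class_source(bands, w, protocol$task_s, dt,
                          function(bi) sub_seed(scenario$seed, subject, cl_i,
                                                se, tr, bi))
      data[k, , ] <- project_to_scalp(src, lf, dips[[cl]], scenario$montage,
                                      which_dipole = cl_i)
      labels[k] <- cl; session[k] <- se
    }
  }
  # one amplitude calibration per subject: the class structure keeps its
  # relative amplitudes, the nominal scale is amplitude_uV global RMS
  scale <- scenario$amplitude_uV / sqrt(mean(data^2))
  data <- data * scale
  # sensor noise at a global floor relative to the nominal amplitude
  noise_sd <- scenario$amplitude_uV * 10^(-scenario$snr_db / 20)
  k <- 0L
  for (cl_i in seq_along(classes)) for (se in seq_len(protocol$sessions))
    for (tr in seq_len(protocol$trials)) {
      k <- k + 1L
      for (ch in seq_len(nch)) {
        nz <- shaped_noise(nsmp, fs, scenario$noise_white_frac,
                           sub_seed(scenario$seed, subject, cl_i, se, tr,
                                    100 + ch))
        data[k, , ch] <- data[k, , ch] + noise_sd * nz
      }
    }
  trial_set(data, labels, fs, session, paste0("S", subject),
            scenario$montage$labels)
}

# Unit-variance population outputs mixed so that the realized band-energy
# profile of the source matches the configured weights (the weights are
# band-*energy* fractions).  Because the populations' linewidths straddle the
# band edges, the mixing energies are calibrated against the realized
# band-confinement matrix C (C[k, j] = fraction of population j's energy in
# band k): solve C e = w and mix with sqrt(e).  Falls back to e = w when the
# calibration would need a negative energy.
class_source <- function(bands, w, task_s, dt, seed_fn,
                         band_edges = band_defaults()) {
  fs <- 1 / dt
  outs <- lapply(seq_along(bands), function(bi) {
    x <- integrate_population(
      bands[[bi]], input = exogenous_input_spec(n = 1, dt = dt,
                                                seed = seed_fn(bi)),
      t_total = task_s + 2, burn_in = 2)
    x <- x - mean(x)
    x / max(sd(x), 1e-12)
  })
  wv <- c(w$w_low, w$w_medium, w$w_high)
  C <- vapply(outs, function(x) {
    ps <- welch_psd(as.numeric(x), fs, seg_len = min(round(2 * fs), length(x)))
    tot <- sum(ps$psd[ps$freq >= 4 & ps$freq <= 55])
    vapply(band_edges, function(b) {
      hi <- min(b$f_high, 55)
      sum(ps$psd[ps$freq >= b$f_low & ps$freq < hi]) / max(tot, 1e-300)
    }, 1.0)
  }, numeric(3))
  e <- tryCatch(solve(C, wv), error = function(err) wv)
  if (any(e < 0)) e <- wv
  mix_populations(outs, population_weights(sqrt(e[1]), sqrt(e[2]), sqrt(e[3])))
}

#' Generate recordings for all subjects of a protocol
#'
#' @inheritParams generate_subject_recordings
#' @return Named list of [trial_set()]s, one per subject.
#' @export
generate_recordings <- function(protocol, scenario) {
  out <- lapply(seq_len(protocol$n_subjects), function(s)
    generate_subject_recordings(protocol, scenario, s))
  names(out) <- paste0("S", seq_len(protocol$n_subjects))
  out
}

#' Split sessions into template and test sets
#'
#' Session 1 becomes the template/training set; the remaining sessions form
#' the test set.  Disjointness is guaranteed by session id.
#'
#' @param ts A [trial_set()] with at least two sessions.
#' @return List with `template` and `test` [trial_set()]s.
#' @export
split_sessions <- function(ts) {
  stopifnot(inherits(ts, "trial_set"))
  ses <- sort(unique(ts$session))
  if (length(ses) < 2)
    stop("need at least 2 sessions to split (got ", length(ses), ")")
  list(template = subset_trials(ts, ts$session == ses[1]),
       test = subset_trials(ts, ts$session != ses[1]))
}

#' Simulate the theoretical scalp EEG counterpart of a scenario
#'
#' The "simulated" input fed to the GAN converter: same source model and
#' forward projection as the surrogate recordings but without subject jitter
#' and without sensor noise (the theoretical-only simulation).
#'
#' @param protocol A [recording_protocol()].
#' @param scenario A [scenario_config()].
#' @param trials_per_class Number of simulated trials per class.
#' @param seed Seed offset so different draws are independent.
#' @return A [trial_set()] (session id 0).
#' @export
simulate_scalp_trials <- function(protocol, scenario, trials_per_class = 6,
                                  seed = 0L) {
  classes <- protocol$classes
  fs <- protocol$fs
  nsmp <- round(protocol$task_s * fs)
  dips <- lapply(classes, place_dipole, model = scenario$model)
  names(dips) <- classes
  lf <- analytic_leadfield(scenario$model, scenario$montage, dips)
  bands <- nmm_band_defaults()
  nch <- length(scenario$montage$labels)
  n_trial <- trials_per_class * length(classes)
  data <- array(0, c(n_trial, nsmp, nch))
  labels <- character(n_trial)
  k <- 0L
  for (cl_i in seq_along(classes)) {
    cl <- classes[cl_i]
    w <- scenario$class_weights[[cl]]
    for (tr in seq_len(trials_per_class)) {
      k <- k + 1L
      src <- class_source(bands, w, protocol$task_s, 1 / fs,
                          function(bi) sub_seed(scenario$seed, 9000 + seed,
                                                cl_i, tr, bi))
      data[k, , ] <- project_to_scalp(src, lf, dips[[cl]], scenario$montage,
                                      which_dipole = cl_i)
      labels[k] <- cl
    }
  }
  data <- data * (scenario$amplitude_uV / sqrt(mean(data^2)))
  trial_set(data, labels, fs, 0L, "SIM", scenario$montage$labels)
}
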