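test_that("sigmoid matches its closed form, midpoint and saturation", {
  sp <- sigmoid_params()
  expect_equal(sigmoid_rate(6, sp), 2.5)                       # Sigm(s0) = e0
  expect_equal(sigmoid_rate(1e6, sp), 5.0, tolerance = 1e-12)  # 2 e0
  expect_equal(sigmoid_rate(0, sp), 5 / (1 + exp(3.36)), tolerance = 1e-12)
  expect_equal(round(sigmoid_rate(0, sp), 4), 0.1678)
  v <- seq(-50, 50, by = 0.5)
  s <- sigmoid_rate(v, sp)
  expect_true(all(diff(s) > 0))            # strictly increasing
  expect_true(all(s > 0 & s < 2 * sp$e0))  # bounded
  expect_error(sigmoid_rate(NaN, sp), "non-finite")
})

test_that("state derivatives reproduce hand-evaluated drive terms", {
  low <- nmm_band_defaults()$low
  d0 <- nmm_derivatives(rep(0, 8), low, p = 0)
  expect_equal(d0[1:4], rep(0, 4))
  expect_equal(d0[5], 2.7 * 40 * sigmoid_rate(0), tolerance = 1e-12)
  expect_equal(d0[5], 18.12, tolerance = 1e-3)
  d60 <- nmm_derivatives(rep(0, 8), low, p = 60)
  expect_equal(d60[6], 108 * (sigmoid_rate(0) + 60 / 108), tolerance = 1e-12)
  expect_equal(d60[6], 78.1, tolerance = 1e-3)
  # zero gains reduce every drive to pure damped decay
  pp0 <- low; pp0$A <- pp0$B <- pp0$G <- 1e-300
  st <- c(1, -2, 0.5, 3, 0.1, 0.2, -0.3, 0.4)
  dd <- nmm_derivatives(st, pp0, p = 0)
  expect_equal(dd[5], -2 * low$a * st[5] - low$a^2 * st[1], tolerance = 1e-6)
  expect_equal(dd[8], -2 * low$g * st[8] - low$g^2 * st[4], tolerance = 1e-6)
})

test_that("exogenous noise honors its moments, seeding and zero-variance", {
  sp <- exogenous_input_spec(mean = 60, variance = 100, n = 1e5, seed = 42)
  x <- exogenous_noise(sp)
  expect_lt(abs(mean(x) - 60), 0.3)
  expect_lt(abs(var(x) - 100), 3)
  expect_identical(x, exogenous_noise(sp))
  x0 <- exogenous_noise(exogenous_input_spec(variance = 0, n = 10, seed = 1))
  expect_equal(x0, rep(60, 10))
})

test_that("RK4 integration is deterministic, bounded, and 4th order", {
  low <- nmm_band_defaults()$low
  inp <- exogenous_input_spec(n = 1, seed = 7)
  x1 <- integrate_population(low, input = inp, t_total = 5, burn_in = 1)
  x2 <- integrate_population(low, input = inp, t_total = 5, burn_in = 1)
  expect_identical(as.numeric(x1), as.numeric(x2))
  expect_true(all(abs(x1) < 1e3))
  expect_equal(attr(x1, "fs"), 1000)
  # order check on smooth (noise-free) input, no ignition discontinuity;
  # dt well below the fastest rate constant so the asymptotic regime holds
  run_dt <- function(dt) {
    inp <- exogenous_input_spec(mean = 60, variance = 0, n = 1, dt = dt)
    integrate_population(nmm_band_defaults()$medium, input = inp,
                         t_total = 0.5, burn_in = 0, ignition = 0)
  }
  a <- run_dt(5e-4); b <- run_dt(2.5e-4); c <- run_dt(1.25e-4)
  e1 <- max(abs(a - b[seq(2, length(b), by = 2)]))
  e2 <- max(abs(b[seq(2, length(b), by = 2)] - c[seq(4, length(c), by = 4)]))
  expect_gt(e1 / e2, 16 * 0.8)
  expect_lt(e1 / e2, 16 * 1.2)
})

test_that("divergent parameter sets raise a named blow-up error", {
  bad <- population_params("low", A = 500, B = 3.2, G = 27,
                           a = 40, b = 20, g = 300)
  expect_error(
    integrate_population(bad, input = exogenous_input_spec(n = 1, seed = 1),
                         t_total = 3, burn_in = 1, blow_threshold = 1e3),
    "blow-up.*low")
})

test_that("population mixing is the pointwise weighted sum and linear", {
  a <- sin(1:100); b <- cos(1:100); c <- 1:100 / 100
  w1 <- population_weights(1, 0, 0)
  expect_equal(mix_populations(list(a, b, c), w1), a)
  w <- population_weights(0.1190, 0.3332, 0.5478)  # raise-brow weights
  m <- mix_populations(list(a, b, c), w)
  expect_equal(m, 0.1190 * a + 0.3332 * b + 0.5478 * c)
  w2 <- population_weights(2 * 0.1190, 2 * 0.3332, 2 * 0.5478)
  expect_equal(mix_populations(list(a, b, c), w2), 2 * m)
  expect_error(mix_populations(list(a, b, c[-1]), w), "length")
})

test_that("band weights recover a pure tone and a flat spectrum", {
  fs <- 250
  t <- seq(0, 8 - 1 / fs, by = 1 / fs)
  tone <- array(rep(sin(2 * pi * 10 * t), 2), c(1, length(t), 2))
  ts_tone <- trial_set(tone, "mRB", fs)
  w <- band_weights_from_reference(ts_tone)
  expect_gt(w$w_low, 0.95)
  expect_lt(w$w_medium + w$w_high, 0.05)
  set.seed(5)
  wn <- array(rnorm(4 * length(t) * 2), c(4, length(t), 2))
  ww <- band_weights_from_reference(trial_set(wn, rep("mRB", 4), fs))
  expect_equal(ww$w_low, 8 / 51, tolerance = 0.12)
  expect_equal(ww$w_medium, 18 / 51, tolerance = 0.12)
  expect_equal(ww$w_high, 25 / 51, tolerance = 0.12)
  bad <- band_definition("x", 130, 200)  # above Nyquist after clipping
  expect_error(
    band_weights_from_reference(ts_tone, bands = list(bad, bad, bad)),
    "empty")
})

test_that("each population's spectral peak lies in its designated band", {
  bands <- nmm_band_defaults()
  edges <- list(low = c(4, 12), medium = c(12, 30), high = c(30, 100))
  for (nm in names(bands)) {
    x <- integrate_population(
      bands[[nm]], input = exogenous_input_spec(n = 1, seed = 11),
      t_total = 12, burn_in = 2)
    pk <- dominant_peak(x, 1000, c(1, 100))
    expect_gte(pk, edges[[nm]][1])
    expect_lte(pk, edges[[nm]][2])
  }
})

test_that("raising G shifts the high-band peak monotonically", {
  base <- nmm_band_defaults()$high
  peaks <- vapply(c(45, 60, 75), function(G) {
    pp <- base; pp$G <- G
    x <- integrate_population(pp, input = exogenous_input_spec(n = 1, seed = 4),
                              t_total = 18, burn_in = 2)
    dominant_peak(x, 1000, c(15, 100), seg_len = 4000)
  }, 1.0)
  expect_true(all(diff(peaks) > 0))
})
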