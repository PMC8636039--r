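test_that("architecture specs enforce the canonical invariants", {
  expect_error(generator_spec(1000, 8, filters = c(64, 52, 42, 36, 7)),
               "filters")
  expect_error(discriminator_spec(30, 8), "window")
  gs <- generator_spec(1000, 8)
  expect_equal(gs$filters, c(64L, 52L, 42L, 36L, 8L))
  expect_equal(gs$kernels, c(64L, 32L, 16L, 6L, 2L))
  ds <- discriminator_spec(100, 8)
  expect_equal(ds$filters, c(16L, 8L, 4L, 2L))
  expect_equal(ds$dropout, 0.4)
})

test_that("label embedding maps one-hot to a LeakyReLU channel", {
  w <- list(W = matrix(0, 4, 50), b = numeric(50))
  e <- embed_label(c(0, 1, 0, 0), w)
  expect_equal(dim(e), c(50L, 1L))
  expect_true(all(e == 0))
  set.seed(1)
  w$W <- matrix(rnorm(200), 4, 50)
  e2 <- embed_label(c(0, 1, 0, 0), w, alpha = 0.2)
  expect_equal(as.numeric(e2),
               ifelse(w$W[2, ] > 0, w$W[2, ], 0.2 * w$W[2, ]))
  expect_error(embed_label(c(0.5, 0.5, 0, 0), w), "one-hot")
})

test_that("generator conserves shape, bounds output, and is deterministic", {
  g <- build_generator(generator_spec(400, 6), seed = 3)
  X <- matrix(rnorm(2400), 400, 6)
  oh <- c(1, 0, 0, 0)
  y1 <- simbci:::generator_forward(g, X, oh)
  expect_equal(dim(y1), c(400L, 6L))
  expect_true(all(abs(y1) < 1))
  expect_identical(y1, simbci:::generator_forward(g, X, oh))
})

test_that("discriminator outputs calibrated scores in (0, 1)", {
  ps <- vapply(1:10, function(s) {
    d <- build_discriminator(discriminator_spec(100, 4), seed = s)
    set.seed(100 + s)
    Wc <- array(rnorm(100 * 4 * 8), c(100, 4, 8))
    oh <- diag(4)[rep(1:4, 2), ]
    mean(simbci:::discriminator_forward_batch(d, Wc, oh)$p)
  }, 1.0)
  expect_true(all(ps > 0 & ps < 1))
  expect_lt(abs(mean(ps) - 0.5), 0.2)
})

test_that("batched and single discriminator passes agree exactly", {
  d <- build_discriminator(discriminator_spec(100, 4), seed = 5)
  set.seed(2)
  Wc <- array(rnorm(100 * 4 * 3), c(100, 4, 3))
  oh <- diag(4)[1:3, ]
  pb <- simbci:::discriminator_forward_batch(d, Wc, oh)$p
  for (i in 1:3)
    expect_equal(pb[i], simbci:::discriminator_forward(d, Wc[, , i], oh[i, ])$p)
})

test_that("network gradients agree with finite differences", {
  gs <- generator_spec(40, 2, filters = c(6, 5, 4, 3, 2),
                       kernels = c(7, 5, 3, 3, 2))
  g <- build_generator(gs, seed = 3)
  set.seed(9)
  X <- matrix(rnorm(80), 40, 2); oh <- c(0, 1, 0, 0)
  cache <- simbci:::generator_forward(g, X, oh, cache = TRUE)
  gr <- simbci:::generator_backward(g, cache, 2 * cache$out)
  loss <- function(g) sum(simbci:::generator_forward(g, X, oh)^2)
  eps <- 1e-6
  for (i in c(1, 17, 53)) {
    gp <- g; gp$convs[[1]]$W[i] <- gp$convs[[1]]$W[i] + eps
    gm <- g; gm$convs[[1]]$W[i] <- gm$convs[[1]]$W[i] - eps
    expect_equal(gr$convs[[1]]$dW[i], (loss(gp) - loss(gm)) / (2 * eps),
                 tolerance = 1e-4)
  }
  ds <- discriminator_spec(40, 2, filters = c(4, 3, 2, 2),
                           kernels = c(5, 5, 3, 3))
  d <- build_discriminator(ds, seed = 4)
  W0 <- matrix(rnorm(80), 40, 2); oh1 <- c(1, 0, 0, 0)
  fw <- simbci:::discriminator_forward(d, W0, oh1)
  bk <- simbci:::discriminator_backward(d, fw, fw$p)  # BCE target 0
  dl <- function(d, W) -log(1 - simbci:::discriminator_forward(d, W, oh1)$p)
  for (i in c(3, 11)) {
    Wp <- W0; Wp[i] <- Wp[i] + eps
    Wm <- W0; Wm[i] <- Wm[i] - eps
    expect_equal(bk$dWindow[i], (dl(d, Wp) - dl(d, Wm)) / (2 * eps),
                 tolerance = 1e-4)
  }
})

test_that("window slicing partitions trials and preserves labels", {
  ts <- random_trial_set(n = 3, nsmp = 4000, nch = 2)
  wb <- slice_windows(ts, 100)
  expect_equal(dim(wb$windows), c(120L, 100L, 2L))   # 40 windows per trial
  expect_equal(wb$label_chr, rep(ts$labels, each = 40))
  expect_true(all(rowSums(wb$labels) == 1))
  # exact partition: concatenating windows restores the trial
  back <- do.call(rbind, lapply(1:40, function(k) wb$windows[k, , ]))
  expect_equal(back, ts$data[1, , ])
  expect_error(slice_windows(ts, 5000), "exceeds")
})

test_that("training runs, records finite losses, and is reproducible", {
  sim <- random_trial_set(n = 8, nsmp = 300, nch = 4, seed = 1)
  real <- random_trial_set(n = 8, nsmp = 300, nch = 4, seed = 2)
  g <- build_generator(generator_spec(300, 4), seed = 1)
  d <- build_discriminator(discriminator_spec(100, 4), seed = 2)
  cfg <- train_config(iterations = 5, batch = 8, trials_per_iter = 2, seed = 3)
  tr1 <- train_gan(g, d, sim, real, cfg)
  tr2 <- train_gan(g, d, sim, real, cfg)
  expect_true(all(is.finite(tr1$history$d_loss)))
  expect_true(all(is.finite(tr1$history$g_loss)))
  expect_identical(tr1$history, tr2$history)
  expect_error(train_gan(g, d, sim, random_trial_set(nch = 3), cfg))
})

test_that("discriminator separates trivially separable data within 50 iterations", {
  arr <- function(v) array(v, c(8, 1000, 8))
  sim <- trial_set(arr(-0.5), rep(me_classes(), 2), 1000)
  real <- trial_set(arr(0.5), rep(me_classes(), 2), 1000)
  g <- build_generator(generator_spec(1000, 8), seed = 4)
  d <- build_discriminator(discriminator_spec(100, 8), seed = 5)
  tr <- train_gan(g, d, sim, real,
                  train_config(iterations = 50, batch = 64,
                               trials_per_iter = 2, seed = 6))
  expect_lt(min(tr$history$d_loss), 0.1)
})

test_that("conversion preserves shape, rescales amplitude, checks labels", {
  sim <- random_trial_set(n = 4, nsmp = 300, nch = 4, seed = 1)
  real <- random_trial_set(n = 4, nsmp = 300, nch = 4, seed = 2)
  g <- build_generator(generator_spec(300, 4), seed = 1)
  d <- build_discriminator(discriminator_spec(100, 4), seed = 2)
  tr <- train_gan(g, d, sim, real,
                  train_config(iterations = 2, batch = 4, trials_per_iter = 2,
                               seed = 3))
  out <- convert(tr, sim)
  expect_equal(dim(out$data), dim(sim$data))
  expect_identical(out$data, convert(tr, sim)$data)
  expect_true(all(out$data >= min(real$data) - 1e-9 &
                    out$data <= max(real$data) + 1e-9))
  expect_error(convert(tr, sim, labels = rep("zzz", 4)), "outside")
  # changing the conditioning label changes the output
  o1 <- convert(tr, subset_trials(sim, 1), labels = "mRB")$data
  o2 <- convert(tr, subset_trials(sim, 1), labels = "mLS")$data
  expect_gt(sqrt(mean((o1 - o2)^2)), 0)
})

test_that("converter save/load round-trips weights and inference", {
  sim <- random_trial_set(n = 4, nsmp = 300, nch = 4, seed = 1)
  real <- random_trial_set(n = 4, nsmp = 300, nch = 4, seed = 2)
  g <- build_generator(generator_spec(300, 4), seed = 1)
  d <- build_discriminator(discriminator_spec(100, 4), seed = 2)
  tr <- train_gan(g, d, sim, real,
                  train_config(iterations = 2, batch = 4, trials_per_iter = 2,
                               seed = 3))
  f <- tempfile(fileext = ".json")
  save_converter(tr, f)
  tr2 <- load_converter(f)
  expect_equal(convert(tr2, sim)$data, convert(tr, sim)$data,
               tolerance = 1e-12)
  expect_equal(tr2$history$d_loss, tr$history$d_loss)
})
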