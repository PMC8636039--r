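# Conditional GAN that converts simulated multichannel scalp EEG into
# "practical" EEG sharing the statistics of real template windows.  The
# generator is a label-conditioned five-layer 1-D convolutional map applied
# to whole trials; the discriminator judges 100-ms windows.

#' Generator architecture specification
#'
#' Five same-padding stride-1 1-D convolutions over the temporal dimension
#' (filters 64, 52, 42, 36, channels; kernels 64, 32, 16, 6, 2), LeakyReLU
#' activations and a final tanh, applied to the simulated trial concatenated
#' with an embedded label channel.
#'
#' @param timestamps Samples per trial.
#' @param channels EEG channels.
#' @param n_classes Number of condition classes.
#' @param filters,kernels Convolution stack (validated against the canonical
#'   design; the last filter count must equal `channels`).
#' @param alpha LeakyReLU negative slope.
#' @return A `generator_spec`.
#' @export
generator_spec <- function(timestamps, channels, n_classes = 4,
                           filters = c(64, 52, 42, 36, channels),
                           kernels = c(64, 32, 16, 6, 2), alpha = 0.2) {
  stopifnot(length(filters) == 5, length(kernels) == 5,
            filters[5] == channels, all(filters > 0), all(kernels > 0),
            timestamps >= max(kernels), n_classes >= 2)
  structure(list(timestamps = as.integer(timestamps),
                 channels = as.integer(channels),
                 n_classes = as.integer(n_classes),
                 filters = as.integer(filters), kernels = as.integer(kernels),
                 alpha = alpha), class = "generator_spec")
}

#' Discriminator architecture specification
#'
#' Four valid-padding stride-1 1-D convolutions (filters 16, 8, 4, 2; kernels
#' 32, 16, 8, 4), LeakyReLU, flatten, dropout 0.4 and a sigmoid output unit,
#' applied to a window concatenated with an embedded label channel.
#'
#' @param window Window length in samples (100 at 1000 Hz).
#' @param channels EEG channels.
#' @param n_classes Number of condition classes.
#' @param filters,kernels Convolution stack.
#' @param dropout Dropout rate before the output unit.
#' @param alpha LeakyReLU negative slope.
#' @return A `discriminator_spec`.
#' @export
discriminator_spec <- function(window = 100, channels, n_classes = 4,
                               filters = c(16, 8, 4, 2),
                               kernels = c(32, 16, 8, 4),
                               dropout = 0.4, alpha = 0.2) {
  stopifnot(length(filters) == 4, length(kernels) == 4, all(filters > 0),
            window > sum(kernels - 1), dropout >= 0, dropout < 1)
  structure(list(window = as.integer(window), channels = as.integer(channels),
                 n_classes = as.integer(n_classes),
                 filters = as.integer(filters), kernels = as.integer(kernels),
                 dropout = dropout, alpha = alpha),
            class = "discriminator_spec")
}

#' Training configuration (iterations, RMSprop settings, batch size)
#'
#' Defaults follow the canonical setup: 200 iterations, binary cross-entropy,
#' RMSprop with learning rate 0.0008 for the discriminator and 0.0004 for the
#' stacked generator, clip value 1.0, decay 1e-8, batch of 64 windows.
#'
#' @param iterations Training iterations.
#' @param lr_d,lr_gan Discriminator and stacked-GAN learning rates.
#' @param clipvalue Element-wise gradient clip.
#' @param decay Inverse-time learning-rate decay.
#' @param batch Window batch size per iteration.
#' @param trials_per_iter Distinct simulated trials converted per iteration
#'   (fake windows are sliced from these at random offsets).
#' @param seed RNG seed.
#' @return A `train_config`.
#' @export
train_config <- function(iterations = 200, lr_d = 8e-4, lr_gan = 4e-4,
                         clipvalue = 1.0, decay = 1e-8, batch = 64,
                         trials_per_iter = 4, seed = 1L) {
  stopifnot(iterations >= 1, lr_d > 0, lr_gan > 0, batch >= 2,
            trials_per_iter >= 1)
  structure(list(iterations = as.integer(iterations), lr_d = lr_d,
                 lr_gan = lr_gan, clipvalue = clipvalue, decay = decay,
                 batch = as.integer(batch),
                 trials_per_iter = as.integer(trials_per_iter),
                 seed = as.integer(seed)), class = "train_config")
}

#' Build a generator network
#'
#' @param spec A [generator_spec()].
#' @param seed Seed for the Glorot-uniform initialisation.
#' @return A `generator` object holding the embedding and convolution weights.
#' @export
build_generator <- function(spec, seed = 1L) {
  stopifnot(inherits(spec, "generator_spec"))
  withr_seed(seed, {
    cins <- c(spec$channels + 1L, spec$filters[-5])
    acts <- c(rep("lrelu", 4), "tanh")
    convs <- lapply(seq_len(5), function(i)
      new_conv(cins[i], spec$filters[i], spec$kernels[i], "same", acts[i]))
    structure(list(spec = spec,
                   embed = new_dense(spec$n_classes, spec$timestamps),
                   convs = convs), class = "generator")
  })
}

#' Build a discriminator network
#'
#' @param spec A [discriminator_spec()].
#' @param seed Seed for the Glorot-uniform initialisation.
#' @return A `discriminator` object.
#' @export
build_discriminator <- function(spec, seed = 1L) {
  stopifnot(inherits(spec, "discriminator_spec"))
  withr_seed(seed, {
    cins <- c(spec$channels + 1L, spec$filters[-4])
    convs <- lapply(seq_len(4), function(i)
      new_conv(cins[i], spec$filters[i], spec$kernels[i], "valid", "lrelu"))
    tout <- spec$window
    for (k in spec$kernels) tout <- tout - k + 1L
    flat <- tout * spec$filters[4]
    structure(list(spec = spec,
                   embed = new_dense(spec$n_classes, spec$window),
                   convs = convs,
                   out = new_dense(flat, 1L)), class = "discriminator")
  })
}

# --- forward/backward passes ------------------------------------------------

generator_forward <- function(g, X, one_hot, cache = FALSE) {
  al <- g$spec$alpha
  ze <- as.numeric(one_hot %*% g$embed$W) + g$embed$b
  Xc <- cbind(matrix(lrelu(ze, al), ncol = 1), X)
  hs <- vector("list", 5); zs <- vector("list", 5)
  h <- Xc
  for (i in seq_len(5)) {
    hs[[i]] <- h
    r <- conv_forward_a(g$convs[[i]], h, al)
    zs[[i]] <- r$Z
    h <- r$A
  }
  if (cache) list(out = h, hs = hs, zs = zs, ze = ze, one_hot = one_hot)
  else h
}

conv_forward_a <- function(ly, X, alpha) {
  Z <- conv1d_fwd_cpp(X, ly$W, ly$b, ly$K, ly$padl, ly$padr)
  A <- switch(ly$act, lrelu = lrelu(Z, alpha), tanh = tanh(Z), linear = Z)
  list(Z = Z, A = A)
}

generator_backward <- function(g, cache, dOut) {
  al <- g$spec$alpha
  grads <- list(convs = vector("list", 5))
  dA <- dOut
  for (i in 5:1) {
    ly <- g$convs[[i]]
    Z <- cache$zs[[i]]
    dZ <- if (ly$act == "tanh") dA * (1 - tanh(Z)^2) else dA * lrelu_grad(Z, al)
    bk <- conv1d_bwd_cpp(cache$hs[[i]], ly$W, dZ, ly$K, ly$padl, ly$padr)
    grads$convs[[i]] <- list(dW = bk$dW, db = as.numeric(bk$db))
    dA <- bk$dX
  }
  de <- dA[, 1] * lrelu_grad(cache$ze, al)
  grads$embed <- list(dW = outer(as.numeric(cache$one_hot), de), db = de)
  grads
}

# Batched discriminator pass.  `Wc` is a cube (window_len, channels, n);
# `onehots` is n x n_classes.  Returns scores and the caches needed for the
# batched backward pass.
discriminator_forward_batch <- function(d, Wc, onehots, train = FALSE) {
  sp <- d$spec; al <- sp$alpha
  n <- dim(Wc)[3]
  Ze <- onehots %*% d$embed$W +
    matrix(d$embed$b, n, sp$window, byrow = TRUE)          # n x window
  Xc <- array(0, c(sp$window, sp$channels + 1L, n))
  Xc[, 1, ] <- t(lrelu(Ze, al))
  Xc[, -1, ] <- Wc
  hs <- vector("list", 4); zs <- vector("list", 4)
  h <- Xc
  for (i in seq_len(4)) {
    ly <- d$convs[[i]]
    hs[[i]] <- h
    Z <- conv1d_fwd_batch_cpp(h, ly$W, ly$b, ly$K, ly$padl, ly$padr)
    zs[[i]] <- Z
    h <- lrelu(Z, al)
  }
  cd <- dim(h)
  flat <- matrix(h, cd[1] * cd[2], cd[3])                  # features x n
  if (train && sp$dropout > 0) {
    mask <- matrix((runif(length(flat)) >= sp$dropout) / (1 - sp$dropout),
                   nrow(flat), ncol(flat))
  } else mask <- matrix(1, nrow(flat), ncol(flat))
  fd <- flat * mask
  z <- as.numeric(crossprod(fd, d$out$W)) + d$out$b
  p <- 1 / (1 + exp(-z))
  list(p = p, z = z, flat = flat, mask = mask, hs = hs, zs = zs, Ze = Ze,
       onehots = onehots, conv_dim = cd)
}

# dz: dL/dz per window (length n)
discriminator_backward_batch <- function(d, cache, dz) {
  al <- d$spec$alpha
  fd <- cache$flat * cache$mask
  grads <- list(out = list(dW = fd %*% dz, db = sum(dz)))
  dflat <- (as.numeric(d$out$W) %o% dz) * cache$mask
  cd <- cache$conv_dim
  dA <- array(dflat, cd)
  gc <- vector("list", 4)
  for (i in 4:1) {
    ly <- d$convs[[i]]
    dZ <- dA * lrelu_grad(cache$zs[[i]], al)
    bk <- conv1d_bwd_batch_cpp(cache$hs[[i]], ly$W, dZ, ly$K, ly$padl, ly$padr)
    gc[[i]] <- list(dW = bk$dW, db = as.numeric(bk$db))
    dA <- bk$dX
  }
  grads$convs <- gc
  dE <- t(dA[, 1, ]) * lrelu_grad(cache$Ze, al)            # n x window
  grads$embed <- list(dW = crossprod(cache$onehots, dE), db = colSums(dE))
  grads$dWindows <- dA[, -1, , drop = FALSE]
  grads
}

discriminator_forward <- function(d, W, one_hot, train = FALSE) {
  sp <- d$spec; al <- sp$alpha
  ze <- as.numeric(one_hot %*% d$embed$W) + d$embed$b
  Xc <- cbind(matrix(lrelu(ze, al), ncol = 1), W)
  hs <- vector("list", 4); zs <- vector("list", 4)
  h <- Xc
  for (i in seq_len(4)) {
    hs[[i]] <- h
    r <- conv_forward_a(d$convs[[i]], h, al)
    zs[[i]] <- r$Z
    h <- r$A
  }
  flat <- as.numeric(h)
  if (train && sp$dropout > 0) {
    mask <- (runif(length(flat)) >= sp$dropout) / (1 - sp$dropout)
  } else mask <- rep(1, length(flat))
  fd <- flat * mask
  z <- sum(fd * d$out$W) + d$out$b
  p <- 1 / (1 + exp(-z))
  list(p = p, z = z, flat = flat, mask = mask, hs = hs, zs = zs, ze = ze,
       one_hot = one_hot, conv_dim = dim(h))
}

# dz = dL/dz at the sigmoid pre-activation (p - target for BCE)
discriminator_backward <- function(d, cache, dz) {
  al <- d$spec$alpha
  grads <- list()
  grads$out <- list(dW = dz * cache$flat * cache$mask, db = dz)
  dflat <- dz * as.numeric(d$out$W) * cache$mask
  dA <- matrix(dflat, cache$conv_dim[1], cache$conv_dim[2])
  gc <- vector("list", 4)
  for (i in 4:1) {
    ly <- d$convs[[i]]
    dZ <- dA * lrelu_grad(cache$zs[[i]], al)
    bk <- conv1d_bwd_cpp(cache$hs[[i]], ly$W, dZ, ly$K, ly$padl, ly$padr)
    gc[[i]] <- list(dW = bk$dW, db = as.numeric(bk$db))
    dA <- bk$dX
  }
  grads$convs <- gc
  de <- dA[, 1] * lrelu_grad(cache$ze, al)
  grads$embed <- list(dW = outer(as.numeric(cache$one_hot), de), db = de)
  grads$dWindow <- dA[, -1, drop = FALSE]
  grads
}

# --- windowing --------------------------------------------------------------

#' Slice trials into labelled windows
#'
#' Non-overlapping windows (stride defaults to the window length, so the
#' windows partition each trial); each window inherits its trial's label.
#'
#' @param trials A [trial_set()].
#' @param window_len Window length in samples (default 100, i.e. 100 ms at
#'   1000 Hz).
#' @param stride Step between window starts.
#' @return A `window_batch`: array `windows x window_len x channels`, one-hot
#'   `labels` matrix, `classes`, `trial_index`.
#' @export
slice_windows <- function(trials, window_len = 100, stride = window_len) {
  stopifnot(inherits(trials, "trial_set"))
  d <- dim(trials$data)
  if (window_len > d[2])
    stop("window_len ", window_len, " exceeds trial length ", d[2])
  starts <- seq(1L, d[2] - window_len + 1L, by = stride)
  classes <- sort(unique(trials$labels))
  nw <- length(starts) * d[1]
  W <- array(0, c(nw, window_len, d[3]))
  lab <- character(nw); tix <- integer(nw)
  k <- 1L
  for (i in seq_len(d[1])) for (s in starts) {
    W[k, , ] <- trials$data[i, s:(s + window_len - 1L), ]
    lab[k] <- trials$labels[i]; tix[k] <- i
    k <- k + 1L
  }
  onehot <- t(vapply(lab, function(l) as.numeric(classes == l),
                     numeric(length(classes))))
  structure(list(windows = W, labels = onehot, classes = classes,
                 label_chr = lab, trial_index = tix,
                 window_len = as.integer(window_len)),
            class = "window_batch")
}

# --- normalization ----------------------------------------------------------

# per-channel min-max parameters mapping data into (-1, 1)
minmax_fit <- function(data) {
  lo <- apply(data, 3, min); hi <- apply(data, 3, max)
  pad <- pmax(hi - lo, 1e-12) * 0.0
  list(lo = lo - pad, hi = hi + pad)
}

minmax_apply <- function(data, nm) {
  for (ch in seq_len(dim(data)[3]))
    data[, , ch] <- 2 * (data[, , ch] - nm$lo[ch]) /
      max(nm$hi[ch] - nm$lo[ch], 1e-12) - 1
  data
}

minmax_invert <- function(data, nm) {
  for (ch in seq_len(dim(data)[3]))
    data[, , ch] <- (data[, , ch] + 1) / 2 *
      max(nm$hi[ch] - nm$lo[ch], 1e-12) + nm$lo[ch]
  data
}

# --- training ---------------------------------------------------------------

#' Train the conditional GAN converter
#'
#' Alternating loop per iteration: (1) the discriminator is trained on real
#' windows (target 1) and windows sliced at random offsets from
#' generator-converted simulated trials (target 0) with binary cross-entropy;
#' (2) the discriminator is frozen and the stacked
#' generator-slicer-discriminator is trained toward target 1.  Both losses are
#' recorded every iteration.  Fully seeded.
#'
#' @param g A `generator` (from [build_generator()]).
#' @param d A `discriminator` (from [build_discriminator()]).
#' @param simulated,real_templates [trial_set()]s sharing channels and fs.
#' @param cfg A [train_config()].
#' @return A `trained_converter`: updated networks, normalisation parameters,
#'   class set and a loss history data frame (`iter`, `d_loss`, `g_loss`).
#' @export
train_gan <- function(g, d, simulated, real_templates, cfg = train_config()) {
  stopifnot(inherits(g, "generator"), inherits(d, "discriminator"),
            dim(simulated$data)[3] == dim(real_templates$data)[3],
            simulated$fs == real_templates$fs)
  spec <- g$spec
  if (dim(simulated$data)[2] != spec$timestamps)
    stop("simulated trial length != generator timestamps")
  classes <- sort(unique(c(simulated$labels, real_templates$labels)))
  if (length(classes) != spec$n_classes)
    stop("class count mismatch with generator spec")
  wlen <- d$spec$window
  sim_nm <- minmax_fit(simulated$data)
  real_nm <- minmax_fit(real_templates$data)
  Xsim <- minmax_apply(simulated$data, sim_nm)
  real_wb <- slice_windows(
    trial_set(minmax_apply(real_templates$data, real_nm),
              real_templates$labels, real_templates$fs,
              real_templates$session, real_templates$subject,
              real_templates$channels), wlen)
  onehot_of <- function(l) as.numeric(classes == l)
  n_real <- dim(real_wb$windows)[1]
  opt_d <- rmsprop_state(); opt_g <- rmsprop_state()
  hist <- data.frame(iter = seq_len(cfg$iterations), d_loss = NA_real_,
                     g_loss = NA_real_)
  withr_seed(cfg$seed, {
    for (it in seq_len(cfg$iterations)) {
      nt <- min(cfg$trials_per_iter, dim(Xsim)[1])
      tsel <- sample.int(dim(Xsim)[1], nt)
      # generator forward (with caches reused by the stacked step)
      caches <- lapply(tsel, function(i)
        generator_forward(g, Xsim[i, , ], onehot_of(simulated$labels[i]),
                          cache = TRUE))
      # ---- discriminator step: batch real (target 1) + sliced fakes (0)
      rsel <- sample.int(n_real, cfg$batch, replace = cfg$batch > n_real)
      fidx <- sample.int(nt, cfg$batch, replace = TRUE)
      offs <- sample.int(spec$timestamps - wlen + 1L, cfg$batch, replace = TRUE)
      nb <- 2L * cfg$batch
      Wc <- array(0, c(wlen, spec$channels, nb))
      oh <- matrix(0, nb, spec$n_classes)
      for (b in seq_len(cfg$batch)) {
        Wc[, , b] <- real_wb$windows[rsel[b], , ]
        oh[b, ] <- real_wb$labels[rsel[b], ]
        Wc[, , cfg$batch + b] <-
          caches[[fidx[b]]]$out[offs[b]:(offs[b] + wlen - 1L), ]
        oh[cfg$batch + b, ] <- onehot_of(simulated$labels[tsel[fidx[b]]])
      }
      target <- rep(c(1, 0), each = cfg$batch)
      fw <- discriminator_forward_batch(d, Wc, oh, train = TRUE)
      hist$d_loss[it] <- mean(mapply(bce, fw$p, target))
      dg <- discriminator_backward_batch(d, fw, (fw$p - target) / nb)
      d <- apply_disc_grads(d, dg, opt_d, cfg$lr_d, it, cfg$clipvalue,
                            cfg$decay)
      # ---- generator (stacked) step: discriminator frozen, target 1
      gidx <- sample.int(nt, cfg$batch, replace = TRUE)
      goffs <- sample.int(spec$timestamps - wlen + 1L, cfg$batch, replace = TRUE)
      Wg <- array(0, c(wlen, spec$channels, cfg$batch))
      ohg <- matrix(0, cfg$batch, spec$n_classes)
      for (b in seq_len(cfg$batch)) {
        Wg[, , b] <- caches[[gidx[b]]]$out[goffs[b]:(goffs[b] + wlen - 1L), ]
        ohg[b, ] <- onehot_of(simulated$labels[tsel[gidx[b]]])
      }
      fwg <- discriminator_forward_batch(d, Wg, ohg, train = TRUE)
      hist$g_loss[it] <- mean(vapply(fwg$p, bce, 1.0, t = 1))
      bkg <- discriminator_backward_batch(d, fwg, (fwg$p - 1) / cfg$batch)
      dOuts <- lapply(seq_len(nt), function(i)
        matrix(0, spec$timestamps, spec$channels))
      for (b in seq_len(cfg$batch)) {
        i <- gidx[b]; o <- goffs[b]
        dOuts[[i]][o:(o + wlen - 1L), ] <-
          dOuts[[i]][o:(o + wlen - 1L), ] + bkg$dWindows[, , b]
      }
      gg <- NULL
      for (i in seq_len(nt))
        gg <- acc_grads(gg, generator_backward(g, caches[[i]], dOuts[[i]]))
      g <- apply_gen_grads(g, gg, opt_g, cfg$lr_gan, it, cfg$clipvalue,
                           cfg$decay)
      if (!is.finite(hist$d_loss[it]) || !is.finite(hist$g_loss[it]))
        stop(sprintf("NaN/Inf loss at iteration %d (d=%.4g g=%.4g)", it,
                     hist$d_loss[it], hist$g_loss[it]))
    }
  })
  real_rms <- apply(real_templates$data, 3, function(x) sqrt(mean(x^2)))
  structure(list(generator = g, discriminator = d, classes = classes,
                 sim_norm = sim_nm, real_norm = real_nm, real_rms = real_rms,
                 config = cfg,
                 channels = simulated$channels, fs = simulated$fs,
                 history = hist),
            class = "trained_converter")
}

bce <- function(p, t) {
  p <- min(max(p, 1e-12), 1 - 1e-12)
  -(t * log(p) + (1 - t) * log(1 - p))
}

acc_grads <- function(acc, g) {
  if (is.null(acc)) return(g)
  rec <- function(a, b) {
    if (is.list(a)) Map(rec, a, b) else a + b
  }
  rec(acc, g)
}

scale_grads <- function(g, s) {
  rec <- function(a) if (is.list(a)) lapply(a, rec) else a * s
  rec(g)
}

apply_disc_grads <- function(d, gr, opt, lr, it, clip, decay) {
  for (i in seq_len(4)) {
    d$convs[[i]]$W <- rmsprop_update(opt, paste0("cW", i), d$convs[[i]]$W,
                                     gr$convs[[i]]$dW, lr, it, clip, decay = decay)
    d$convs[[i]]$b <- rmsprop_update(opt, paste0("cb", i), d$convs[[i]]$b,
                                     gr$convs[[i]]$db, lr, it, clip, decay = decay)
  }
  d$embed$W <- rmsprop_update(opt, "eW", d$embed$W, gr$embed$dW, lr, it, clip,
                              decay = decay)
  d$embed$b <- rmsprop_update(opt, "eb", d$embed$b, gr$embed$db, lr, it, clip,
                              decay = decay)
  d$out$W <- rmsprop_update(opt, "oW", d$out$W, gr$out$dW, lr, it, clip,
                            decay = decay)
  d$out$b <- rmsprop_update(opt, "ob", d$out$b, gr$out$db, lr, it, clip,
                            decay = decay)
  d
}

apply_gen_grads <- function(g, gr, opt, lr, it, clip, decay) {
  for (i in seq_len(5)) {
    g$convs[[i]]$W <- rmsprop_update(opt, paste0("cW", i), g$convs[[i]]$W,
                                     gr$convs[[i]]$dW, lr, it, clip, decay = decay)
    g$convs[[i]]$b <- rmsprop_update(opt, paste0("cb", i), g$convs[[i]]$b,
                                     gr$convs[[i]]$db, lr, it, clip, decay = decay)
  }
  g$embed$W <- rmsprop_update(opt, "eW", g$embed$W, gr$embed$dW, lr, it, clip,
                              decay = decay)
  g$embed$b <- rmsprop_update(opt, "eb", g$embed$b, gr$embed$db, lr, it, clip,
                              decay = decay)
  g
}

#' Convert simulated trials into practical EEG
#'
#' Per-trial generator inference; the tanh output is rescaled from `(-1, 1)`
#' back to the real-template amplitude recorded at training time, and the
#' output trials carry the conditioning labels.
#'
#' @param trained A `trained_converter` from [train_gan()].
#' @param simulated A [trial_set()] with matching channel count.
#' @param labels Conditioning labels (defaults to the trials' own labels).
#' @param match_rms Additionally match each output channel's RMS (pooled over
#'   trials) to the template-session RMS recorded at training time.  The tanh
#'   head habitually under-uses its range early in training, so the plain
#'   min-max inversion alone systematically inflates or deflates amplitudes;
#'   RMS matching pins the converted data to the template amplitude.
#' @return A [trial_set()] of converted trials.
#' @export
convert <- function(trained, simulated, labels = simulated$labels,
                    match_rms = TRUE) {
  stopifnot(inherits(trained, "trained_converter"),
            dim(simulated$data)[3] == length(trained$channels))
  if (!all(labels %in% trained$classes))
    stop("labels outside trained classes: ",
         paste(setdiff(labels, trained$classes), collapse = ", "))
  X <- minmax_apply(simulated$data, trained$sim_norm)
  out <- array(0, dim(simulated$data))
  for (i in seq_len(dim(X)[1])) {
    oh <- as.numeric(trained$classes == labels[i])
    out[i, , ] <- generator_forward(trained$generator, X[i, , ], oh)
  }
  out <- minmax_invert(out, trained$real_norm)
  if (match_rms && !is.null(trained$real_rms)) {
    for (ch in seq_len(dim(out)[3])) {
      r <- sqrt(mean(out[, , ch]^2))
      if (r > 0 && trained$real_rms[ch] > 0)
        out[, , ch] <- out[, , ch] * (trained$real_rms[ch] / r)
    }
  }
  trial_set(out, labels, simulated$fs, simulated$session,
            simulated$subject, simulated$channels)
}

#' Mean discriminator score of a window batch
#'
#' Inference-mode (no dropout) scores, used to check that converted windows
#' sit closer to the real-template score than raw simulated windows.
#'
#' @param d A `discriminator`.
#' @param wb A `window_batch` whose windows are scaled to `(-1, 1)`.
#' @return Mean sigmoid score.
#' @export
discriminator_score <- function(d, wb) {
  n <- dim(wb$windows)[1]
  mean(vapply(seq_len(n), function(j)
    discriminator_forward(d, wb$windows[j, , ], wb$labels[j, ])$p, 1.0))
}

#' Save / load a trained converter as JSON plus metadata
#'
#' Weights and normalisation parameters are stored as a single JSON document
#' (text, portable); metadata records the architecture, training config and
#' class set.
#'
#' @param trained A `trained_converter`.
#' @param path Output path (`.json`).
#' @return `load_converter` returns the restored `trained_converter`
#'   (without optimizer state; loss history preserved).
#' @export
save_converter <- function(trained, path) {
  ser <- list(
    classes = trained$classes, channels = trained$channels, fs = trained$fs,
    gen_spec = unclass(trained$generator$spec),
    disc_spec = unclass(trained$discriminator$spec),
    config = unclass(trained$config),
    sim_norm = trained$sim_norm, real_norm = trained$real_norm,
    real_rms = trained$real_rms,
    history = as.list(trained$history),
    gen_weights = net_weights(trained$generator),
    disc_weights = net_weights(trained$discriminator))
  jsonlite::write_json(ser, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

net_weights <- function(net) {
  w <- list(embed_W = net$embed$W, embed_b = net$embed$b,
            convs = lapply(net$convs, function(c) list(W = c$W, b = c$b)))
  if (!is.null(net$out)) w$out <- list(W = net$out$W, b = net$out$b)
  w
}

#' @rdname save_converter
#' @export
load_converter <- function(path) {
  s <- jsonlite::read_json(path, simplifyVector = TRUE,
                           simplifyDataFrame = FALSE)
  s$history <- as.data.frame(lapply(s$history, unlist))
  gs <- do.call(generator_spec, s$gen_spec[c("timestamps", "channels",
                                             "n_classes", "filters", "kernels",
                                             "alpha")])
  ds <- do.call(discriminator_spec, s$disc_spec[c("window", "channels",
                                                  "n_classes", "filters",
                                                  "kernels", "dropout",
                                                  "alpha")])
  g <- build_generator(gs); d <- build_discriminator(ds)
  g <- restore_weights(g, s$gen_weights)
  d <- restore_weights(d, s$disc_weights)
  structure(list(generator = g, discriminator = d, classes = s$classes,
                 sim_norm = lapply(s$sim_norm, as.numeric),
                 real_norm = lapply(s$real_norm, as.numeric),
                 real_rms = as.numeric(s$real_rms),
                 config = do.call(train_config, s$config[c(
                   "iterations", "lr_d", "lr_gan", "clipvalue", "decay",
                   "batch", "trials_per_iter", "seed")]),
                 channels = s$channels, fs = s$fs,
                 history = as.data.frame(s$history)),
            class = "trained_converter")
}

restore_weights <- function(net, w) {
  net$embed$W <- as.matrix(w$embed_W); net$embed$b <- as.numeric(w$embed_b)
  for (i in seq_along(net$convs)) {
    net$convs[[i]]$W <- as.matrix(w$convs[[i]]$W)
    net$convs[[i]]$b <- as.numeric(w$convs[[i]]$b)
  }
  if (!is.null(net$out)) {
    net$out$W <- as.matrix(w$out$W); net$out$b <- as.numeric(w$out$b)
  }
  net
}
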