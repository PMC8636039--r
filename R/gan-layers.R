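# Minimal differentiable layer kit for the conditional GAN converter.
# Forward/backward passes are explicit; 1-D convolutions run through the
# compiled im2col/GEMM kernels.

lrelu <- function(x, alpha = 0.2) ifelse(x > 0, x, alpha * x)
lrelu_grad <- function(x, alpha = 0.2) ifelse(x > 0, 1, alpha)

glorot_mat <- function(nin, nout) {
  lim <- sqrt(6 / (nin + nout))
  matrix(runif(nin * nout, -lim, lim), nin, nout)
}

new_dense <- function(nin, nout) {
  list(W = glorot_mat(nin, nout), b = numeric(nout))
}

# Conv layer weights stored as (K*Cin) x F, matching the compiled kernel's
# patch layout (tap-major within channel).
new_conv <- function(cin, f, k, padding = c("same", "valid"), act = "lrelu") {
  padding <- match.arg(padding)
  if (padding == "same") {
    padl <- (k - 1L) %/% 2L; padr <- k - 1L - padl
  } else padl <- padr <- 0L
  list(W = glorot_mat(k * cin, f), b = numeric(f), K = as.integer(k),
       padl = as.integer(padl), padr = as.integer(padr), act = act, cin = cin, f = f)
}

# RMSprop with element-wise gradient clipping and keras-style inverse-time
# learning-rate decay.
rmsprop_state <- function() new.env(parent = emptyenv())

rmsprop_update <- function(state, key, param, grad, lr, iter,
                           clipvalue = 1.0, rho = 0.9, eps = 1e-7,
                           decay = 1e-8) {
  grad <- pmin(pmax(grad, -clipvalue), clipvalue)
  r <- state[[key]]
  if (is.null(r)) r <- grad * 0
  r <- rho * r + (1 - rho) * grad^2
  state[[key]] <- r
  lr_t <- lr / (1 + decay * iter)
  param - lr_t * grad / (sqrt(r) + eps)
}

check_one_hot <- function(one_hot) {
  if (!is.numeric(one_hot) || any(!one_hot %in% c(0, 1)) || sum(one_hot) != 1)
    stop("label must be a one-hot vector")
  invisible(TRUE)
}

#' Embed a one-hot class label as a signal channel
#'
#' Dense map from the one-hot label to `length` units with LeakyReLU
#' activation, reshaped to a `length x 1` column that the caller concatenates
#' with the signal along the channel axis.
#'
#' @param one_hot One-hot numeric label vector.
#' @param weights List with `W` (`n_classes x length`) and `b` (`length`);
#'   typically the trained embedding layer of a generator or discriminator.
#' @param alpha LeakyReLU negative slope.
#' @return `length x 1` matrix.
#' @export
embed_label <- function(one_hot, weights, alpha = 0.2) {
  check_one_hot(one_hot)
  z <- as.numeric(one_hot %*% weights$W) + weights$b
  matrix(lrelu(z, alpha), ncol = 1)
}
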