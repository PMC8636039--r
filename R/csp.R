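# One-vs-rest common spatial patterns.

#' Fit a one-vs-rest CSP filter bank
#'
#' For each class the generalized eigenproblem of the class covariance
#' against the composite (class + rest) covariance is solved on trace
#' normalized per-window spatial covariances with a small ridge for rank
#' safety.  Rows are sorted by decreasing eigenvalue with a deterministic
#' sign convention (largest-magnitude entry positive); the top and bottom
#' `m` filters are retained.
#'
#' @param wb A `window_batch` of preprocessed windows.
#' @param m Retained filter pairs per class.
#' @param ridge Relative ridge added to the composite covariance.
#' @return A `spatial_filter_bank`: per-class `2m x channels` projection
#'   matrices, the full sorted filter matrices, eigenvalues, `m`, classes.
#' @export
csp_fit <- function(wb, m = 3, ridge = 1e-6) {
  stopifnot(inherits(wb, "window_batch"))
  nch <- dim(wb$windows)[3]
  if (2 * m > nch) stop("m too large for the channel count")
  covs <- window_covariances(wb)
  cls <- wb$classes
  cnt <- table(factor(wb$label_chr, levels = cls))
  if (any(cnt < 2)) stop("need at least 2 windows per class for CSP")
  class_cov <- lapply(cls, function(cl)
    cov_mean(covs[wb$label_chr == cl]))
  names(class_cov) <- cls
  bank <- lapply(cls, function(cl) {
    Sc <- class_cov[[cl]]
    Sr <- cov_mean(covs[wb$label_chr != cl])
    Scomp <- Sc + Sr
    Scomp <- Scomp + ridge * sum(diag(Scomp)) * diag(nch)
    eW <- eigen(Scomp, symmetric = TRUE)
    if (min(eW$values) <= 0) stop("composite covariance not positive definite")
    P <- eW$vectors %*% diag(1 / sqrt(eW$values)) %*% t(eW$vectors)
    Sw <- P %*% Sc %*% P
    ew <- eigen((Sw + t(Sw)) / 2, symmetric = TRUE)
    W <- t(ew$vectors) %*% P          # rows = filters, sorted desc eigenvalue
    for (r in seq_len(nrow(W))) {
      j <- which.max(abs(W[r, ]))
      if (W[r, j] < 0) W[r, ] <- -W[r, ]
    }
    sel <- c(seq_len(m), (nch - m + 1):nch)
    list(W_full = W, eigenvalues = ew$values, W = W[sel, , drop = FALSE])
  })
  names(bank) <- cls
  structure(list(bank = bank, m = as.integer(m), classes = cls,
                 channels = nch), class = "spatial_filter_bank")
}

window_covariances <- function(wb) {
  n <- dim(wb$windows)[1]
  lapply(seq_len(n), function(i) {
    X <- wb$windows[i, , ]
    X <- sweep(X, 2, colMeans(X))
    S <- crossprod(X)
    tr <- sum(diag(S))
    if (tr <= 0) diag(ncol(X)) / ncol(X) else S / tr
  })
}

cov_mean <- function(lst) Reduce(`+`, lst) / length(lst)

#' Log-variance CSP features
#'
#' Per window and per class bank: log variance of each retained filtered
#' signal, concatenated across the one-vs-rest banks (`4 * 2m` features for
#' four classes).
#'
#' @param wb A `window_batch`.
#' @param bank A `spatial_filter_bank` with matching channel count.
#' @param eps Variance floor applied before the logarithm.
#' @return Matrix `windows x features`.
#' @export
csp_features <- function(wb, bank, eps = 1e-12) {
  stopifnot(inherits(bank, "spatial_filter_bank"))
  if (dim(wb$windows)[3] != bank$channels)
    stop("channel count mismatch between windows and filter bank")
  n <- dim(wb$windows)[1]
  feats <- matrix(0, n, length(bank$classes) * 2 * bank$m)
  for (i in seq_len(n)) {
    X <- wb$windows[i, , ]
    X <- sweep(X, 2, colMeans(X))
    f <- unlist(lapply(bank$bank, function(b) {
      Y <- X %*% t(b$W)
      v <- colSums(Y^2) / (nrow(Y) - 1)
      log(pmax(v, eps))
    }))
    feats[i, ] <- f
  }
  colnames(feats) <- unlist(lapply(bank$classes, function(cl)
    paste0(cl, "_f", seq_len(2 * bank$m))))
  feats
}
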