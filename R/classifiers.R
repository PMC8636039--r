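# Classifier families mirroring the usual BCI toolbox set: nearest-neighbor
# variants, decision tree, linear and Gaussian-kernel SVMs, discriminant
# analysis, bagged trees and a random-subspace KNN ensemble.  Implemented
# self-contained (plus MASS for LDA) so the pipeline has no optional
# dependencies; hyperparameters are framework defaults recorded in reports.

#' Default classifier set
#'
#' @param names Optional subset of classifier names.
#' @return Named list of classifiers, each with `fit(X, y, seed)` and
#'   `predict(model, X)` functions.
#' @export
classifier_set <- function(names = NULL) {
  all <- list(
    knn_fine = knn_classifier(1),
    knn_medium = knn_classifier(10),
    tree = tree_classifier(),
    lda = lda_classifier(),
    svm_linear = svm_linear_classifier(),
    svm_rbf = svm_rbf_classifier(),
    bagged_trees = bagged_tree_classifier(),
    subspace_knn = subspace_knn_classifier())
  if (is.null(names)) all else all[names]
}

# ---- k nearest neighbors ---------------------------------------------------

knn_classifier <- function(k) {
  list(
    fit = function(X, y, seed = 1) list(X = X, y = y, k = min(k, nrow(X))),
    predict = function(m, X) {
      D <- cross_dist2(X, m$X)
      apply(D, 1, function(di) {
        nn <- order(di)[seq_len(m$k)]
        votes <- table(m$y[nn])
        top <- names(votes)[votes == max(votes)]
        if (length(top) == 1) top else m$y[nn[m$y[nn] %in% top][1]]
      })
    })
}

cross_dist2 <- function(A, B) {
  outer(rowSums(A^2), rep(1, nrow(B))) + outer(rep(1, nrow(A)), rowSums(B^2)) -
    2 * A %*% t(B)
}

# ---- CART decision tree ----------------------------------------------------

grow_tree <- function(X, y, depth, max_depth, min_node, nq = 8) {
  tab <- table(y)
  node <- list(pred = names(tab)[which.max(tab)])
  if (depth >= max_depth || nrow(X) < min_node || length(tab) == 1)
    return(node)
  n <- nrow(X)
  gini <- function(cnt) 1 - sum((cnt / max(sum(cnt), 1))^2)
  best <- list(score = gini(tab) - 1e-9)
  for (j in seq_len(ncol(X))) {
    qs <- unique(quantile(X[, j], probs = seq(1, nq) / (nq + 1), names = FALSE))
    for (thr in qs) {
      left <- X[, j] <= thr
      nl <- sum(left)
      if (nl == 0 || nl == n) next
      s <- (nl * gini(table(y[left])) + (n - nl) * gini(table(y[!left]))) / n
      if (s < best$score) best <- list(score = s, j = j, thr = thr)
    }
  }
  if (is.null(best$j)) return(node)
  left <- X[, best$j] <= best$thr
  node$j <- best$j; node$thr <- best$thr
  node$left <- grow_tree(X[left, , drop = FALSE], y[left], depth + 1,
                         max_depth, min_node, nq)
  node$right <- grow_tree(X[!left, , drop = FALSE], y[!left], depth + 1,
                          max_depth, min_node, nq)
  node
}

predict_tree <- function(node, x) {
  while (!is.null(node$j))
    node <- if (x[node$j] <= node$thr) node$left else node$right
  node$pred
}

tree_classifier <- function(max_depth = 8, min_node = 5) {
  list(
    fit = function(X, y, seed = 1)
      list(tree = grow_tree(X, y, 0, max_depth, min_node)),
    predict = function(m, X)
      apply(X, 1, function(x) predict_tree(m$tree, x)))
}

# ---- discriminant analysis -------------------------------------------------

lda_classifier <- function() {
  list(
    fit = function(X, y, seed = 1) {
      fit <- tryCatch(MASS::lda(X, grouping = factor(y)),
                      error = function(e) NULL)
      if (is.null(fit)) {
        Xj <- X + matrix(rnorm(length(X), sd = 1e-6 * max(sd(X), 1e-9)),
                         nrow(X))
        fit <- MASS::lda(Xj, grouping = factor(y))
      }
      list(fit = fit)
    },
    predict = function(m, X) as.character(predict(m$fit, X)$class))
}

# ---- linear SVM (one-vs-rest pegasos) -------------------------------------

pegasos_fit <- function(X, yy, lambda = 1e-3, epochs = 10) {
  n <- nrow(X); d <- ncol(X)
  w <- numeric(d); b <- 0
  t <- 0
  for (ep in seq_len(epochs)) {
    for (i in sample.int(n)) {
      t <- t + 1
      eta <- 1 / (lambda * t)
      marg <- yy[i] * (sum(w * X[i, ]) + b)
      w <- (1 - eta * lambda) * w
      if (marg < 1) {
        w <- w + eta * yy[i] * X[i, ]
        b <- b + eta * yy[i] * 0.1
      }
    }
  }
  list(w = w, b = b)
}

svm_linear_classifier <- function(lambda = 1e-3, epochs = 10) {
  list(
    fit = function(X, y, seed = 1) {
      mu <- colMeans(X); sg <- pmax(apply(X, 2, sd), 1e-9)
      Xs <- scale(X, mu, sg)
      cls <- sort(unique(y))
      withr_seed(seed, {
        ms <- lapply(cls, function(cl)
          pegasos_fit(Xs, ifelse(y == cl, 1, -1), lambda, epochs))
      })
      list(models = ms, classes = cls, mu = mu, sg = sg)
    },
    predict = function(m, X) {
      Xs <- scale(X, m$mu, m$sg)
      S <- vapply(m$models, function(mm) as.numeric(Xs %*% mm$w + mm$b),
                  numeric(nrow(Xs)))
      m$classes[max.col(matrix(S, nrow(Xs)))]
    })
}

# ---- Gaussian-kernel SVM (kernelized pegasos, one-vs-rest) -----------------

svm_rbf_classifier <- function(lambda = 1e-3, epochs = 5) {
  list(
    fit = function(X, y, seed = 1) {
      mu <- colMeans(X); sg <- pmax(apply(X, 2, sd), 1e-9)
      Xs <- scale(X, mu, sg)
      gamma <- 1 / (ncol(Xs) * max(mean(apply(Xs, 2, var)), 1e-9))
      K <- exp(-gamma * cross_dist2(Xs, Xs))
      cls <- sort(unique(y))
      n <- nrow(Xs)
      withr_seed(seed, {
        alphas <- lapply(cls, function(cl) {
          yy <- ifelse(y == cl, 1, -1)
          a <- numeric(n); t <- 0
          for (ep in seq_len(epochs)) for (i in sample.int(n)) {
            t <- t + 1
            f <- sum(a * yy * K[, i]) / (lambda * t)
            if (yy[i] * f < 1) a[i] <- a[i] + 1
          }
          a * yy / (lambda * t)
        })
      })
      list(alphas = alphas, classes = cls, X = Xs, gamma = gamma,
           mu = mu, sg = sg)
    },
    predict = function(m, X) {
      Xs <- scale(X, m$mu, m$sg)
      Kt <- exp(-m$gamma * cross_dist2(Xs, m$X))
      S <- vapply(m$alphas, function(a) as.numeric(Kt %*% a),
                  numeric(nrow(Xs)))
      m$classes[max.col(matrix(S, nrow(Xs)))]
    })
}

# ---- ensembles -------------------------------------------------------------

bagged_tree_classifier <- function(n_trees = 20, max_depth = 8) {
  list(
    fit = function(X, y, seed = 1) {
      withr_seed(seed, {
        trees <- lapply(seq_len(n_trees), function(i) {
          idx <- sample.int(nrow(X), replace = TRUE)
          grow_tree(X[idx, , drop = FALSE], y[idx], 0, max_depth, 5)
        })
      })
      list(trees = trees)
    },
    predict = function(m, X) {
      votes <- vapply(m$trees, function(tr)
        apply(X, 1, function(x) predict_tree(tr, x)), character(nrow(X)))
      apply(matrix(votes, nrow(X)), 1, function(v) {
        tb <- table(v); names(tb)[which.max(tb)]
      })
    })
}

subspace_knn_classifier <- function(n_learners = 15, k = 1) {
  list(
    fit = function(X, y, seed = 1) {
      d <- ncol(X)
      dsub <- max(2, floor(d / 2))
      withr_seed(seed, {
        subs <- lapply(seq_len(n_learners), function(i) sample.int(d, dsub))
      })
      list(X = X, y = y, subs = subs, k = k)
    },
    predict = function(m, X) {
      votes <- vapply(m$subs, function(sb) {
        D <- cross_dist2(X[, sb, drop = FALSE], m$X[, sb, drop = FALSE])
        apply(D, 1, function(di) m$y[order(di)[seq_len(m$k)]][1])
      }, character(nrow(X)))
      apply(matrix(votes, nrow(X)), 1, function(v) {
        tb <- table(v); names(tb)[which.max(tb)]
      })
    })
}
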