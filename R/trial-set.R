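#' Labelled multichannel EEG trials
#'
#' The central data container: an array of trials by samples by channels with
#' class labels, session ids and sampling rate.
#'
#' @param data Numeric array `trials x samples x channels` (microvolts).
#' @param labels Character/factor vector, one class label per trial.
#' @param fs Sampling rate (Hz).
#' @param session Integer vector of session ids (recycled if length 1).
#' @param subject Subject identifier.
#' @param channels Character vector of channel names (defaults to `Ch1..ChK`).
#' @return An object of class `trial_set`.
#' @export
trial_set <- function(data, labels, fs, session = 1L, subject = "S1",
                      channels = NULL) {
  stopifnot(length(dim(data)) == 3, fs > 0)
  n <- dim(data)[1]
  if (length(labels) != n)
    stop("label count (", length(labels), ") != trial count (", n, ")")
  if (length(session) == 1) session <- rep(as.integer(session), n)
  stopifnot(length(session) == n)
  if (is.null(channels)) channels <- paste0("Ch", seq_len(dim(data)[3]))
  stopifnot(length(channels) == dim(data)[3])
  structure(list(data = data, labels = as.character(labels), fs = fs,
                 session = as.integer(session), subject = subject,
                 channels = channels),
            class = "trial_set")
}

#' @export
print.trial_set <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<trial_set> subject %s: %d trials x %d samples x %d channels @ %g Hz\n",
              x$subject, d[1], d[2], d[3], x$fs))
  cat("  classes:", paste(sprintf("%s(%d)", names(table(x$labels)),
                                  table(x$labels)), collapse = " "), "\n")
  cat("  sessions:", paste(sort(unique(x$session)), collapse = " "), "\n")
  invisible(x)
}

#' Concatenate trial sets along the trial dimension
#' @param ... `trial_set` objects sharing fs and channel layout.
#' @return A combined [trial_set()].
#' @export
bind_trials <- function(...) {
  xs <- list(...)
  stopifnot(length(xs) >= 1, all(vapply(xs, inherits, TRUE, "trial_set")))
  fs <- unique(vapply(xs, `[[`, 1.0, "fs"))
  nch <- unique(vapply(xs, function(x) dim(x$data)[3], 1L))
  nsmp <- unique(vapply(xs, function(x) dim(x$data)[2], 1L))
  stopifnot(length(fs) == 1, length(nch) == 1, length(nsmp) == 1)
  dat <- do.call(abind3, lapply(xs, `[[`, "data"))
  trial_set(dat, unlist(lapply(xs, `[[`, "labels")), fs,
            unlist(lapply(xs, `[[`, "session")), xs[[1]]$subject,
            xs[[1]]$channels)
}

# rbind for 3-d arrays along dim 1
abind3 <- function(...) {
  xs <- list(...)
  d <- dim(xs[[1]])
  out <- array(0, c(sum(vapply(xs, function(x) dim(x)[1], 1L)), d[2], d[3]))
  at <- 1L
  for (x in xs) {
    k <- dim(x)[1]
    if (k > 0) out[at:(at + k - 1L), , ] <- x
    at <- at + k
  }
  out
}

#' Subset a trial set by trial index
#' @param ts A [trial_set()].
#' @param idx Integer or logical trial index.
#' @return A [trial_set()] with the selected trials.
#' @export
subset_trials <- function(ts, idx) {
  trial_set(ts$data[idx, , , drop = FALSE], ts$labels[idx], ts$fs,
            ts$session[idx], ts$subject, ts$channels)
}
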