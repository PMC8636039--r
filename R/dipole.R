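#' Equivalent current dipole
#'
#' @param position 3-vector (m, head-centered coordinates), strictly inside
#'   the brain shell.
#' @param moment 3-vector dipole moment (A m), nonzero.
#' @param region Label in `frontal`, `left_motor`, `right_motor` (or `custom`).
#' @return An object of class `dipole`.
#' @export
dipole <- function(position, moment, region = "custom") {
  stopifnot(length(position) == 3, length(moment) == 3,
            all(is.finite(position)), all(is.finite(moment)))
  if (sqrt(sum(moment^2)) <= 0) stop("dipole moment must be nonzero")
  structure(list(position = as.numeric(position), moment = as.numeric(moment),
                 region = region), class = "dipole")
}

#' Canonical class dipoles
#'
#' Template dipole for each microexpression class: frontal lobe for raise- and
#' furrow-brow, right motor cortex for left-smirk, left motor cortex for
#' right-smirk (contralateral control); orientation radial (orthogonal to the
#' local surface).
#'
#' @param class_label One of `mRB`, `mFB`, `mLS`, `mRS`.
#' @param model A [shell_model()] (for the center offset).
#' @param magnitude Dipole moment magnitude (A m).
#' @return A [dipole()].
#' @export
place_dipole <- function(class_label, model = shell_model(),
                         magnitude = 1e-8) {
  pos <- switch(class_label,
                mRB = c(0, 0.06, 0.05),
                mFB = c(0, 0.06, 0.05),
                mLS = c(0.04, 0.01, 0.06),   # right motor cortex
                mRS = c(-0.04, 0.01, 0.06),  # left motor cortex
                stop("unknown class label '", class_label, "'"))
  region <- switch(class_label, mRB = , mFB = "frontal",
                   mLS = "right_motor", mRS = "left_motor")
  u <- pos / sqrt(sum(pos^2))
  dipole(pos + model$center, u * magnitude, region)
}

#' Far-field dipole potential in an unbounded homogeneous medium
#'
#' `U = |d| cos(theta) / (4 pi kappa r^2)` with `theta` the angle between the
#' moment and the observation direction; the scale factor is fixed to
#' `1/(4 pi kappa)` (quasi-static conducting medium).
#'
#' @param d A [dipole()].
#' @param x Observation point (3-vector or n x 3 matrix), distinct from the
#'   dipole position.
#' @param kappa Conductivity (S/m).
#' @return Potential(s) in volts.
#' @export
dipole_potential_free_medium <- function(d, x, kappa = 0.33) {
  stopifnot(inherits(d, "dipole"), kappa > 0)
  x <- matrix(x, ncol = 3)
  rel <- sweep(x, 2, d$position)
  r <- sqrt(rowSums(rel^2))
  if (any(r < 1e-12)) stop("observation point coincides with the dipole (singular)")
  md <- sqrt(sum(d$moment^2))
  cth <- (rel %*% d$moment) / (r * md)
  as.numeric(md * cth / (4 * pi * kappa * r^2))
}
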