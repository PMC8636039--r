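# Collocation boundary element method for the isotropic three-shell forward
# problem.  Constant (centroid) collocation with van Oosterom & Strackee
# solid angles, deflation of the singular interior-Neumann mode, and
# electrode interpolation from the nearest scalp elements.

mesh_centroids <- function(surface) {
  V <- surface$vertices; F <- surface$faces
  (V[F[, 1], ] + V[F[, 2], ] + V[F[, 3], ]) / 3
}

# Assemble the (deflated) BEM system matrix for a tri_surface_set.
# Returns list(A = LU-able matrix, centroids, surf_index, coef) where
# v = g + B v  =>  (I - B) v = g, and A = I - B + deflation.
bem_system <- function(mesh) {
  validate_mesh(mesh)
  ns <- length(mesh$surfaces)
  cent <- lapply(mesh$surfaces, mesh_centroids)
  ntri <- vapply(cent, nrow, 1L)
  idx_end <- cumsum(ntri)
  idx_start <- idx_end - ntri + 1L
  N <- sum(ntri)
  obs <- do.call(rbind, cent)
  B <- matrix(0, N, N)
  for (l in seq_len(ns)) {
    s <- mesh$surfaces[[l]]
    W <- solid_angles_cpp(obs, s$vertices, matrix(as.integer(s$faces), ncol = 3))
    dsig <- mesh$sigma_in[l] - mesh$sigma_out[l]
    B[, idx_start[l]:idx_end[l]] <- W * dsig
  }
  denom <- rep(mesh$sigma_in + mesh$sigma_out, ntri)
  B <- B / (2 * pi) / denom   # rows scaled by the observation surface's sigma sum
  # Zero the self-element contribution (planar triangle subtends zero angle
  # at its own centroid; numerically exact but enforce it).
  diag(B) <- 0
  A <- diag(N) - B + matrix(1 / N, N, N)  # deflation of the constant mode
  list(A = A, centroids = obs, ntri = ntri, idx_start = idx_start,
       idx_end = idx_end, denom = denom)
}

# Solve surface potentials for one or more dipoles (unit moments along the
# coordinate axes give the lead field columns).
bem_solve <- function(sys, mesh, dipoles_pos, dipoles_mom, sigma_src) {
  nq <- nrow(dipoles_pos)
  G <- matrix(0, nrow(sys$centroids), nq)
  for (q in seq_len(nq)) {
    dd <- dipole(dipoles_pos[q, ], dipoles_mom[q, ])
    vinf <- dipole_potential_exact(dd, sys$centroids, sigma_src)
    G[, q] <- 2 * sigma_src * vinf / sys$denom
  }
  solve(sys$A, G)
}

# Exact (near-field) dipole potential in an unbounded homogeneous medium:
# U = d . (x - x0) / (4 pi sigma |x - x0|^3).  The far-field cos(theta)/r^2
# form of dipole_potential_free_medium() is identical for a point dipole.
dipole_potential_exact <- function(d, x, sigma) {
  rel <- sweep(matrix(x, ncol = 3), 2, d$position)
  r3 <- (rowSums(rel^2))^1.5
  as.numeric((rel %*% d$moment) / (4 * pi * sigma * r3))
}

#' Boundary element method lead field
#'
#' Computes the electrodes-by-moment-components gain matrix for a set of
#' dipoles inside a nested three-surface mesh with isotropic per-compartment
#' conductivities.  The interior Neumann singularity is removed by deflation;
#' electrode potentials are interpolated by inverse-distance weighting of the
#' three nearest scalp elements; the output is re-referenced (CPz by default).
#'
#' @param mesh A `tri_surface_set` (see [three_shell_mesh()]).
#' @param montage An `electrode_montage`.
#' @param dipoles List of [dipole()] objects inside the brain surface.
#' @param reference `"CPz"`-style channel label or `"average"`.
#' @return A `lead_field` object: matrix `n_electrodes x (3 n_dipoles)`
#'   (V per A m) with provenance attributes (`method`, `reference`,
#'   `montage_hash`).
#' @export
bem_leadfield <- function(mesh, montage, dipoles, reference = "CPz") {
  stopifnot(inherits(mesh, "tri_surface_set"), length(dipoles) >= 1)
  sys <- bem_system(mesh)
  scalp <- mesh$surfaces$scalp
  scalp_cent <- mesh_centroids(scalp)
  off <- sys$idx_start[length(sys$idx_start)]
  pos <- do.call(rbind, lapply(dipoles, `[[`, "position"))
  nq <- length(dipoles)
  P <- matrix(0, nrow = 3 * nq, ncol = 3)
  for (q in seq_len(nq)) P[(3 * q - 2):(3 * q), ] <- diag(3)
  pos3 <- pos[rep(seq_len(nq), each = 3), , drop = FALSE]
  V <- bem_solve(sys, mesh, pos3, P, mesh$sigma_in[1])
  Vs <- V[off:nrow(V), , drop = FALSE]        # scalp block
  LF <- electrode_interp(montage$positions, scalp_cent) %*% Vs
  LF <- apply_reference(LF, montage, reference)
  structure(LF, class = c("lead_field", "matrix"), method = "bem",
            reference = reference, montage_hash = montage_hash(montage),
            electrodes = montage$labels)
}

# inverse-distance interpolation matrix electrodes x scalp-elements (k = 3)
electrode_interp <- function(epos, cent, k = 3) {
  n <- nrow(epos)
  M <- matrix(0, n, nrow(cent))
  for (i in seq_len(n)) {
    d2 <- rowSums(sweep(cent, 2, epos[i, ])^2)
    nn <- order(d2)[seq_len(k)]
    w <- 1 / pmax(sqrt(d2[nn]), 1e-9)
    M[i, nn] <- w / sum(w)
  }
  M
}

apply_reference <- function(LF, montage, reference) {
  if (identical(reference, "average")) {
    sweep(LF, 2, colMeans(LF))
  } else {
    ref <- match(reference, montage$labels)
    if (is.na(ref)) stop("reference channel '", reference, "' not in montage")
    sweep(LF, 2, LF[ref, ])
  }
}

montage_hash <- function(montage) {
  x <- paste(c(montage$labels, sprintf("%.6f", montage$positions)),
             collapse = ",")
  # small deterministic string hash (djb2)
  h <- 5381
  for (ch in utf8ToInt(x)) h <- (h * 33 + ch) %% 2^31
  sprintf("%08x", h)
}

#' Analytic three-sphere lead field
#'
#' Same contract as [bem_leadfield()] but using the concentric-sphere series
#' solution; exact for the spherical template geometry and much faster, hence
#' the default engine of the synthetic recording generator.
#'
#' @inheritParams bem_leadfield
#' @param model The [shell_model()] describing the spheres.
#' @export
analytic_leadfield <- function(model, montage, dipoles, reference = "CPz",
                               n_terms = 100) {
  nq <- length(dipoles)
  LF <- matrix(0, length(montage$labels), 3 * nq)
  for (q in seq_len(nq)) {
    for (ax in 1:3) {
      mom <- c(0, 0, 0); mom[ax] <- 1
      dd <- dipole(dipoles[[q]]$position, mom)
      LF[, 3 * (q - 1) + ax] <-
        analytic_three_sphere_potential(dd, montage$positions, model,
                                        n_terms = n_terms)
    }
  }
  LF <- apply_reference(LF, montage, reference)
  structure(LF, class = c("lead_field", "matrix"), method = "analytic",
            reference = reference, montage_hash = montage_hash(montage),
            electrodes = montage$labels)
}

#' Gain vector of a lead field for one dipole moment
#' @param lf A `lead_field`.
#' @param d A [dipole()] (its moment is applied).
#' @param which_dipole Index of the dipole block in the lead field.
#' @return Per-electrode gain (V).
#' @export
leadfield_gain <- function(lf, d, which_dipole = 1) {
  block <- lf[, (3 * which_dipole - 2):(3 * which_dipole), drop = FALSE]
  as.numeric(block %*% d$moment)
}

#' Project a source time series to the scalp montage
#'
#' Multichannel scalp EEG as the outer product of the lead-field gains with
#' the mixed source potential, optionally rescaled so the median per-channel
#' RMS matches a template value.  Under the CPz reference the CPz channel is
#' identically zero before noise is added.
#'
#' @param source Numeric source series (mV).
#' @param lf A `lead_field` whose montage hash matches `montage`.
#' @param d The [dipole()] carrying the moment to apply.
#' @param montage The `electrode_montage` used to build `lf`.
#' @param which_dipole Dipole block index in `lf`.
#' @param template_rms Target median per-channel RMS (same units as the
#'   output); `NULL` leaves the physical scale (V per A m times mV).
#' @return Matrix `samples x channels`.
#' @export
project_to_scalp <- function(source, lf, d, montage, which_dipole = 1,
                             template_rms = NULL) {
  if (!identical(attr(lf, "montage_hash"), montage_hash(montage)))
    stop("lead field provenance does not match the montage")
  g <- leadfield_gain(lf, d, which_dipole)
  eeg <- outer(as.numeric(source), g)
  if (!is.null(template_rms)) {
    rms <- sqrt(colMeans(eeg^2))
    med <- stats::median(rms[rms > 0])
    if (is.finite(med) && med > 0) eeg <- eeg * (template_rms / med)
  }
  colnames(eeg) <- montage$labels
  eeg
}
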