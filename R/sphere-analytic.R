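# Analytic Legendre-series forward solution for a dipole inside concentric
# isotropic spherical shells.  Serves as the oracle for the BEM solver.

# Legendre P_n(x) and associated P_n^1(x) for n = 1..N at scalar x.
legendre_table <- function(N, x) {
  P <- numeric(N + 1)          # P[n+1] = P_n
  P[1] <- 1; if (N >= 1) P[2] <- x
  for (n in 2:N) P[n + 1] <- ((2 * n - 1) * x * P[n] - (n - 1) * P[n - 1]) / n
  s <- sqrt(max(0, 1 - x^2))
  P1 <- numeric(N + 1)         # P1[n+1] = P_n^1 (positive convention)
  if (N >= 1) P1[2] <- s
  if (N >= 2) P1[3] <- 3 * x * s
  if (N >= 3) for (n in 3:N)
    P1[n + 1] <- ((2 * n - 1) * x * P1[n] - n * P1[n - 1]) / (n - 1)
  list(P = P[-1], P1 = P1[-1])
}

# Per-degree radial factors at the outer surface for unit source coefficient.
# Layers: 1 brain, 2 skull, 3 scalp; radii scaled so the scalp radius is 1.
# Unknowns per degree: A1, A2, B2, A3, B3; the dipole's own field contributes
# r^-(n+1) with unit coefficient in layer 1.
sphere_surface_factors <- function(model, N) {
  r <- model$radii / model$radii[3]
  s <- model$conductivities
  out <- numeric(N)
  for (n in seq_len(N)) {
    M <- matrix(0, 5, 5)
    rhs <- numeric(5)
    # columns: A1, A2, B2, A3, B3
    r1 <- r[1]; r2 <- r[2]
    # continuity of U at r1:  A1 r1^n + r1^-(n+1) = A2 r1^n + B2 r1^-(n+1)
    M[1, ] <- c(r1^n, -r1^n, -r1^(-(n + 1)), 0, 0)
    rhs[1] <- -r1^(-(n + 1))
    # continuity of sigma dU/dr at r1
    M[2, ] <- c(s[1] * n * r1^(n - 1), -s[2] * n * r1^(n - 1),
                s[2] * (n + 1) * r1^(-(n + 2)), 0, 0)
    rhs[2] <- s[1] * (n + 1) * r1^(-(n + 2))
    # continuity of U at r2
    M[3, ] <- c(0, r2^n, r2^(-(n + 1)), -r2^n, -r2^(-(n + 1)))
    # continuity of sigma dU/dr at r2
    M[4, ] <- c(0, s[2] * n * r2^(n - 1), -s[2] * (n + 1) * r2^(-(n + 2)),
                -s[3] * n * r2^(n - 1), s[3] * (n + 1) * r2^(-(n + 2)))
    # insulating outer boundary at r = 1
    M[5, ] <- c(0, 0, 0, n, -(n + 1))
    # equilibrate: powers of the radii make the raw system ill-conditioned
    rs <- 1 / pmax(apply(abs(M), 1, max), 1e-300)
    M <- M * rs; rhs <- rhs * rs
    cs <- 1 / pmax(apply(abs(M), 2, max), 1e-300)
    sol <- solve(M %*% diag(cs), rhs) * cs
    out[n] <- sol[4] + sol[5]   # A3 + B3 at r = 1
  }
  out
}

#' Analytic concentric three-sphere scalp potential
#'
#' Legendre-series solution for a dipole inside the innermost shell of a
#' three-layer isotropic sphere with an insulating exterior, evaluated at
#' electrode positions on (or near) the scalp surface.
#'
#' @param d A [dipole()].
#' @param electrodes n x 3 matrix of electrode positions (m) or a 3-vector.
#' @param model A [shell_model()].
#' @param n_terms Maximum series degree.
#' @param tol Relative truncation tolerance for early stopping.
#' @return Numeric vector of potentials (V), one per electrode.
#' @export
analytic_three_sphere_potential <- function(d, electrodes,
                                            model = shell_model(),
                                            n_terms = 100, tol = 1e-9) {
  stopifnot(inherits(d, "dipole"), n_terms >= 1)
  E <- matrix(electrodes, ncol = 3)
  E <- sweep(E, 2, model$center)
  pos <- d$position - model$center
  R3 <- model$radii[3]
  b <- sqrt(sum(pos^2))
  if (b / model$radii[1] >= 0.95)
    stop("dipole eccentricity ", round(b / model$radii[1], 3),
         " >= 0.95: series does not converge reliably")
  f <- b / R3
  zhat <- if (b > 1e-12 * R3) pos / b else c(0, 0, 1)
  m_r <- sum(d$moment * zhat)
  mt_vec <- d$moment - m_r * zhat
  mt <- sqrt(sum(mt_vec^2))
  xhat <- if (mt > 1e-15) mt_vec / mt else orth_any(zhat)
  fac <- sphere_surface_factors(model, n_terms)
  sig1 <- model$conductivities[1]
  scale <- 1 / (4 * pi * sig1 * R3^2)
  U <- numeric(nrow(E))
  for (i in seq_len(nrow(E))) {
    e <- E[i, ]
    eu <- e / sqrt(sum(e^2))
    x <- max(-1, min(1, sum(eu * zhat)))
    ep <- eu - x * zhat
    nep <- sqrt(sum(ep^2))
    cphi <- if (nep > 1e-12) sum(ep * xhat) / nep else 0
    lt <- legendre_table(n_terms, x)
    acc <- 0
    for (n in seq_len(n_terms)) {
      term <- fac[n] * f^(n - 1) *
        (n * m_r * lt$P[n] + mt * lt$P1[n] * cphi)
      acc <- acc + term
      if (n > 10 && abs(term) < tol * max(abs(acc), 1e-300)) break
    }
    U[i] <- scale * acc
  }
  U
}

orth_any <- function(z) {
  v <- if (abs(z[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  v <- v - sum(v * z) * z
  v / sqrt(sum(v^2))
}

#' Homogeneous insulated-sphere scalp potential (closed series form)
#'
#' Single-compartment limit used as an independent check of the multilayer
#' machinery: surface potential
#' `U = (1/(4 pi sigma R^2)) sum_n ((2n+1)/n) f^(n-1) (n m_r P_n + m_t P_n^1 cos phi)`.
#'
#' @inheritParams analytic_three_sphere_potential
#' @param radius Sphere radius (m).
#' @param sigma Conductivity (S/m).
#' @export
homogeneous_sphere_potential <- function(d, electrodes, radius = 0.1,
                                         sigma = 0.33, n_terms = 100) {
  model <- shell_model(radii = radius * c(0.5, 0.75, 1),
                       conductivities = rep(sigma, 3))
  E <- matrix(electrodes, ncol = 3)
  pos <- d$position
  b <- sqrt(sum(pos^2))
  f <- b / radius
  zhat <- if (b > 1e-12) pos / b else c(0, 0, 1)
  m_r <- sum(d$moment * zhat)
  mt_vec <- d$moment - m_r * zhat
  mt <- sqrt(sum(mt_vec^2))
  xhat <- if (mt > 1e-15) mt_vec / mt else orth_any(zhat)
  U <- numeric(nrow(E))
  for (i in seq_len(nrow(E))) {
    eu <- E[i, ] / sqrt(sum(E[i, ]^2))
    x <- max(-1, min(1, sum(eu * zhat)))
    ep <- eu - x * zhat
    nep <- sqrt(sum(ep^2))
    cphi <- if (nep > 1e-12) sum(ep * xhat) / nep else 0
    lt <- legendre_table(n_terms, x)
    n <- seq_len(n_terms)
    U[i] <- sum((2 * n + 1) / n * f^(n - 1) *
                  (n * m_r * lt$P + mt * lt$P1 * cphi)) /
      (4 * pi * sigma * radius^2)
  }
  U
}
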