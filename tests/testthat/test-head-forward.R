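test_that("free-medium dipole potential follows cos(theta)/r^2", {
  d <- dipole(c(0, 0, 0), c(0, 0, 1e-8))
  # equatorial plane is equipotential zero
  expect_equal(dipole_potential_free_medium(d, c(0.05, 0, 0)), 0,
               tolerance = 1e-20)
  # inverse-square distance
  u1 <- dipole_potential_free_medium(d, c(0, 0, 0.05))
  u2 <- dipole_potential_free_medium(d, c(0, 0, 0.10))
  expect_equal(u1 / u2, 4, tolerance = 1e-10)
  # direct evaluation: |d| = 1e-8, kappa = 0.33, r = 0.05, theta = 0
  expect_equal(u1, 1e-8 / (4 * pi * 0.33 * 0.05^2), tolerance = 1e-12)
  expect_equal(u1, 9.65e-7, tolerance = 1e-3)
  expect_error(dipole_potential_free_medium(d, c(0, 0, 0)), "singular")
})

test_that("analytic series matches the homogeneous closed form and converges", {
  m_eq <- shell_model(conductivities = c(0.33, 0.33, 0.33))
  mon <- standard_montage(m_eq)
  d <- dipole(c(0.02, 0.01, 0.03), c(1e-8, 2e-8, -0.5e-8))
  u1 <- analytic_three_sphere_potential(d, mon$positions, m_eq, n_terms = 120)
  u2 <- homogeneous_sphere_potential(d, mon$positions, radius = 0.1,
                                     sigma = 0.33, n_terms = 120)
  expect_lt(max(abs(u1 - u2)) / max(abs(u2)), 1e-6)
  # truncation convergence at eccentricity 0.7
  m3 <- shell_model()
  d7 <- dipole(c(0, 0, 0.7 * m3$radii[1]), c(1e-8, 0, 1e-8))
  u60 <- analytic_three_sphere_potential(d7, mon$positions, m3, n_terms = 60,
                                         tol = 0)
  u100 <- analytic_three_sphere_potential(d7, mon$positions, m3, n_terms = 100,
                                          tol = 0)
  expect_lt(max(abs(u60 - u100)) / max(abs(u100)), 1e-6)
  # central dipole: potential proportional to cos(theta) about the moment axis
  dc <- dipole(c(0, 0, 1e-6), c(0, 0, 1e-8))
  uc <- analytic_three_sphere_potential(dc, mon$positions, m3)
  cth <- mon$positions[, 3] / sqrt(rowSums(mon$positions^2))
  expect_gt(abs(cor(uc, cth)), 0.999999)
  # eccentricity guard
  dh <- dipole(c(0, 0, 0.96 * m3$radii[1]), c(0, 0, 1e-8))
  expect_error(analytic_three_sphere_potential(dh, mon$positions, m3),
               "eccentricity")
})

test_that("superposition holds for the analytic forward solution", {
  m3 <- shell_model()
  mon <- standard_montage(m3)
  d1 <- dipole(c(0.02, 0, 0.03), c(1e-8, 0, 0))
  d2 <- dipole(c(-0.01, 0.02, 0.02), c(0, 1e-8, 1e-8))
  dsum <- dipole(d1$position, d1$moment)  # same site, summed moments
  u1 <- analytic_three_sphere_potential(d1, mon$positions, m3)
  u2 <- analytic_three_sphere_potential(d2, mon$positions, m3)
  u12 <- analytic_three_sphere_potential(
    dipole(d1$position, d1$moment * 2), mon$positions, m3)
  expect_equal(u12, 2 * u1, tolerance = 1e-10)      # linearity in the moment
  lf <- analytic_leadfield(m3, mon, list(d1, d2), reference = "average")
  expect_equal(as.numeric(lf[, 1:3] %*% d1$moment + lf[, 4:6] %*% d2$moment),
               (u1 - mean(u1)) + (u2 - mean(u2)), tolerance = 1e-6)
})

test_that("class dipoles land in the documented regions", {
  expect_equal(place_dipole("mRS")$region, "left_motor")
  expect_lt(place_dipole("mRS")$position[1], 0)
  expect_equal(place_dipole("mLS")$region, "right_motor")
  expect_gt(place_dipole("mLS")$position[1], 0)
  expect_equal(place_dipole("mRB")$region, "frontal")
  expect_equal(place_dipole("mFB")$region, "frontal")
  # radial orientation
  d <- place_dipole("mRB")
  u <- d$position / sqrt(sum(d$position^2))
  expect_equal(abs(sum(u * d$moment)) / sqrt(sum(d$moment^2)), 1,
               tolerance = 1e-9)
  expect_error(place_dipole("mXX"), "unknown class")
})

test_that("scalp projection is linear, zero for zero source, CPz-referenced", {
  m3 <- shell_model()
  mon <- standard_montage(m3)
  d <- place_dipole("mRS", m3)
  lf <- analytic_leadfield(m3, mon, list(d))
  z <- project_to_scalp(numeric(50), lf, d, mon)
  expect_true(all(z == 0))
  src <- sin(seq_len(200) / 10)
  e1 <- project_to_scalp(src, lf, d, mon)
  e2 <- project_to_scalp(3 * src, lf, d, mon)
  expect_equal(e2, 3 * e1, tolerance = 1e-12)
  expect_true(all(abs(e1[, "CPz"]) < 1e-18))
  # rescaling hits the requested median channel RMS
  es <- project_to_scalp(src, lf, d, mon, template_rms = 12)
  expect_equal(median(sqrt(colMeans(es^2))[colMeans(es^2) > 0]), 12,
               tolerance = 1e-9)
  badm <- mon; badm$labels[1] <- "XX"
  expect_error(project_to_scalp(src, lf, d, badm), "provenance")
})

test_that("mesh validation rejects open and flipped surfaces, passes good ones", {
  mesh <- three_shell_mesh(subdiv = 1)
  expect_true(validate_mesh(mesh))
  open_mesh <- mesh
  open_mesh$surfaces$brain$faces <- open_mesh$surfaces$brain$faces[-1, ]
  expect_error(validate_mesh(open_mesh), "not closed")
  flipped <- mesh
  flipped$surfaces$skull$faces <- flipped$surfaces$skull$faces[, c(1, 3, 2)]
  expect_error(validate_mesh(flipped), "oriented")
})

test_that("BEM lead field: linearity, reference conventions, oracle proximity", {
  m3 <- shell_model()
  mesh <- three_shell_mesh(m3, subdiv = 2)
  mon <- standard_montage(m3)
  d <- dipole(c(0.02, 0.01, 0.03), c(1e-8, 0, 0.5e-8))
  lf <- bem_leadfield(mesh, mon, list(d), reference = "average")
  expect_true(all(is.finite(lf)))
  # linear in the moment
  g1 <- leadfield_gain(lf, d)
  g2 <- leadfield_gain(lf, dipole(d$position, 2 * d$moment))
  expect_equal(g2, 2 * g1, tolerance = 1e-12)
  # average reference sums to zero
  expect_lt(abs(sum(g1)), 1e-8 * max(abs(g1)))
  # CPz reference zeroes the reference channel
  lfc <- bem_leadfield(mesh, mon, list(d), reference = "CPz")
  expect_equal(unname(leadfield_gain(lfc, d)[mon$labels == "CPz"]), 0)
  # coarse-mesh oracle comparison (the strict version runs in acceptance)
  ua <- analytic_three_sphere_potential(d, mon$positions, m3, n_terms = 120)
  ua <- ua - mean(ua)
  expect_lt(sqrt(sum((g1 - ua)^2) / sum(ua^2)), 0.15)
})

test_that("skull conductivity controls spatial smearing monotonically", {
  mon <- standard_montage()
  d <- dipole(c(0, 0.03, 0.04), c(0, 0.6e-8, 0.8e-8))
  spread <- vapply(c(0.0042, 0.33), function(sk) {
    m <- shell_model(conductivities = c(0.33, sk, 0.33))
    u <- analytic_three_sphere_potential(d, mon$positions, m)
    u <- abs(u - mean(u))
    # participation ratio: high = power spread over many electrodes
    sum(u^2)^2 / sum(u^4)
  }, 1.0)
  expect_gt(spread[1], spread[2])  # low skull conductivity smears more
})

test_that("montage and mesh files round-trip", {
  mon <- standard_montage()
  f <- tempfile(fileext = ".sfp")
  write_sfp(mon, f)
  mon2 <- read_sfp(f)
  expect_equal(mon2$labels, mon$labels)
  expect_equal(unname(mon2$positions), unname(mon$positions), tolerance = 1e-6)
  ic <- icosphere(1)
  fo <- tempfile(fileext = ".obj")
  write_obj(list(vertices = ic$vertices, faces = ic$faces), fo)
  s2 <- read_obj(fo)
  expect_equal(unname(s2$vertices), unname(ic$vertices), tolerance = 1e-7)
  expect_equal(unname(s2$faces), unname(ic$faces))
})
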