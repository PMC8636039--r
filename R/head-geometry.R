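#' Three-shell spherical head model
#'
#' Concentric brain/skull/scalp compartments with isotropic conductivities.
#' Defaults follow the classic 1 : 1/80 : 1 ratio (brain 0.33, skull 0.0042,
#' scalp 0.33 S/m) and radii 0.087/0.092/0.100 m.
#'
#' @param radii Strictly increasing brain < skull < scalp radii (m).
#' @param conductivities Positive conductivities (S/m), same order.
#' @param center Sphere center (m).
#' @return An object of class `shell_model`.
#' @export
shell_model <- function(radii = c(0.087, 0.092, 0.100),
                        conductivities = c(0.33, 0.0042, 0.33),
                        center = c(0, 0, 0)) {
  stopifnot(length(radii) == 3, all(diff(radii) > 0),
            length(conductivities) == 3, all(conductivities > 0),
            length(center) == 3)
  structure(list(radii = radii, conductivities = conductivities,
                 center = center), class = "shell_model")
}

# Subdivided icosahedron on the unit sphere; level 3 gives 1280 triangles.
icosphere <- function(subdiv = 3) {
  t <- (1 + sqrt(5)) / 2
  V <- rbind(c(-1, t, 0), c(1, t, 0), c(-1, -t, 0), c(1, -t, 0),
             c(0, -1, t), c(0, 1, t), c(0, -1, -t), c(0, 1, -t),
             c(t, 0, -1), c(t, 0, 1), c(-t, 0, -1), c(-t, 0, 1))
  V <- V / sqrt(rowSums(V^2))
  F <- rbind(c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11), c(1, 11, 12),
             c(2, 6, 10), c(6, 12, 5), c(12, 11, 3), c(11, 8, 7), c(8, 2, 9),
             c(4, 10, 5), c(4, 5, 3), c(4, 3, 7), c(4, 7, 9), c(4, 9, 10),
             c(5, 10, 6), c(3, 5, 12), c(7, 3, 11), c(9, 7, 8), c(10, 9, 2))
  for (lev in seq_len(subdiv)) {
    edge_mid <- new.env()
    midpoint <- function(i, j) {
      key <- paste(min(i, j), max(i, j))
      got <- edge_mid[[key]]
      if (!is.null(got)) return(got)
      m <- V[i, ] + V[j, ]
      m <- m / sqrt(sum(m^2))
      V <<- rbind(V, m)
      idx <- nrow(V)
      edge_mid[[key]] <- idx
      idx
    }
    Fn <- matrix(0L, 0, 3)
    for (f in seq_len(nrow(F))) {
      a <- F[f, 1]; b <- F[f, 2]; c <- F[f, 3]
      ab <- midpoint(a, b); bc <- midpoint(b, c); ca <- midpoint(c, a)
      Fn <- rbind(Fn, c(a, ab, ca), c(b, bc, ab), c(c, ca, bc), c(ab, bc, ca))
    }
    F <- Fn
  }
  # orient all triangles outward (counter-clockwise from outside)
  for (f in seq_len(nrow(F))) {
    v1 <- V[F[f, 1], ]; v2 <- V[F[f, 2], ]; v3 <- V[F[f, 3], ]
    n <- cross3(v2 - v1, v3 - v1)
    if (sum(n * (v1 + v2 + v3)) < 0) F[f, ] <- F[f, c(1, 3, 2)]
  }
  list(vertices = V, faces = F)
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2], a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

#' Nested triangulated three-shell surfaces
#'
#' Procedurally generated icosphere meshes for the brain, skull and scalp
#' shells of a [shell_model()] (a stand-in for an external template mesh;
#' external Wavefront OBJ surfaces can be loaded with [read_obj()]).
#'
#' @param model A [shell_model()].
#' @param subdiv Icosphere subdivision level (3 = 1280 triangles/surface).
#' @return An object of class `tri_surface_set`: list of three surfaces
#'   (vertices, faces) ordered brain, skull, scalp, plus per-interface
#'   inside/outside conductivities.
#' @export
three_shell_mesh <- function(model = shell_model(), subdiv = 3) {
  base <- icosphere(subdiv)
  surfaces <- lapply(seq_len(3), function(i) {
    list(vertices = sweep(base$vertices * model$radii[i], 2, model$center, `+`),
         faces = base$faces)
  })
  names(surfaces) <- c("brain", "skull", "scalp")
  sig <- model$conductivities
  structure(list(surfaces = surfaces,
                 sigma_in = c(sig[1], sig[2], sig[3]),
                 sigma_out = c(sig[2], sig[3], 0),
                 center = model$center),
            class = "tri_surface_set")
}

#' Validate a triangulated surface set
#'
#' Checks closedness (every edge shared by exactly two triangles), consistent
#' outward orientation (interior solid angle 4 pi at the centroid) and nesting
#' of the three surfaces.
#'
#' @param mesh A `tri_surface_set`.
#' @return Invisibly `TRUE`; stops with a descriptive error otherwise.
#' @export
validate_mesh <- function(mesh) {
  stopifnot(inherits(mesh, "tri_surface_set"))
  rmax_prev <- -Inf
  for (nm in names(mesh$surfaces)) {
    s <- mesh$surfaces[[nm]]
    ed <- rbind(s$faces[, c(1, 2)], s$faces[, c(2, 3)], s$faces[, c(3, 1)])
    key <- paste(pmin(ed[, 1], ed[, 2]), pmax(ed[, 1], ed[, 2]))
    if (any(table(key) != 2)) stop("surface '", nm, "' is not closed")
    ctr <- colMeans(s$vertices)
    omega <- sum(solid_angles_cpp(matrix(ctr, 1), s$vertices,
                                  matrix(as.integer(s$faces), ncol = 3)))
    if (abs(omega - 4 * pi) > 1e-6)
      stop("surface '", nm, "' is not consistently outward-oriented")
    r <- sqrt(rowSums(sweep(s$vertices, 2, mesh$center)^2))
    if (min(r) <= rmax_prev) stop("surfaces are not strictly nested at '", nm, "'")
    rmax_prev <- max(r)
  }
  invisible(TRUE)
}

#' Standard 30-channel 10-20 electrode montage
#'
#' Idealised spherical positions for the 30 recording labels (AFz ground and
#' CPz reference; CPz is carried as a recorded channel and is identically zero
#' under the CPz reference convention).  Positions are placed on the scalp
#' shell of `model` using the gnomonic two-angle construction (18-degree
#' 10-20 steps; x right, y anterior, z up, meters, head-centered).
#'
#' @param model A [shell_model()] providing the scalp radius.
#' @return An object of class `electrode_montage` with `labels`, `positions`
#'   (n x 3, m), `ground`, `reference`.
#' @export
standard_montage <- function(model = shell_model()) {
  ang <- montage_angles()
  R <- model$radii[3]
  pos <- t(apply(ang, 1, function(a) {
    d <- c(tan(a[2] * pi / 180), tan(a[1] * pi / 180), 1)
    d / sqrt(sum(d^2)) * R
  }))
  pos <- sweep(pos, 2, model$center, `+`)
  structure(list(labels = rownames(ang), positions = pos,
                 ground = "AFz", reference = "CPz"),
            class = "electrode_montage")
}

# (anterior angle, rightward angle) in degrees per label
montage_angles <- function() {
  a <- rbind(
    Fp1 = c(72, -18), Fp2 = c(72, 18),
    F7 = c(36, -72), F3 = c(36, -36), Fz = c(36, 0), F4 = c(36, 36), F8 = c(36, 72),
    FC5 = c(18, -54), FC1 = c(18, -18), FC2 = c(18, 18), FC6 = c(18, 54),
    T7 = c(0, -72), C3 = c(0, -36), Cz = c(0, 0), C4 = c(0, 36), T8 = c(0, 72),
    CP5 = c(-18, -54), CP1 = c(-18, -18), CPz = c(-18, 0), CP2 = c(-18, 18),
    CP6 = c(-18, 54),
    P7 = c(-36, -72), P3 = c(-36, -36), Pz = c(-36, 0), P4 = c(-36, 36),
    P8 = c(-36, 72),
    PO3 = c(-54, -36), PO4 = c(-54, 36),
    O1 = c(-72, -18), O2 = c(-72, 18))
  a
}

#' Subset an electrode montage
#'
#' Keeps the given labels (order preserved); the reference must remain in the
#' subset.
#'
#' @param montage An `electrode_montage`.
#' @param labels Labels to keep.
#' @return An `electrode_montage`.
#' @export
montage_subset <- function(montage, labels) {
  idx <- match(labels, montage$labels)
  if (anyNA(idx))
    stop("unknown labels: ", paste(labels[is.na(idx)], collapse = ", "))
  if (!montage$reference %in% labels)
    stop("the reference channel must remain in the subset")
  structure(list(labels = montage$labels[idx],
                 positions = montage$positions[idx, , drop = FALSE],
                 ground = montage$ground, reference = montage$reference),
            class = "electrode_montage")
}

#' Read / write .sfp-style electrode files
#'
#' Plain text, one `label x y z` line per electrode (meters).
#'
#' @param path File path.
#' @param montage An `electrode_montage` (for writing).
#' @param ground,reference Labels recorded in the returned montage.
#' @return `read_sfp` returns an `electrode_montage`.
#' @export
read_sfp <- function(path, ground = "AFz", reference = "CPz") {
  tab <- read.table(path, header = FALSE, col.names = c("label", "x", "y", "z"),
                    stringsAsFactors = FALSE)
  if (anyDuplicated(tab$label)) stop("duplicate electrode labels in ", path)
  structure(list(labels = tab$label,
                 positions = as.matrix(tab[, c("x", "y", "z")]),
                 ground = ground, reference = reference),
            class = "electrode_montage")
}

#' @rdname read_sfp
#' @export
write_sfp <- function(montage, path) {
  df <- data.frame(label = montage$labels, montage$positions)
  write.table(df, path, quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read / write Wavefront OBJ surfaces
#'
#' Minimal OBJ support: `v` and triangular `f` records.
#'
#' @param path File path.
#' @param surface List with `vertices` (n x 3) and `faces` (m x 3, 1-based).
#' @return `read_obj` returns such a list.
#' @export
read_obj <- function(path) {
  lines <- readLines(path)
  vl <- grep("^v ", lines, value = TRUE)
  fl <- grep("^f ", lines, value = TRUE)
  V <- do.call(rbind, lapply(strsplit(vl, "[ ]+"), function(x) as.numeric(x[2:4])))
  F <- do.call(rbind, lapply(strsplit(fl, "[ ]+"), function(x)
    as.integer(sub("/.*", "", x[2:4]))))
  list(vertices = V, faces = F)
}

#' @rdname read_obj
#' @export
write_obj <- function(surface, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("v %.9g %.9g %.9g", surface$vertices[, 1],
                     surface$vertices[, 2], surface$vertices[, 3]), con)
  writeLines(sprintf("f %d %d %d", surface$faces[, 1], surface$faces[, 2],
                     surface$faces[, 3]), con)
  invisible(path)
}
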