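#' Construct a triangulated surface mesh
#'
#' Low-level constructor. Coordinates are in mm, right-handed, with the
#' cortical sheet lying near z = 0 and the coil approaching from +z. The
#' medial edge is minimum-x and the anterior edge maximum-y; this convention
#' fixes stimulation-zone labelling unambiguously.
#'
#' @param vertices V x 3 numeric matrix of coordinates (mm).
#' @param faces F x 3 integer matrix of 1-based vertex indices.
#' @param normals Optional V x 3 matrix of unit outward normals; computed
#'   from the faces (area-weighted, oriented toward +z) when omitted.
#' @return Object of class `surface_mesh` with elements `vertices`, `faces`,
#'   `normals`.
#' @export
surface_mesh <- function(vertices, faces, normals = NULL) {
  vertices <- as.matrix(vertices)
  faces <- matrix(as.integer(as.matrix(faces)), ncol = 3)
  if (nrow(vertices) < 3 || ncol(vertices) != 3)
    stop_input("mesh needs >= 3 vertices with 3 coordinates each")
  if (nrow(faces) < 1)
    stop_input("mesh needs >= 1 face")
  if (any(faces < 1) || any(faces > nrow(vertices)))
    stop_input("face indices out of range")
  if (is.null(normals)) normals <- vertex_normals(vertices, faces)
  structure(list(vertices = vertices, faces = faces, normals = normals),
            class = "surface_mesh")
}

#' @export
print.surface_mesh <- function(x, ...) {
  cat(sprintf("surface_mesh: %d vertices, %d faces\n",
              nrow(x$vertices), nrow(x$faces)))
  rg <- apply(x$vertices, 2, range)
  cat(sprintf("  x [%.1f, %.1f]  y [%.1f, %.1f]  z [%.2f, %.2f] mm\n",
              rg[1, 1], rg[2, 1], rg[1, 2], rg[2, 2], rg[1, 3], rg[2, 3]))
  invisible(x)
}

n_vertices <- function(mesh) nrow(mesh$vertices)

# Area-weighted per-vertex normals from face cross products, unit length,
# flipped to point toward +z (the coil side).
vertex_normals <- function(vertices, faces) {
  v1 <- vertices[faces[, 1], , drop = FALSE]
  v2 <- vertices[faces[, 2], , drop = FALSE]
  v3 <- vertices[faces[, 3], , drop = FALSE]
  e1 <- v2 - v1
  e2 <- v3 - v1
  fn <- cbind(e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
              e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
              e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1])  # length = 2 * area
  nrm <- matrix(0, nrow(vertices), 3)
  for (k in 1:3) {
    for (d in 1:3) {
      acc <- rowsum(fn[, d], faces[, k])
      idx <- as.integer(rownames(acc))
      nrm[idx, d] <- nrm[idx, d] + acc[, 1]
    }
  }
  len <- sqrt(rowSums(nrm^2))
  bad <- len < 1e-12
  if (any(bad)) {
    nrm[bad, ] <- rep(c(0, 0, 1), each = sum(bad))
    len[bad] <- 1
  }
  nrm <- nrm / len
  flip <- nrm[, 3] < 0
  nrm[flip, ] <- -nrm[flip, ]
  nrm
}

#' Generate a synthetic folded cortical patch
#'
#' Builds a rectangular sheet z = f(x, y), triangulated row-major, standing
#' in for a pial surface patch. The multi-gyral layout uses a periodic fold
#' across the medial-lateral (x) axis with a mild anterior-posterior
#' modulation, emulating repeated gyral crowns; the single-dominant-gyrus
#' layout uses a Ricker (Mexican-hat) cross-section, giving exactly one
#' crown flanked by two sulci, as in the macaque prefrontal cortex. Fold
#' phases and the crown position receive small seed-controlled jitter, so
#' the generator is a pure function of (profile, resolution, seed).
#'
#' @param profile A [species_profile()].
#' @param resolution Vertices per mm along each axis (default 0.35, about
#'   2.9 mm vertex spacing). Must yield at least a 20 x 20 lattice.
#' @param seed Integer random seed.
#' @return A [surface_mesh()]. Attribute `lattice` stores `c(nx, ny)`.
#' @examples
#' mesh <- make_folded_sheet(species_profile("macaque"), seed = 1)
#' mesh
#' @export
make_folded_sheet <- function(profile, resolution = 0.35, seed = 1L) {
  validate_species_profile(profile)
  if (!is.numeric(resolution) || resolution <= 0)
    stop_input("'resolution' must be positive")
  nx <- round(profile$extent[1] * resolution) + 1L
  ny <- round(profile$extent[2] * resolution) + 1L
  if (nx < 20 || ny < 20)
    stop_input("resolution too coarse: need at least a 20 x 20 vertex lattice, got ",
               nx, " x ", ny)
  xs <- seq(0, profile$extent[1], length.out = nx)
  ys <- seq(0, profile$extent[2], length.out = ny)
  A <- profile$fold_amplitude
  lam <- profile$fold_wavelength
  cx <- profile$extent[1] / 2
  cy <- profile$extent[2] / 2

  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(as.integer(seed))
  jit <- stats::runif(3, -1, 1)

  if (profile$fold_layout == "multi-gyral") {
    phi <- jit[1] * pi / 6
    psi <- jit[2] * pi
    zx <- cos(2 * pi * (xs - cx) / lam + phi)
    zy <- 0.85 + 0.15 * cos(2 * pi * (ys - cy) / (2.3 * lam) + psi)
    z <- A * outer(zx, zy)                      # nx x ny
  } else {
    # Ricker wavelet across x: one crown at u = 0, sulcal minima at
    # u = +/- sqrt(3); scale chosen so the sulci sit lam/2 from the crown.
    cxj <- cx + jit[1] * 0.03 * profile$extent[1]
    s <- lam / (2 * sqrt(3))
    u <- (xs - cxj) / s
    zx <- (1 - u^2) * exp(-u^2 / 2)
    zy <- 0.9 + 0.1 * (1 + jit[2] * 0.3) *
      exp(-((ys - cy) / (0.6 * profile$extent[2]))^2)
    z <- A * outer(zx, zy)
  }

  # row-major lattice: vertex (ix, iy) -> index (iy - 1) * nx + ix
  vertices <- cbind(
    x = rep(xs, times = ny),
    y = rep(ys, each = nx),
    z = as.vector(z)
  )
  faces <- lattice_faces(nx, ny)
  mesh <- surface_mesh(vertices, faces)
  attr(mesh, "lattice") <- c(nx = nx, ny = ny)
  attr(mesh, "profile") <- profile
  mesh
}

# Two counter-clockwise (seen from +z) triangles per lattice cell.
lattice_faces <- function(nx, ny) {
  ix <- rep(seq_len(nx - 1), times = ny - 1)
  iy <- rep(seq_len(ny - 1), each = nx - 1)
  v00 <- (iy - 1L) * nx + ix
  v10 <- v00 + 1L
  v01 <- v00 + nx
  v11 <- v01 + 1L
  rbind(cbind(v00, v10, v11), cbind(v00, v11, v01))
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
}

.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}

#' Default parcellation layouts
#'
#' A layout is a data frame of axis-aligned rectangles in fractional patch
#' coordinates (`x0 < x1`, `y0 < y1` in `[0, 1]`, x growing medial to
#' lateral, y posterior to anterior) with a network `label` (1..7). Earlier
#' rows win where rectangles overlap; vertices covered by no rectangle get
#' label 0 (unassigned). Rectangle areas must sum to at most 1.
#'
#' The human-like default places the Default network as the medial band and
#' the Frontoparietal network as the lateral band, with a posterior strip of
#' Somatomotor / Dorsal Attention / Ventral Attention. The macaque-like
#' default places the Frontoparietal network on the dominant gyral crown
#' (central x band), Somatomotor posteriorly on both flanks, and small
#' Default / Dorsal Attention / Ventral Attention patches.
#'
#' @param species `"human"` or `"macaque"`.
#' @return A layout data frame (`label`, `x0`, `x1`, `y0`, `y1`).
#' @export
default_layout <- function(species = c("human", "macaque")) {
  species <- match.arg(species)
  if (species == "human") {
    data.frame(
      label = c(7L, 6L, 7L, 6L, 2L, 3L, 4L),
      x0 = c(0.0, 0.5, 0.0, 5 / 6, 1 / 6, 7 / 18, 11 / 18),
      x1 = c(0.5, 1.0, 1 / 6, 1.0, 7 / 18, 11 / 18, 5 / 6),
      y0 = c(0.15, 0.15, 0.0, 0.0, 0.0, 0.0, 0.0),
      y1 = c(1.0, 1.0, 0.15, 0.15, 0.15, 0.15, 0.15)
    )
  } else {
    data.frame(
      label = c(6L, 2L, 2L, 7L, 3L, 4L),
      x0 = c(0.35, 0.00, 0.65, 0.00, 0.80, 0.80),
      x1 = c(0.65, 0.35, 1.00, 0.20, 1.00, 1.00),
      y0 = c(0.00, 0.00, 0.00, 0.60, 0.60, 0.30),
      y1 = c(1.00, 0.30, 0.30, 1.00, 1.00, 0.60)
    )
  }
}

#' Assign network labels to mesh vertices
#'
#' Paints the rectangles of a layout (see [default_layout()]) onto the mesh
#' in fractional patch coordinates. Every vertex receives exactly one label;
#' leftover vertices get 0 (unassigned / medial wall), which downstream
#' overlap calculations report as the unassigned share.
#'
#' @param mesh A [surface_mesh()].
#' @param layout Layout data frame, or `"human"` / `"macaque"` for the
#'   defaults.
#' @param seed Unused by the rectangular layouts; kept so that parcellation
#'   generation has the same pure-function signature as the mesh generator.
#' @return Integer vector of per-vertex labels in 0..7, class
#'   `parcellation_map`.
#' @examples
#' mesh <- make_folded_sheet(species_profile("macaque"), seed = 1)
#' table(make_parcellation(mesh, "macaque"))
#' @export
make_parcellation <- function(mesh, layout = "human", seed = 1L) {
  stopifnot(inherits(mesh, "surface_mesh"))
  if (is.character(layout)) layout <- default_layout(layout)
  if (!is.data.frame(layout) ||
      !all(c("label", "x0", "x1", "y0", "y1") %in% names(layout)))
    stop_input("layout must be a data frame with label, x0, x1, y0, y1")
  if (nrow(layout) < 1)
    stop_input("layout must list at least 1 band")
  if (any(layout$label < 1 | layout$label > 7))
    stop_input("layout labels must be in 1..7")
  if (any(layout$x1 <= layout$x0) || any(layout$y1 <= layout$y0) ||
      any(layout$x0 < 0) || any(layout$x1 > 1) ||
      any(layout$y0 < 0) || any(layout$y1 > 1))
    stop_input("layout rectangles must satisfy 0 <= x0 < x1 <= 1, 0 <= y0 < y1 <= 1")
  area <- sum((layout$x1 - layout$x0) * (layout$y1 - layout$y0))
  if (area > 1 + 1e-9)
    stop_input("layout band widths sum to more than 1 (total area ",
               signif(area, 4), ")")

  v <- mesh$vertices
  fx <- (v[, 1] - min(v[, 1])) / max(diff(range(v[, 1])), .Machine$double.eps)
  fy <- (v[, 2] - min(v[, 2])) / max(diff(range(v[, 2])), .Machine$double.eps)
  labels <- integer(nrow(v))
  # earlier rows win; the last band is closed on its upper edges so the
  # fx = 1 / fy = 1 boundary vertices are not dropped
  for (i in rev(seq_len(nrow(layout)))) {
    b <- layout[i, ]
    inb <- fx >= b$x0 & fy >= b$y0 &
      (fx < b$x1 | (b$x1 >= 1 - 1e-12 & fx <= 1)) &
      (fy < b$y1 | (b$y1 >= 1 - 1e-12 & fy <= 1))
    labels[inb] <- b$label
  }
  structure(labels, class = "parcellation_map")
}

#' @export
print.parcellation_map <- function(x, ...) {
  tab <- table(factor(unclass(x), levels = 0:7))
  names(tab) <- c("unassigned", yeo7_abbrev)
  cat("parcellation_map over", length(x), "vertices\n")
  print(tab)
  invisible(x)
}

#' Nearest-point value transfer onto a mesh
#'
#' Assigns to every mesh vertex the value of its nearest point (Euclidean
#' distance), the reduced form of the iterative-closest-point interpolation
#' used to carry volumetric field estimates onto a pial surface. Ties are
#' broken by the lowest point index, so the mapping is deterministic.
#'
#' @param points N x 3 matrix of coordinates (mm).
#' @param values Length-N vector of scalars.
#' @param mesh A [surface_mesh()].
#' @return Numeric vector, one value per mesh vertex.
#' @export
map_points_to_surface <- function(points, values, mesh) {
  stopifnot(inherits(mesh, "surface_mesh"))
  points <- matrix(as.numeric(points), ncol = 3)
  if (nrow(points) < 1) stop_input("point set must be non-empty")
  if (length(values) != nrow(points))
    stop_input("'values' must have one entry per point")
  v <- mesh$vertices
  out <- numeric(nrow(v))
  block <- max(1L, floor(2e6 / nrow(points)))
  pt2 <- rowSums(points^2)
  for (start in seq(1L, nrow(v), by = block)) {
    idx <- start:min(start + block - 1L, nrow(v))
    # squared distance up to a per-vertex constant; which.max of the
    # negative keeps the lowest-index tie-break of which.min
    d2 <- outer(rep(1, length(idx)), pt2) - 2 * v[idx, , drop = FALSE] %*% t(points)
    out[idx] <- values[apply(d2, 1, which.min)]
  }
  out
}
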