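#' Figure-8 coil model
#'
#' Parameters of the simplified planar figure-8 coil: two circular loops of
#' equal radius with opposite winding sense, lying in a plane parallel to
#' the patch, their centers separated by one loop diameter along the handle
#' axis. The default 35 mm radius corresponds to a 70 mm figure-8 coil. The
#' induced primary electric field is the free-space -dA/dt of the loop
#' currents; each loop is discretized into straight segments.
#'
#' @param radius Loop radius in mm (default 35).
#' @param segments Straight segments per loop (default 64, minimum 8).
#' @param dIdt Coil current rate of change in A/s (default 1e8, a typical
#'   TMS pulse slope). |E| scales linearly in `dIdt`.
#' @return Object of class `coil_model`.
#' @export
coil_model <- function(radius = 35, segments = 64L, dIdt = 1e8) {
  if (!is.numeric(radius) || radius <= 0) stop_input("'radius' must be > 0")
  if (segments < 8) stop_input("'segments' must be >= 8")
  if (!is.numeric(dIdt) || dIdt <= 0) stop_input("'dIdt' must be > 0")
  structure(list(radius = radius, segments = as.integer(segments),
                 dIdt = dIdt), class = "coil_model")
}

#' Enumerate the stimulation grid
#'
#' Builds the full placement set: a planar 6 x 6 lattice of coil locations
#' at the species grid spacing (10 mm human-like, 5 mm macaque-like),
#' centered over the patch center and offset from the surface by the scalp
#' standoff, crossed with 12 coil orientations 0-165 degrees in 15-degree
#' steps (0 degrees = handle along the midline, the +y axis). Row 0 is the
#' most anterior row (maximum y) and column 0 the most medial column
#' (minimum x), matching the zone convention of [zone_of()].
#'
#' @param profile A [species_profile()].
#' @param mesh The [surface_mesh()] the grid is positioned over.
#' @param n_rows,n_cols,orientations Grid overrides; defaults 6, 6 and
#'   `seq(0, 165, by = 15)`.
#' @return A `coil_grid` data frame with one row per placement: `row`,
#'   `col`, `theta_deg`, coil center `x`, `y`, `z`, handle direction
#'   `hx`, `hy`, `hz` and coil normal `nx`, `ny`, `nz` (pointing toward the
#'   surface, -z).
#' @examples
#' mesh <- make_folded_sheet(species_profile("macaque"), seed = 1)
#' grid <- build_grid(species_profile("macaque"), mesh)
#' nrow(grid)  # 432
#' @export
build_grid <- function(profile, mesh, n_rows = 6L, n_cols = 6L,
                       orientations = seq(0, 165, by = 15)) {
  validate_species_profile(profile)
  stopifnot(inherits(mesh, "surface_mesh"))
  v <- mesh$vertices
  cx <- mean(range(v[, 1]))
  cy <- mean(range(v[, 2]))
  span_x <- (n_cols - 1) * profile$spacing
  span_y <- (n_rows - 1) * profile$spacing
  if (span_x > diff(range(v[, 1])) || span_y > diff(range(v[, 2])))
    stop_input("grid footprint (", span_x, " x ", span_y,
               " mm) exceeds the patch extent")
  z_coil <- max(v[, 3]) + profile$standoff
  rows <- rep(rep(0:(n_rows - 1L), each = n_cols), times = length(orientations))
  cols <- rep(rep(0:(n_cols - 1L), times = n_rows), times = length(orientations))
  th <- rep(orientations, each = n_rows * n_cols)
  # col 0 medial (min x); row 0 anterior (max y)
  x <- cx + (cols - (n_cols - 1) / 2) * profile$spacing
  y <- cy + ((n_rows - 1) / 2 - rows) * profile$spacing
  thr <- th * pi / 180
  df <- data.frame(
    row = rows, col = cols, theta_deg = th,
    x = x, y = y, z = z_coil,
    hx = sin(thr), hy = cos(thr), hz = 0,
    nx = 0, ny = 0, nz = -1
  )
  df <- df[order(df$row, df$col, df$theta_deg), ]
  rownames(df) <- NULL
  class(df) <- c("coil_grid", class(df))
  df
}

# Segment midpoints and direction vectors (mm) for one figure-8 placement.
# The two loop centers sit at center +/- radius * handle; winding sense is
# opposite so the central segments' contributions add beneath the junction.
figure8_segments <- function(coil, placement) {
  S <- coil$segments
  ang <- seq(0, 2 * pi, length.out = S + 1)
  h <- c(placement$hx, placement$hy, placement$hz)
  nrm <- c(placement$nx, placement$ny, placement$nz)
  p <- c(crossprod3(nrm, h))          # in-plane axis perpendicular to handle
  ctr <- c(placement$x, placement$y, placement$z)
  seg <- function(center, sense) {
    pts <- outer(cos(ang), h * coil$radius) + outer(sin(ang), p * coil$radius)
    pts <- sweep(pts, 2, center, "+")
    mid <- (pts[-1, , drop = FALSE] + pts[-(S + 1), , drop = FALSE]) / 2
    dl <- sense * (pts[-1, , drop = FALSE] - pts[-(S + 1), , drop = FALSE])
    list(mid = mid, dl = dl)
  }
  a <- seg(ctr + coil$radius * h, +1)
  b <- seg(ctr - coil$radius * h, -1)
  list(mid = rbind(a$mid, b$mid), dl = rbind(a$dl, b$dl))
}

crossprod3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

#' Primary electric field of a figure-8 coil on a mesh
#'
#' Computes the free-space primary field magnitude |E| = |dA/dt| at every
#' mesh vertex, where A is the magnetic vector potential of the two
#' discretized coil loops,
#' \deqn{A(r) = \frac{\mu_0 I}{4\pi} \sum_k \frac{\Delta l_k}{|r - m_k|},}
#' with segment midpoints m_k and directed lengths \eqn{\Delta l_k}. This is
#' the field a homogeneous-conductivity model captures; tissue interfaces
#' and charge accumulation are deliberately out of scope.
#'
#' @param coil A [coil_model()].
#' @param placement One row of a `coil_grid` (see [build_grid()]).
#' @param mesh A [surface_mesh()].
#' @return Numeric vector of |E| in V/m, class `efield_map`, with the
#'   placement stored in attribute `placement`.
#' @export
primary_efield <- function(coil, placement, mesh) {
  stopifnot(inherits(coil, "coil_model"), inherits(mesh, "surface_mesh"))
  if (placement$z <= max(mesh$vertices[, 3]))
    stop_input("placement must sit off-surface (positive standoff)")
  sg <- figure8_segments(coil, placement)
  ev <- efield_vectors(sg, mesh$vertices, coil$dIdt)
  structure(sqrt(rowSums(ev^2)), class = "efield_map",
            placement = placement[, c("row", "col", "theta_deg")])
}

# -dA/dt (V/m) at each evaluation point; positions in mm, converted to m.
efield_vectors <- function(sg, points, dIdt) {
  mid <- sg$mid * 1e-3
  dl <- sg$dl * 1e-3
  pts <- points * 1e-3
  # |r - m| for all point x segment pairs
  d2 <- outer(rowSums(pts^2), rowSums(mid^2), "+") - 2 * pts %*% t(mid)
  d2[d2 < 0] <- 0
  d <- sqrt(d2)
  if (any(d < 1e-12))
    stop_input("evaluation point coincides with a coil segment")
  inv <- 1 / d
  1e-7 * dIdt * cbind(inv %*% dl[, 1], inv %*% dl[, 2], inv %*% dl[, 3])
}

#' Synthetic Gaussian field map centered on a vertex
#'
#' Test fixture: an isotropic field with |E|(v) = exp(-d(v)^2 / (2 spread^2))
#' where d is Euclidean distance to the chosen center vertex (a stand-in for
#' geodesic distance on these shallow patches). The maximum is exactly 1 at
#' the center.
#'
#' @param mesh A [surface_mesh()].
#' @param center_vertex 1-based vertex index.
#' @param spread Gaussian scale in mm.
#' @return An `efield_map`.
#' @export
planted_field <- function(mesh, center_vertex, spread) {
  stopifnot(inherits(mesh, "surface_mesh"))
  nv <- n_vertices(mesh)
  if (!is.numeric(center_vertex) || center_vertex < 1 || center_vertex > nv)
    stop_input("invalid center vertex index")
  if (!is.numeric(spread) || spread <= 0) stop_input("'spread' must be > 0")
  d2 <- rowSums(sweep(mesh$vertices, 2, mesh$vertices[center_vertex, ])^2)
  structure(exp(-d2 / (2 * spread^2)), class = "efield_map",
            placement = NULL)
}

#' Electric field stimulation index (EFSI)
#'
#' For each vertex, the percentage of field maps (coil configurations) in
#' which that vertex's |E| strictly exceeds `fraction` of that map's
#' maximum. A vertex with EFSI near 100 sits above half-maximum in nearly
#' every simulated configuration -- the region a stimulation grid targets
#' preferentially regardless of coil placement. The per-configuration
#' complement (percentage of vertices above threshold in each map) is
#' returned as attribute `per_map_percent`.
#'
#' @param fields List of `efield_map`s on the same mesh, or a V x K numeric
#'   matrix with one column per configuration.
#' @param fraction Threshold as a fraction of each map's maximum
#'   (default 0.5).
#' @return Numeric vector in \[0, 100\], class `efsi_map`.
#' @export
efsi <- function(fields, fraction = 0.5) {
  fm <- as_field_matrix(fields)
  if (ncol(fm) < 1) stop_input("need at least one field map")
  mx <- apply(fm, 2, max)
  if (any(mx <= 0)) stop_input("field map ", which(mx <= 0)[1],
                               " is all zero (degenerate)")
  above <- sweep(fm, 2, fraction * mx, ">")
  structure(100 * rowMeans(above), class = "efsi_map",
            per_map_percent = 100 * colMeans(above))
}

as_field_matrix <- function(fields) {
  if (is.list(fields)) {
    if (length(fields) == 0) stop_input("empty field list")
    nv <- unique(vapply(fields, length, 1L))
    if (length(nv) != 1) stop_input("field maps are not on the same mesh")
    fields <- matrix(unlist(fields, use.names = FALSE), nrow = nv)
  }
  as.matrix(fields)
}
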