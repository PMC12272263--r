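test_that("folded sheets are deterministic, well-formed meshes", {
  prof <- species_profile("human")
  m1 <- make_folded_sheet(prof, seed = 7)
  m2 <- make_folded_sheet(prof, seed = 7)
  expect_identical(m1$vertices, m2$vertices)
  expect_identical(m1$faces, m2$faces)
  m3 <- make_folded_sheet(prof, seed = 8)
  expect_false(identical(m1$vertices, m3$vertices))

  for (m in list(m1, make_folded_sheet(species_profile("macaque"), seed = 1))) {
    expect_gte(nrow(m$vertices), 3)
    expect_gte(nrow(m$faces), 1)
    expect_true(all(m$faces >= 1 & m$faces <= nrow(m$vertices)))
    expect_equal(sqrt(rowSums(m$normals^2)), rep(1, nrow(m$vertices)),
                 tolerance = 1e-6)
    # no degenerate triangles
    v1 <- m$vertices[m$faces[, 1], ]
    e1 <- m$vertices[m$faces[, 2], ] - v1
    e2 <- m$vertices[m$faces[, 3], ] - v1
    cr <- cbind(e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
                e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
                e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1])
    expect_gt(min(sqrt(rowSums(cr^2))) / 2, 1e-6)
  }
})

test_that("zero fold amplitude gives a flat sheet with uniform +z normals", {
  prof <- species_profile("human", fold_amplitude = 0)
  m <- make_folded_sheet(prof, seed = 3)
  expect_equal(max(abs(m$vertices[, 3])), 0)
  expect_equal(m$normals, matrix(rep(c(0, 0, 1), each = nrow(m$normals)),
                                 ncol = 3))
})

test_that("single-dominant-gyrus layout has one crown flanked by two sulci", {
  prof <- species_profile("macaque")
  m <- make_folded_sheet(prof, resolution = 0.6, seed = 5)
  lat <- attr(m, "lattice")
  # cross-fold transect through the patch center: one row of the lattice
  mid_row <- ceiling(lat["ny"] / 2)
  idx <- (mid_row - 1) * lat["nx"] + seq_len(lat["nx"])
  z <- m$vertices[idx, 3]
  dz <- diff(z)
  n_local_max <- sum(dz[-length(dz)] > 0 & dz[-1] < 0)
  expect_identical(n_local_max, 1L)
  # sulci: interior minima below the flat baseline on both sides of crown
  crown <- which.max(z)
  expect_lt(min(z[1:crown]), 0)
  expect_lt(min(z[crown:length(z)]), 0)
})

test_that("parcellation layouts paint bands as specified", {
  m <- flat_sheet(10, 10)
  # single band covering the whole patch
  one <- data.frame(label = 6L, x0 = 0, x1 = 1, y0 = 0, y1 = 1)
  expect_true(all(unclass(make_parcellation(m, one)) == 6L))
  # two equal bands on a 100-vertex sheet: 50 vertices each
  two <- data.frame(label = c(7L, 6L), x0 = c(0, 0.5), x1 = c(0.5, 1),
                    y0 = 0, y1 = 1)
  p <- unclass(make_parcellation(m, two))
  expect_identical(as.integer(table(p)), c(50L, 50L))
  # widths summing above 1 rejected
  over <- data.frame(label = c(7L, 6L), x0 = c(0, 0.4), x1 = c(0.7, 1),
                     y0 = 0, y1 = 1)
  expect_error(make_parcellation(m, over), "sum")
})

test_that("default human layout: medial column DN, lateral column FPN", {
  m <- make_folded_sheet(species_profile("human"), seed = 2)
  p <- unclass(make_parcellation(m, "human"))
  expect_length(p, nrow(m$vertices))
  x <- m$vertices[, 1]
  expect_true(all(p[x == min(x)] == yeo7_networks["Default"]))
  expect_true(all(p[x == max(x)] == yeo7_networks["Frontoparietal"]))
  expect_gte(length(setdiff(unique(p), 0L)), 2)
})

test_that("default macaque layout puts FPN on the dominant crown", {
  m <- make_folded_sheet(species_profile("macaque"), seed = 2)
  p <- unclass(make_parcellation(m, "macaque"))
  crown <- which(m$vertices[, 3] > 0.9 * max(m$vertices[, 3]))
  expect_true(all(p[crown] == yeo7_networks["Frontoparietal"]))
  expect_gte(length(setdiff(unique(p), 0L)), 2)
})

test_that("map_points_to_surface matches brute-force nearest neighbour", {
  m <- flat_sheet(5, 4)
  # identity mapping
  vals <- seq_len(nrow(m$vertices))
  expect_equal(map_points_to_surface(m$vertices, vals, m), vals)
  # single point: constant map
  expect_equal(map_points_to_surface(matrix(c(9, 9, 9), 1), 4.2, m),
               rep(4.2, nrow(m$vertices)))
  # known small instance against exhaustive search
  pts <- rbind(c(0, 0, 0), c(3.2, 1.1, 0.5), c(1.0, 2.9, -0.2))
  vv <- c(10, 20, 30)
  expect_equal(map_points_to_surface(pts, vv, m), nn_brute(pts, vv, m$vertices))
  # randomized property, fixed seed
  set.seed(11)
  for (i in 1:5) {
    pts <- matrix(stats::rnorm(3 * 7, sd = 3), ncol = 3)
    vv <- stats::rnorm(7)
    expect_equal(map_points_to_surface(pts, vv, m),
                 nn_brute(pts, vv, m$vertices))
  }
  expect_error(map_points_to_surface(matrix(numeric(0), ncol = 3), numeric(0), m),
               "non-empty")
})

test_that("PLY and parcellation TSV round-trip", {
  m <- make_folded_sheet(species_profile("macaque"),
                         resolution = 0.32, seed = 4)
  f <- withr::local_tempfile(fileext = ".ply")
  write_ply(m, f)
  m2 <- read_ply(f)
  expect_equal(m2$vertices, m$vertices, tolerance = 1e-6,
               ignore_attr = TRUE)
  expect_identical(m2$faces, m$faces)

  p <- make_parcellation(m, "macaque")
  tf <- withr::local_tempfile(fileext = ".tsv")
  write_parcellation(p, tf)
  expect_identical(as.integer(read_parcellation(tf)), as.integer(p))
})
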