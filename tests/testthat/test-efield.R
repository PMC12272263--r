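test_that("build_grid enumerates the full placement set", {
  prof <- species_profile("macaque")
  mesh <- make_folded_sheet(prof, seed = 1)
  grid <- build_grid(prof, mesh)
  expect_identical(nrow(grid), 432L)
  expect_identical(nrow(unique(grid[, c("row", "col")])), 36L)
  expect_true(all(vapply(split(grid$theta_deg, paste(grid$row, grid$col)),
                         function(th) length(unique(th)), 1L) == 12L))
  # adjacent same-row locations are exactly one spacing apart
  loc <- unique(grid[, c("row", "col", "x", "y")])
  loc <- loc[order(loc$row, loc$col), ]
  dx <- with(loc, tapply(x, row, function(v) diff(sort(v))))
  expect_true(all(abs(unlist(dx) - prof$spacing) < 1e-12))
  # orientation convention and handle/normal orthogonality
  expect_true(all(abs(grid$hx * grid$nx + grid$hy * grid$ny +
                        grid$hz * grid$nz) < 1e-6))
  th0 <- grid[grid$theta_deg == 0, ][1, ]
  expect_equal(c(th0$hx, th0$hy, th0$hz), c(0, 1, 0))
  # grid larger than the patch is refused
  expect_error(build_grid(species_profile("macaque", spacing = 50), mesh),
               "footprint")
})

test_that("field magnitude is linear in dI/dt and deterministic", {
  prof <- species_profile("macaque")
  mesh <- make_folded_sheet(prof, seed = 1)
  grid <- build_grid(prof, mesh)
  pl <- grid[grid$row == 2 & grid$col == 3 & grid$theta_deg == 45, ]
  e1 <- primary_efield(coil_model(dIdt = 1e8), pl, mesh)
  e2 <- primary_efield(coil_model(dIdt = 2e8), pl, mesh)
  expect_equal(as.numeric(e2), 2 * as.numeric(e1), tolerance = 1e-12)
  e3 <- primary_efield(coil_model(dIdt = 1e8), pl, mesh)
  expect_identical(as.numeric(e1), as.numeric(e3))
  expect_true(all(as.numeric(e1) >= 0))
  expect_gt(max(as.numeric(e1)), 0)
})

test_that("discretized loop vector potential matches the elliptic closed form", {
  # package segment-sum kernel on a single 35 mm loop vs the
  # elliptic-integral closed form; |E|/dIdt = |A| for a unit-rate pulse
  a_mm <- 35
  sg <- single_loop_segments(a_mm, 64)
  pts_mm <- expand.grid(rho = c(5, 17.5, 30, 50), z = c(10, 25))
  eval_pts <- cbind(pts_mm$rho, 0, pts_mm$z)
  Avec <- tmstarget:::efield_vectors(list(mid = sg$mid, dl = sg$dl),
                                     eval_pts, dIdt = 1)
  A_disc <- sqrt(rowSums(Avec^2))
  A_exact <- mapply(function(r, z) loop_A_phi(a_mm * 1e-3, r * 1e-3, z * 1e-3),
                    pts_mm$rho, pts_mm$z)
  expect_lt(max(abs(A_disc - A_exact) / A_exact), 0.01)
})

test_that("peak |E| of a centered figure-8 lies under the coil intersection", {
  prof <- species_profile("human", fold_amplitude = 0)
  mesh <- make_folded_sheet(prof, seed = 1)
  grid <- build_grid(prof, mesh)
  ctr <- c(mean(range(mesh$vertices[, 1])), mean(range(mesh$vertices[, 2])))
  for (th in c(0, 90)) {
    pl <- grid[grid$row == 2 & grid$col == 2 & grid$theta_deg == th, ]
    pl$x <- ctr[1]; pl$y <- ctr[2]
    e <- primary_efield(coil_model(), pl, mesh)
    vmax <- mesh$vertices[which.max(as.numeric(e)), 1:2]
    expect_lt(sqrt(sum((vmax - ctr)^2)), prof$fold_wavelength)
  }
})

test_that("on a folded sheet crowns receive more field than sulcal floors", {
  prof <- species_profile("macaque")
  mesh <- make_folded_sheet(prof, seed = 1)
  grid <- build_grid(prof, mesh)
  pl <- grid[grid$row == 2 & grid$col == 2 & grid$theta_deg == 0, ]
  e <- as.numeric(primary_efield(coil_model(), pl, mesh))
  z <- mesh$vertices[, 3]
  crown <- z > 0.8 * max(z)
  sulcus <- z < 0.8 * min(z)
  expect_gt(mean(e[crown]), mean(e[sulcus]))
})

test_that("planted_field is a unit-peak monotone Gaussian falloff", {
  mesh <- flat_sheet(8, 8)
  ctr <- 28L
  f <- planted_field(mesh, ctr, spread = 2)
  expect_equal(as.numeric(f[ctr]), 1)
  expect_true(all(as.numeric(f) <= 1))
  d <- sqrt(rowSums(sweep(mesh$vertices, 2, mesh$vertices[ctr, ])^2))
  nn <- min(d[d > 0])
  expect_true(all(f[d > nn] < f[ctr]))
  expect_true(all(f[order(d)] == sort(as.numeric(f), decreasing = TRUE)))
  # spread -> Inf limit approaches a constant field
  expect_true(all(planted_field(mesh, ctr, spread = 1e9) > 1 - 1e-12))
  expect_error(planted_field(mesh, 0, 1), "vertex")
})

test_that("efsi counts above-half-max configurations per vertex", {
  f1 <- c(1.0, 0.6, 0.4, 0.2)
  # single map: 100 exactly above half-max, else 0
  expect_equal(as.numeric(efsi(list(f1))), c(100, 100, 0, 0))
  # vertex above half-max in 2 of 3 maps
  f2 <- c(0.3, 1.0, 0.9, 0.1)
  f3 <- c(0.9, 0.2, 1.0, 0.1)
  e <- as.numeric(efsi(list(f1, f2, f3)))
  expect_equal(e[1], 200 / 3, tolerance = 1e-4)
  # per-map maxima always count themselves
  expect_equal(as.numeric(efsi(list(f1, f2, f3)))[
    which(f1 == 1)], 200 / 3, tolerance = 1e-4)
  expect_true(all(e >= 0 & e <= 100))
  # relative threshold: positive rescaling never changes the result
  expect_equal(as.numeric(efsi(list(10 * f1, 0.2 * f2, f3))), e)
  # monotone in a vertex's field values
  f2b <- f2; f2b[4] <- 0.95
  expect_gte(as.numeric(efsi(list(f1, f2b, f3)))[4], e[4])
  # secondary per-configuration output
  expect_equal(attr(efsi(list(f1)), "per_map_percent"), 50)
  expect_error(efsi(list()), "empty")
  expect_error(efsi(list(c(0, 0, 0))), "zero")
})
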