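# Independent oracles used by DERIVED-value tests. These are deliberately
# naive implementations that share no code with the package paths they
# check.

# Complete elliptic integrals K(k), E(k) by arithmetic-geometric mean.
ke_agm <- function(k) {
  a <- 1; b <- sqrt(1 - k^2); cc <- k; s <- cc^2 / 2; p <- 1
  for (i in 1:60) {
    an <- (a + b) / 2
    b <- sqrt(a * b)
    cc <- a - an
    a <- an
    p <- p * 2
    s <- s + p * cc^2 / 2
    if (cc < 1e-16) break
  }
  K <- pi / (2 * a)
  list(K = K, E = K * (1 - s))
}

# Closed-form azimuthal vector potential A_phi (T*m) of a circular loop of
# radius a (m) carrying current I (A), at cylindrical (rho, z) in m.
loop_A_phi <- function(a, rho, z, I = 1) {
  k2 <- 4 * a * rho / ((a + rho)^2 + z^2)
  k <- sqrt(k2)
  ke <- ke_agm(k)
  (4e-7 * I / k) * sqrt(a / rho) * ((1 - k2 / 2) * ke$K - ke$E)
}

# Exhaustive nearest-point assignment (lowest index wins ties).
nn_brute <- function(points, values, vertices) {
  apply(vertices, 1, function(v) {
    d <- sqrt(colSums((t(points) - v)^2))
    values[which.min(d)]
  })
}

# Residual-correlation oracle: regress the covariate (with intercept) out
# of both series by explicit normal equations, then Pearson-correlate.
partial_corr_oracle <- function(seed_series, ts, covariate) {
  D <- cbind(1, covariate)
  beta <- function(y) solve(t(D) %*% D, t(D) %*% y)
  rs <- seed_series - D %*% beta(seed_series)
  apply(unclass(ts), 1, function(x) {
    rx <- x - D %*% beta(x)
    sum(rs * rx) / sqrt(sum(rs^2) * sum(rx^2))
  })
}

# Single circular loop (radius mm, in the z = 0 plane, centered at the
# origin) as a segment structure consumable by the package's field kernel.
single_loop_segments <- function(radius_mm, n_seg) {
  ang <- seq(0, 2 * pi, length.out = n_seg + 1)
  pts <- cbind(radius_mm * cos(ang), radius_mm * sin(ang), 0)
  list(mid = (pts[-1, ] + pts[-(n_seg + 1), ]) / 2,
       dl = pts[-1, ] - pts[-(n_seg + 1), ])
}
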