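# Independent oracles and shared fixtures for the test suite.

# O(N_R * N_G) brute-force pairing: nearest receptor within great-circle
# distance r_star, ties to the lowest receptor index.
brute_force_encounters <- function(rpos, gpos, r_star, L) {
  out <- rep(NA_integer_, nrow(gpos))
  for (g in seq_len(nrow(gpos))) {
    d <- great_circle_distance(matrix(gpos[g, ], nrow(rpos), 3,
                                      byrow = TRUE), rpos, L)
    ok <- which(d <= r_star)
    if (length(ok)) out[g] <- ok[which.min(d[ok])]
  }
  out
}

brute_force_resultant <- function(points, active, select) {
  v <- c(0, 0, 0)
  for (i in seq_along(active)) {
    keep <- if (select == "active") active[i] == 1L else active[i] == 0L
    if (keep) v <- v + points[i, ]
  }
  v
}

# rotation matrix about a unit axis by angle (radians), Rodrigues form
rotation_matrix <- function(axis, angle) {
  axis <- axis / sqrt(sum(axis^2))
  K <- matrix(c(0, -axis[3], axis[2],
                axis[3], 0, -axis[1],
                -axis[2], axis[1], 0), 3, 3, byrow = TRUE)
  diag(3) + sin(angle) * K + (1 - cos(angle)) * (K %*% K)
}

# mean equilibrium occupancy over a uniform sphere for gradient (C0, b), by
# quadrature in u = cos(latitude)
mean_occupancy_sphere <- function(C0, b, Kd) {
  f <- function(u) C0 * (1 + b * u) / (C0 * (1 + b * u) + Kd)
  stats::integrate(f, -1, 1)$value / 2
}

# cache for expensive shared computations (filled lazily by tests)
.shared_cache <- new.env(parent = emptyenv())
shared <- function(key, expr) {
  if (!exists(key, envir = .shared_cache))
    assign(key, force(expr), envir = .shared_cache)
  get(key, envir = .shared_cache)
}
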