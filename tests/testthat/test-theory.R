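test_that("equilibrium occupancy reproduces the printed values", {
  expect_equal(receptor_occupancy(6, 6), 0.5)
  expect_equal(receptor_occupancy(18, 6), 0.75)
  expect_equal(round(receptor_occupancy(1, 6), 2), 0.14)
  expect_equal(receptor_occupancy(0, 6), 0)
  expect_error(receptor_occupancy(-1, 6))
})

test_that("switching rate and molar on-rate conversions are exact", {
  expect_equal(switching_rate(0, 0.0167, 0.1), 0.1)
  expect_equal(switching_rate(6, 0.0167, 0.1), 0.2002)
  # stationary occupancy kon*C/lambda equals C/(C+Kd) when Kd = koff/kon
  kon <- 0.1 / 6
  expect_equal(kon * 4 / switching_rate(4, kon, 0.1),
               receptor_occupancy(4, 6))
  expect_equal(signif(kon_from_koff_kd(0.1, 6), 3), 1.67e7)
  expect_equal(kon_from_koff_kd(0, 6), 0)
  # round trip back to Kd (nM)
  kon_molar <- kon_from_koff_kd(0.25, 8)
  expect_equal(0.25 / (kon_molar / 1e9), 8)
})

test_that("encounter-time estimate scales as expected", {
  base <- tau_dif_estimate(2.5, 375, 0.002, 0.01)
  expect_equal(tau_dif_estimate(2.5, 375, 0.004, 0.01), base / 2)
  # quadrupling L at fixed N_R, D_G and delta/r* ratio scales by 16
  delta1 <- sqrt(4 * pi * 2.5^2 / 375)
  delta2 <- sqrt(4 * pi * 10^2 / 375)
  r2 <- 0.01 * delta2 / delta1
  expect_equal(tau_dif_estimate(10, 375, 0.002, r2), 16 * base)
  expect_error(tau_dif_estimate(2.5, 375, 0.002, 0.5), "regime")
})

test_that("weak-signal bound has the closed-form landmarks", {
  expect_equal(weak_signal_bound(375, 0.33, 6, 6), 24 / (375 * 0.33^2))
  expect_equal(signif(weak_signal_bound(375, 0.33, 6, 6), 4), 0.5877)
  # minimized over C0 at C0 = Kd
  grid <- c(1, 2, 4, 6, 9, 18, 36)
  vals <- vapply(grid, function(c0) weak_signal_bound(375, 0.33, c0, 6),
                 numeric(1))
  expect_equal(grid[which.min(vals)], 6)
})

test_that("Fisher bound is rotation equivariant and scales as 1/N_R", {
  set.seed(5)
  g <- gradient_spec(C0 = 6, b = 0.33, theta = c(1, 0, 0), L = 2.5)
  pos <- sample_uniform_sphere(500, 2.5)
  fb <- fisher_information(pos, g, 6)
  expect_true(all(eigen(fb$info_matrix)$values > 0))

  R <- rotation_matrix(c(1, 1, 2), 1.1)
  g_rot <- gradient_spec(C0 = 6, b = 0.33, theta = as.numeric(R %*% g$theta),
                         L = 2.5)
  fb_rot <- fisher_information(pos %*% t(R), g_rot, 6)
  expect_equal(fb_rot$bound, fb$bound, tolerance = 1e-9)

  # four-fold receptor count quarters the bound (averaged over placements)
  b1 <- mean(replicate(40, fisher_information(
    sample_uniform_sphere(500, 2.5), g, 6)$bound))
  b4 <- mean(replicate(40, fisher_information(
    sample_uniform_sphere(2000, 2.5), g, 6)$bound))
  expect_lt(abs(b4 / b1 - 0.25), 0.03)

  # degenerate placement: all receptors on the gradient axis
  pole <- rbind(c(2.5, 0, 0), c(2.5, 0, 0), c(-2.5, 0, 0))
  expect_error(fisher_information(pole, g, 6), "singular")
})

test_that("collective variance has the right limits and monotonicity", {
  expect_equal(collective_variance(0.3, 1, 0.2, 5), 0.3 * 0.7)
  expect_equal(collective_variance(0.5, 4, 0.2, 1e9), 0.25 / 4,
               tolerance = 1e-6)
  expect_equal(collective_variance(0.5, 2, 0.2, 5), 0.1875)
  # decreasing in lambda * tau_dif and in n
  lt <- c(0.1, 1, 10, 100)
  v <- collective_variance(0.5, 10, 1, lt)
  expect_true(all(diff(v) < 0))
  vn <- vapply(1:6, function(n) collective_variance(0.5, n, 1, 1),
               numeric(1))
  expect_true(all(diff(vn) < 0))
})

test_that("classical bias formula flattens the occupancy profile", {
  expect_equal(classical_bias(0.5, 2), 0.5)
  expect_equal(classical_bias(0, 5), 0)
  expect_equal(classical_bias(0.2, 0), 0)
  spread_g <- classical_bias(0.75, 2) - classical_bias(0.14, 2)
  expect_lt(spread_g, 0.75 - 0.14)
})
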