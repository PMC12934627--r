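test_that("exact chain reproduces closed-form landmarks", {
  # n = 1: the single G protein mirrors the receptor, variance p(1-p)
  ex1 <- exact_reduced_stationary(1, 0.3, 0.2, 5, "ratiometric")
  expect_equal(ex1$mean, 0.3, tolerance = 1e-12)
  expect_equal(ex1$variance, 0.21, tolerance = 1e-12)
  # n = 2, p = 0.5, lambda*tau = 1
  ex2 <- exact_reduced_stationary(2, 0.5, 0.2, 5, "ratiometric")
  expect_equal(ex2$variance, 0.1875, tolerance = 1e-10)
  # classical with the receptor pinned bound: birth-death stationary mean
  EN <- mean_encounters(1 / 0.05, 8)
  exc <- exact_reduced_stationary(4, 1, 0.2, 8, "classical", k_gi = 0.05)
  expect_equal(exc$mean, EN / (1 + EN), tolerance = 1e-10)
})

test_that("mean encounters per reset behaves in its limits", {
  expect_equal(mean_encounters(5, 5), 1)
  expect_equal(mean_encounters(10, 5), 2)
  # k_gi -> infinity: no encounters survive a reset, bias collapses to zero
  expect_lt(classical_bias(0.75, mean_encounters(1e-9, 5)), 1e-9)
})

test_that("ratiometric reduced model is unbiased with Eq-consistent variance", {
  cfg <- reduced_config(n = 10, C = 6, tau_dif = 5, t_end = 8000, seed = 9)
  tr <- simulate_reduced(cfg)
  expect_true(all(abs(tr$A_n * tr$n - round(tr$A_n * tr$n)) < 1e-9))
  mo <- reduced_moments(tr, burn_in = 100)
  expect_lt(abs(mo$mean - 0.5), 4 * mo$se_mean)
  v_form <- collective_variance(0.5, 10, 0.2, 5)
  expect_lt(abs(mo$variance - v_form), 4 * mo$se_variance)
})

test_that("variance falls as samples decorrelate or collectives grow", {
  # simulation: lambda*tau_dif = 0.25 vs 4 at n = 10
  lo <- reduced_moments(simulate_reduced(
    reduced_config(n = 10, tau_dif = 1.25, t_end = 6000, seed = 10)), 50)
  hi <- reduced_moments(simulate_reduced(
    reduced_config(n = 10, tau_dif = 20, t_end = 6000, seed = 11)), 50)
  se <- sqrt(lo$se_variance^2 + hi$se_variance^2)
  expect_gt(lo$variance - hi$variance, 4 * se)
  # exact chain: decreasing in n at fixed lambda*tau_dif
  vn <- vapply(1:5, function(n)
    exact_reduced_stationary(n, 0.5, 0.2, 5, "ratiometric")$variance,
    numeric(1))
  expect_true(all(diff(vn) < 0))
})

test_that("classical stationary mean follows the dose-response bias", {
  # in the decorrelated-encounter regime the bias formula
  # p_R E[N] / (1 + p_R E[N]) holds to ~10%; tau_dif = 60 s puts the
  # slowest-switching position (C = 1 nM) at lambda*tau_dif = 7
  tau <- 60
  for (C in c(1, 6, 18)) for (EN in c(0.5, 1, 2, 4)) {
    p <- receptor_occupancy(C, 6)
    lam <- switching_rate(C, 0.1 / 6, 0.1)
    ex <- exact_reduced_stationary(4, p, lam, tau, "classical",
                                   k_gi = 1 / (EN * tau))
    expect_lt(abs(ex$mean / classical_bias(p, EN) - 1), 0.10)
  }
  # and the event-driven simulation agrees with the bias formula
  for (C in c(1, 18)) for (EN in c(0.5, 2)) {
    p <- receptor_occupancy(C, 6)
    cfg <- reduced_config(n = 8, C = C, tau_dif = tau, mode = "classical",
                          k_gi = 1 / (EN * tau), t_end = 40000,
                          seed = 1000 + round(C * 10 + EN * 100))
    mo <- reduced_moments(simulate_reduced(cfg), burn_in = 500)
    target <- classical_bias(p, EN)
    expect_lt(abs(mo$mean - target), 0.10 * target + 4 * mo$se_mean)
  }
})

test_that("tuning k_gi at mid-gradient cannot fix front and back", {
  # choose k_gi so the classical chain matches p_R = 0.5 at C = 6 nM
  tau <- 60
  lam_mid <- switching_rate(6, 0.1 / 6, 0.1)
  f <- function(kgi) exact_reduced_stationary(
    6, 0.5, lam_mid, tau, "classical", k_gi = kgi)$mean - 0.5
  kgi <- uniroot(f, c(1e-4, 1))$root
  for (C in c(1, 18)) {
    p <- receptor_occupancy(C, 6)
    lam <- switching_rate(C, 0.1 / 6, 0.1)
    exc <- exact_reduced_stationary(6, p, lam, tau, "classical",
                                    k_gi = kgi)
    exr <- exact_reduced_stationary(6, p, lam, tau, "ratiometric")
    expect_equal(exr$mean, p, tolerance = 1e-10)   # ratiometric unbiased
    expect_gt(abs(exc$mean - p), 0.02)             # classical deviates
  }
})
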