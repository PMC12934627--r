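test_that("kinetic parameters enforce Kd = koff/kon", {
  k <- kinetic_params(koff = 0.1, Kd = 6)
  expect_equal(k$kon, 0.1 / 6)
  expect_error(kinetic_params(kon = 0.02, koff = 0.1, Kd = 6),
               "inconsistent")
  k2 <- kinetic_params(kon = 0.1 / 6, koff = 0.1, Kd = 6)
  expect_equal(k2$Kd, 6)
})

test_that("config validation catches unusable settings", {
  expect_error(sim_config(mode = "classical"), "k_gi")
  expect_error(sim_config(dt = 2), "dt")   # koff * dt > 0.2
  k_fast <- kinetic_params(D_G = 0.05)
  expect_error(sim_config(kinetics = k_fast, dt = 0.02), "r_star")
  cfg <- sim_config()
  expect_gt(cfg$burn_in, 0)
  expect_lt(cfg$kinetics$kon * 7.98 * cfg$dt, 0.2)
})

test_that("state initialization matches equilibrium occupancy", {
  cfg0 <- sim_config(N_R = 0, N_G = 10, t_end = 1, burn_in = 0)
  st0 <- initialize_state(cfg0)
  expect_length(st0$receptor_active, 0)

  cfg <- sim_config(N_R = 6000, N_G = 10, t_end = 1, burn_in = 0, seed = 2)
  set.seed(cfg$seed); s1 <- initialize_state(cfg)
  set.seed(cfg$seed); s2 <- initialize_state(cfg)
  expect_identical(s1, s2)

  pbar <- mean_occupancy_sphere(6, 0.33, 6)
  se <- sqrt(0.25 / 6000)
  expect_lt(abs(mean(s1$receptor_active) - pbar), 4 * se)
  expect_lt(abs(mean(s1$g_active) - 0.5), 4 * sqrt(0.25 / 10000))
})

test_that("receptor telegraph dynamics reach the occupancy curve", {
  # koff = 0 makes the bound state absorbing
  g <- gradient_spec(C0 = 6, b = 0)
  k_abs <- kinetic_params(kon = 0.1 / 6, koff = 0, Kd = 0)
  pos <- sample_uniform_sphere(20, 2.5)
  st <- membrane_state(pos, rep(1L, 20), pos[0, , drop = FALSE], integer(0))
  for (i in 1:50) st <- step_receptors(st, g, k_abs, 0.05)
  expect_identical(st$receptor_active, rep(1L, 20))

  # long-run occupancy at C = 1 nM approaches 1/7 ~ 0.14
  set.seed(21)
  g1 <- gradient_spec(C0 = 1, b = 0)
  kk <- kinetic_params()
  pos <- sample_uniform_sphere(200, 2.5)
  p <- receptor_occupancy(1, 6)
  st <- membrane_state(pos, as.integer(runif(200) < p),
                       pos[0, , drop = FALSE], integer(0))
  occ <- 0; nsteps <- 4000; dt <- 0.05
  for (i in seq_len(nsteps)) {
    st <- step_receptors(st, g1, kk, dt)
    occ <- occ + mean(st$receptor_active)
  }
  occ <- occ / nsteps
  lam <- switching_rate(1, kk$kon, kk$koff)
  n_eff <- 200 * (nsteps * dt) / (2 / lam)    # independent samples
  expect_lt(abs(occ - p), 4 * sqrt(p * (1 - p) / n_eff))
})

test_that("per-receptor occupancy is consistent with the equilibrium curve", {
  # z-scores of per-receptor time-averaged occupancy against C/(C+Kd)
  set.seed(31)
  g <- gradient_spec()
  kk <- kinetic_params()
  n <- 150
  pos <- sample_uniform_sphere(n, 2.5)
  p <- receptor_occupancy(ligand_concentration(pos, g), 6)
  st <- membrane_state(pos, as.integer(runif(n) < p),
                       pos[0, , drop = FALSE], integer(0))
  nsteps <- 4000; dt <- 0.05
  acc <- numeric(n)
  for (i in seq_len(nsteps)) {
    st <- step_receptors(st, g, kk, dt)
    acc <- acc + st$receptor_active
  }
  emp <- acc / nsteps
  lam <- switching_rate(ligand_concentration(pos, g), kk$kon, kk$koff)
  n_eff <- (nsteps * dt) / (2 / lam)
  z <- (emp - p) / sqrt(p * (1 - p) / n_eff)
  expect_lt(abs(mean(z)), 4 / sqrt(n))
  expect_lt(abs(var(z) - 1), 0.5)
})

test_that("encounter pairing matches the all-pairs brute force", {
  set.seed(41)
  L <- 2.5
  rpos <- sample_uniform_sphere(50, L)
  gpos <- sample_uniform_sphere(50, L)
  st <- membrane_state(rpos, rep(0L, 50), gpos, rep(0L, 50))
  for (rs in c(0.05, 0.3, 1.0)) {
    expect_identical(find_encounters(st, rs),
                     brute_force_encounters(rpos, gpos, rs, L))
  }
  # a G protein exactly at a receptor's position pairs with it
  gpos2 <- rpos[7, , drop = FALSE]
  attr(gpos2, "L") <- L
  st2 <- membrane_state(rpos, rep(0L, 50), gpos2, 0L)
  expect_identical(find_encounters(st2, 0.01), 7L)
  # no receptor in range -> NA
  st3 <- membrane_state(rpos[1, , drop = FALSE], 0L,
                        -rpos[1, , drop = FALSE], 0L)
  expect_identical(find_encounters(st3, 0.01), NA_integer_)
})

test_that("equidistant encounters break ties to the lowest receptor index", {
  L <- 2
  phi <- 0.01
  rpos <- rbind(c(cos(phi), sin(phi), 0), c(cos(phi), -sin(phi), 0)) * L
  gpos <- matrix(c(L, 0, 0), 1)
  attr(gpos, "L") <- L
  st <- membrane_state(rpos, c(0L, 0L), gpos, 0L)
  expect_identical(find_encounters(st, 0.1), 1L)
  # reversing receptor order flips the winner
  st_rev <- membrane_state(rpos[2:1, ], c(0L, 0L), gpos, 0L)
  expect_identical(find_encounters(st_rev, 0.1), 1L)
})

test_that("ratiometric rule copies receptor state; states persist otherwise", {
  set.seed(51)
  L <- 2.5
  rpos <- sample_uniform_sphere(20, L)
  gpos <- sample_uniform_sphere(30, L)
  st <- membrane_state(rpos, rep(1L, 20), gpos, rep(0L, 30))
  pairing <- find_encounters(st, 3)          # everyone paired (r* huge)
  expect_true(all(!is.na(pairing)))
  st2 <- update_g_ratiometric(st, pairing)
  expect_identical(st2$g_active, rep(1L, 30))
  # no pairings: unchanged
  st3 <- update_g_ratiometric(st, rep(NA_integer_, 30))
  expect_identical(st3$g_active, st$g_active)
})

test_that("classical rule decays uniformly and activates on bound contact", {
  set.seed(52)
  L <- 2.5
  rpos <- sample_uniform_sphere(20, L)
  gpos <- sample_uniform_sphere(200, L)
  st <- membrane_state(rpos, rep(0L, 20), gpos, rep(1L, 200))
  # no pairings, k_gi * dt huge -> essentially all decay
  st2 <- update_g_classical(st, rep(NA_integer_, 200), k_gi = 200, dt = 1)
  expect_true(mean(st2$g_active) < 0.05)
  # all receptors inactive: active count can only decrease
  pairing <- find_encounters(st, 3)
  st3 <- update_g_classical(st, pairing, k_gi = 0.01, dt = 0.05)
  expect_lte(sum(st3$g_active), sum(st$g_active))
  # bound receptor contact wins over decay within the step
  st$receptor_active <- rep(1L, 20)
  st4 <- update_g_classical(st, pairing, k_gi = 200, dt = 1)
  expect_identical(st4$g_active[!is.na(pairing)],
                   rep(1L, sum(!is.na(pairing))))
})
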