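test_that("resultant vectors equal the brute-force sum", {
  set.seed(1)
  pts <- sample_uniform_sphere(40, 2.5)
  act <- as.integer(runif(40) < 0.4)
  for (sel in c("active", "inactive")) {
    expect_equal(resultant_vector(pts, act, sel),
                 brute_force_resultant(pts, act, sel))
  }
  expect_equal(resultant_vector(pts, rep(0L, 40), "active"), c(0, 0, 0))
  # two active particles at +-x cancel
  two <- rbind(c(1, 0, 0), c(-1, 0, 0))
  expect_equal(resultant_vector(two, c(1L, 1L), "active"), c(0, 0, 0))
})

test_that("combined vector is the bound-minus-unbound difference", {
  expect_equal(combined_vector(c(1, 2, 3), c(0, 0, 0)), c(1, 2, 3))
  expect_equal(combined_vector(c(1, 2, 3), c(1, 2, 3)), c(0, 0, 0))
  set.seed(2)
  pts <- sample_uniform_sphere(30, 1)
  all_on <- rep(1L, 30)
  vrl <- resultant_vector(pts, all_on, "active")
  vr <- resultant_vector(pts, all_on, "inactive")
  expect_equal(combined_vector(vrl, vr), vrl)  # no inactive receptors
})

test_that("angular error spans [0, 180] with the expected landmarks", {
  th <- c(0, 0, 1)
  expect_equal(angular_error(th, th), 0)
  expect_equal(angular_error(-th, th), 180)
  expect_equal(angular_error(c(1, 0, 0), th), 90)
  expect_error(angular_error(c(0, 0, 0), th), "zero")
  # vectorized over rows
  errs <- angular_error(rbind(th, -th, c(0, 1, 0)), th)
  expect_equal(errs, c(0, 180, 90))
})

test_that("angular-error ECDF matches the uniform-direction reference", {
  expect_equal(uniform_angular_cdf(0), 0)
  expect_equal(uniform_angular_cdf(90), 0.5)
  expect_equal(uniform_angular_cdf(180), 1)
  F1 <- empirical_cdf(rep(0, 5))
  expect_equal(F1(0), 1)
  F2 <- empirical_cdf(90)
  expect_equal(F2(89.9), 0)
  expect_equal(F2(90), 1)

  set.seed(3)
  n <- 5000
  dirs <- sample_uniform_sphere(n, 1)
  errs <- angular_error(dirs, c(0, 0, 1))
  Fhat <- empirical_cdf(errs)
  grid <- seq(0, 180, by = 1)
  dkw <- sqrt(log(2 / 0.001) / (2 * n))
  expect_lt(max(abs(Fhat(grid) - uniform_angular_cdf(grid))), dkw)
})

test_that("NSR converges to the isotropic-Gaussian closed form", {
  expect_equal(noise_to_signal(matrix(rep(c(1, 2, 3), 10), 10, 3,
                                      byrow = TRUE)), 0)
  set.seed(4)
  mu <- c(2, 1, 0); sigma <- 0.5
  n <- 20000
  samp <- matrix(rnorm(3 * n, sd = sigma), n, 3) +
    matrix(mu, n, 3, byrow = TRUE)
  target <- 3 * sigma^2 / sum(mu^2)
  expect_lt(abs(noise_to_signal(samp) / target - 1), 0.05)
  # reflection through the sample mean leaves the NSR unchanged
  m <- colMeans(samp)
  mirrored <- 2 * matrix(m, n, 3, byrow = TRUE) - samp
  expect_equal(noise_to_signal(mirrored), noise_to_signal(samp))
  expect_error(noise_to_signal(rbind(c(1, 0, 0), c(-1, 0, 0))), "zero mean")
})

test_that("direction stats bundle and serialize the accuracy metrics", {
  set.seed(6)
  theta <- c(0, 0, 1)
  samp <- matrix(rnorm(3 * 50, sd = 0.3), 50, 3) +
    matrix(theta, 50, 3, byrow = TRUE)
  ds <- direction_stats(samp, theta)
  expect_equal(ds$n_samples, 50)
  expect_equal(ds$nsr, noise_to_signal(samp))
  expect_equal(ds$cdf(180), 1)
  base <- tempfile()
  paths <- write_direction_stats(ds, base)
  js <- jsonlite::read_json(paste0(base, ".json"))
  expect_equal(js$nsr, ds$nsr)
  cdf <- read.csv(paste0(base, "_cdf.csv"))
  expect_true(all(diff(cdf$cdf) >= 0))
  expect_equal(nrow(read.csv(paste0(base, "_errors.csv"))), 50)
  unlink(paths)
})

test_that("adaptation time is the first sub-90-degree crossing", {
  new_theta <- c(1, 0, 0)
  tt <- seq(0, 100, by = 0.5)
  # trace already aligned at the flip
  aligned <- matrix(new_theta, length(tt), 3, byrow = TRUE)
  expect_equal(time_to_adapt(tt, aligned, 10, new_theta), 0.5)
  # stuck at 180 degrees forever
  stuck <- matrix(-new_theta, length(tt), 3, byrow = TRUE)
  expect_true(is.na(time_to_adapt(tt, stuck, 10, new_theta)))
  # constant rotation at omega deg/s from 180 degrees: crossing at 90/omega
  omega <- 2
  ang <- pmax(180 - omega * pmax(tt - 10, 0), 0) * pi / 180
  rot <- cbind(cos(ang), sin(ang), 0)
  expect_equal(time_to_adapt(tt, rot, 10, new_theta), 45.5,
               tolerance = 0.5 / 45)
})
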