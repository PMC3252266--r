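test_that("shift operator moves derivative blocks up and is nilpotent", {
  expect_equal(shift_operator(1, 3), matrix(0, 3, 3))
  D2 <- shift_operator(2, 1)
  expect_equal(drop(D2 %*% c(1.5, -4)), c(-4, 0))
  D4 <- shift_operator(4, 2)
  D4_3 <- D4 %*% D4 %*% D4
  expect_gt(max(abs(D4_3)), 0)
  expect_equal(D4_3 %*% D4, matrix(0, 8, 8))
  expect_error(shift_operator(0, 2), "order")
  expect_error(shift_operator(2, 0), "dim")
})

test_that("derivative autocorrelation matches analytic Gaussian moments", {
  s <- 0.5
  # Cov of (z, z', z'') for rho(t) = exp(-t^2 / (2 s^2)):
  # rho''(0) = -1/s^2, rho''''(0) = 3/s^4, built here by hand
  S_expected <- matrix(c(1, 0, -1 / s^2,
                         0, 1 / s^2, 0,
                         -1 / s^2, 0, 3 / s^4), 3, 3)
  expect_equal(deriv_autocorr(3, s), S_expected)
  expect_equal(generalized_precision(0, 3, s), solve(S_expected),
               tolerance = 1e-12)
})

test_that("generalized precision extends the base precision across orders", {
  expect_equal(generalized_precision(0, 1, 0.7), matrix(1, 1, 1))
  expect_equal(generalized_precision(16, 1, 2), matrix(exp(16), 1, 1))
  for (ord in c(2, 4, 8)) {
    for (s in c(0.1, 0.5, 2, 8)) {
      P <- generalized_precision(1.5, ord, s, dim = 2)
      expect_equal(P, t(P))
      ev <- eigen(P, symmetric = TRUE, only.values = TRUE)$values
      # positive definite; the smallest eigenvalue (precision of the
      # highest derivative under rough noise) underflows toward zero for
      # order 8 at smoothness 0.1, so positivity is asserted to within
      # eigensolver round-off there
      if (ord <= 6) expect_gt(min(ev), 0)
      expect_gt(min(ev), -1e-9 * max(ev))
    }
  }
  expect_error(generalized_precision(0, 2, -1), "smoothness")
})

test_that("smooth noise has the stated variance and Gaussian autocorrelation", {
  z <- sample_smooth_noise(8192, 1, 4, 2, seed = 1, n_orders = 2)
  expect_equal(var(z[, 1, 1]) / exp(-4), 1, tolerance = 0.2)
  ac <- drop(acf(z[, 1, 1], lag.max = 4, plot = FALSE)$acf)
  expect_lt(max(abs(ac - exp(-(0:4)^2 / (2 * 4)))), 0.05)
  # derivative block describes the motion of the order-0 path
  expect_gt(cor(diff(z[, 1, 1]), z[-1, 1, 2]), 0.85)
})

test_that("smooth noise is reproducible and scales with log precision", {
  a <- sample_smooth_noise(256, 3, 8, 0.5, seed = 42, n_orders = 2)
  b <- sample_smooth_noise(256, 3, 8, 0.5, seed = 42, n_orders = 2)
  expect_identical(a, b)
  lo <- sample_smooth_noise(10000, 1, 2, 1, seed = 7)
  hi <- sample_smooth_noise(10000, 1, 6, 1, seed = 7)
  expect_equal(sd(hi) / sd(lo), exp(-2), tolerance = 0.05)
})
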