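em <- embedding()

test_that("prediction errors vanish for self-consistent static expectations", {
  m <- make_linear_gaussian_model(2, 1, seed = 5)
  mu <- rep(0, 14)
  s0 <- list(y = matrix(0, 2, 2))
  errs <- prediction_errors(m, mu, s0, em)
  for (g in errs) expect_equal(max(abs(g$eps)), 0)
  expect_equal(free_energy_gradient(m, mu, s0, em), rep(0, 14))
  # a fixed point of the filtering scheme
  st <- filtering_step(m, mu, s0, em)
  expect_lt(max(abs(st$mu)), 1e-6)
})

test_that("precision weighting is exact and errors scale linearly", {
  m <- build_reaching_model()
  ctx <- affsim:::engine_context(m, em)
  set.seed(11)
  mu <- rnorm(ctx$layout$p, sd = 0.3)
  s <- random_sensory(11)
  es <- affsim:::error_system(ctx, m, mu, s, 0)
  for (nm in names(es$groups)) {
    g <- es$groups[[nm]]
    expect_equal(g$xi, drop(ctx$prec[[nm]] %*% g$eps))
  }
  # shifting one stream's log precision scales xi by exp(delta), eps unchanged
  m2 <- apply_lesion(m, lesion("salience_sensory", 4 - 2))
  ctx2 <- affsim:::engine_context(m2, em)
  es2 <- affsim:::error_system(ctx2, m2, mu, s, 0)
  expect_equal(es2$groups$s_salience$eps, es$groups$s_salience$eps)
  expect_equal(es2$groups$s_salience$xi,
               es$groups$s_salience$xi * exp(-2))
})

test_that("free energy is the half sum of precision-weighted squares", {
  m <- build_reaching_model()
  ctx <- affsim:::engine_context(m, em)
  set.seed(12)
  mu <- rnorm(ctx$layout$p, sd = 0.2)
  s <- random_sensory(12)
  es <- affsim:::error_system(ctx, m, mu, s, 0)
  by_hand <- 0
  for (g in es$groups) {
    acc <- 0
    for (i in seq_along(g$eps)) acc <- acc + g$xi[i] * g$eps[i]
    by_hand <- by_hand + acc / 2
  }
  expect_equal(es$F_quad, by_hand)
  expect_gte(es$F_quad, 0)
})

test_that("the analytic free-energy gradient matches finite differences", {
  m <- build_reaching_model()
  p <- length(mu_init(m, em))
  set.seed(20)
  worst <- 0
  for (rep in 1:20) {
    mu <- rnorm(p, sd = 0.4)
    s <- random_sensory(100 + rep)
    g <- free_energy_gradient(m, mu, s, em)
    gfd <- fd_grad(function(u) free_energy(m, u, s, em), mu)
    worst <- max(worst, max(abs(g - gfd)) / max(abs(gfd)))
  }
  expect_lt(worst, 1e-4)
})

test_that("free energy is non-increasing under static descent", {
  m <- build_reaching_model()
  wp <- world_params()
  s <- sense(c(0, 0, 1.2, 0.02, 0.02, 0.02), c(0, 0), rep(0, 4), wp)
  mu <- rep(0, length(mu_init(m, em)))
  Fs <- numeric(30)
  for (it in 1:30) {
    st <- filtering_step(m, mu, s, em, substeps = 2, static = TRUE)
    mu <- st$mu
    Fs[it] <- st$free_energy
  }
  expect_true(all(diff(Fs[-1]) <= 1e-8))
})

test_that("generalized filtering agrees with the Kalman filter on the linear fixture", {
  skip_if_not_installed("Matrix")
  m <- make_linear_gaussian_model(2, 1, seed = 3)
  v_fun <- function(t) sin(2 * pi * t / 32)
  m$top_prior <- list(
    mean = function(t) cbind(v_fun(t), 2 * pi / 32 * cos(2 * pi * t / 32)),
    log_prec = 12)
  sim <- simulate_linear_gaussian(m, 160, v_fun, seed = 11)
  gf <- run_generalized_filter(m, sim$y, em, substeps = 2)
  kf <- kalman_filter(m, sim$y, v_fun)
  burn <- 21:160
  rel <- sqrt(mean((gf$mu[burn, 1:2] - kf[burn, ])^2)) /
    sqrt(mean(kf[burn, ]^2))
  expect_lt(rel, 0.05)
})

test_that("the fixed-step Runge-Kutta cross-check reproduces local linearization", {
  # a mild-precision linear model keeps the fixed-step solver in its
  # stability region; the nominal reaching precisions require the
  # exponential integrator
  m <- make_linear_gaussian_model(2, 1, seed = 9, log_prec_obs = 1,
                                  log_prec_state = 1, log_prec_cause = 1)
  sim <- simulate_linear_gaussian(m, 30, function(t) 0, seed = 2)
  ll <- run_generalized_filter(m, sim$y, em, substeps = 4, solver = "ll")
  rk <- run_generalized_filter(m, sim$y, em, substeps = 8, solver = "rk4")
  expect_equal(rk$mu[30, 1:2], ll$mu[30, 1:2], tolerance = 0.02)
})

test_that("action descends proprioceptive prediction errors", {
  m <- build_reaching_model()
  wp <- world_params()
  wstate <- rep(0, 6)
  # perfectly predicted static input: no action change
  s <- sense(wstate, c(0, 0), rep(0, 4), wp)
  mu <- rep(0, length(mu_init(m, em)))
  # zero all sensory errors by feeding the model's own predictions
  s0 <- list(proprio = matrix(0, 2, 2), visual = matrix(0, 2, 2),
             salience = cbind(rep(1, 4), rep(0, 4)))
  a1 <- action_update(m, mu, s0, wstate, c(0, 0), em, wp)
  expect_equal(a1, c(0, 0))
  # arm sensed as moving slower than predicted -> action increases
  mu2 <- mu
  lay <- affsim:::mu_layout(m, em)
  mu2[lay$levels[[1]]$x[7]] <- 0.5   # predicted vertical arm velocity
  s_lag <- s0
  a2 <- action_update(m, mu2, s_lag, wstate, c(0, 0), em, wp)
  expect_gt(a2[1], 0)
  expect_equal(a2[2], 0)
})

test_that("the sensory sensitivity to action matches finite differences", {
  wp <- world_params()
  ws <- c(0.1, -0.2, 0.5, 0, 0, 0)
  a <- c(0.05, -0.1)
  sa <- affsim:::sensory_action_jac(ws, a, wp)
  for (j in 1:2) {
    da <- 1e-6
    ap <- a; ap[j] <- ap[j] + da
    am <- a; am[j] <- am[j] - da
    fd <- (unlist(sense(ws, ap, rep(0, 4), wp)) -
           unlist(sense(ws, am, rep(0, 4), wp))) / (2 * da)
    expect_equal(unname(unlist(lapply(sa, function(S) S[, j]))), unname(fd),
                 tolerance = 1e-6)
  }
})

test_that("simulation traces are reproducible bit for bit", {
  cfg <- sim_config(seed = 3, n_bins = 30, store_cov = FALSE)
  t1 <- run_active_inference(config = cfg)
  t2 <- run_active_inference(config = cfg)
  expect_identical(t1$mu, t2$mu)
  expect_identical(t1$world, t2$world)
  expect_identical(t1$action, t2$action)
  t3 <- run_active_inference(config = sim_config(seed = 4, n_bins = 30,
                                                 store_cov = FALSE))
  expect_false(identical(t1$world, t3$world))
})
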