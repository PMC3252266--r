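test_that("cue causes are Gaussian bumps at the scheduled onsets", {
  sched <- make_schedule("paper_default")
  expect_equal(sched$onsets, seq(0, 108, by = 12))
  expect_equal(sched$n_cues, 10L)
  # peak amplitude at the bump centre of a non-overlapping cue
  peak <- cue_causes(sched$onsets[3] + sched$peak_lag, sched)
  expect_equal(peak[sched$order[3]], sched$amplitude, tolerance = 1e-6)
  # negligible between well-separated bumps
  narrow <- cue_schedule(c(1, 2, 3), interval = 12, width = 1, peak_lag = 0)
  mid <- cue_causes(6, narrow)
  expect_true(all(mid < narrow$amplitude * exp(-18) * 1.001))
  expect_true(all(cue_causes(seq(0, 120, 0.5), sched) >= 0))
})

test_that("world flow has a resting fixed point and bounded arm drive", {
  wp <- world_params()
  expect_equal(world_flow(rep(0, 6), c(0, 0), rep(0, 4), wp), rep(0, 6))
  for (a in c(-50, -1, 2, 100))
    expect_lte(abs(world_flow(rep(0, 6), c(a, 0), rep(0, 4), wp)[1]), 1)
})

test_that("constant action settles at tau_arm * tanh(gain * a)", {
  wp <- world_params()
  a <- c(0.8, -0.4)
  st <- rep(0, 6)
  sched0 <- cue_schedule(1, amplitude = 0)
  for (t_ in 1:120)
    st <- affsim:::world_rk4(st, a, t_ - 1, sched0, wp, rep(0, 6), 8)
  expect_equal(st[1:2], wp$tau_arm * tanh(wp$action_gain * a),
               tolerance = 1e-3)
})

test_that("with no action the arm decays monotonically to rest", {
  wp <- world_params()
  st <- c(0.6, -0.4, 0, 0, 0, 0)
  sched0 <- cue_schedule(1, amplitude = 0)
  norms <- numeric(30)
  for (t_ in 1:30) {
    st <- affsim:::world_rk4(st, c(0, 0), t_ - 1, sched0, wp, rep(0, 6), 8)
    norms[t_] <- sqrt(sum(st[1:2]^2))
  }
  expect_true(all(diff(norms) < 0))
})

test_that("salience pulses die away before the next onset", {
  wp <- world_params()   # tau_sal = 2 <= interval / 4
  sched <- make_schedule("all_clockwise", width = 1, amplitude = 1)
  st <- rep(0, 6)
  traj <- matrix(0, 48, 4)
  for (t_ in 1:48) {
    st <- affsim:::world_rk4(st, c(0, 0), t_ - 1, sched, wp, rep(0, 6), 8)
    traj[t_, ] <- st[3:6]
  }
  # at each onset, the previous cue's channel is back below 1% of amplitude
  for (k in 2:4) {
    prev <- sched$order[k - 1]
    expect_lt(traj[sched$onsets[k] + 1, prev], 0.01 * sched$amplitude)
  }
})

test_that("the sensory map reports the tangent-map position with chain-rule motion", {
  wp <- world_params()
  s0 <- sense(rep(0, 6), c(0, 0), rep(0, 4), wp)
  expect_equal(s0$proprio[, 1], c(0, 0))
  expect_equal(s0$visual[, 1], c(0, 0))
  st <- c(pi / 4, pi / 4, 0.3, 0, 0, 0)
  s1 <- sense(st, c(0, 0), rep(0, 4), wp)
  expect_equal(s1$visual[, 1], c(1, 1))
  expect_equal(s1$salience[1, 1], 0.3)
  # order-1 block equals the analytic derivative of the observation
  da <- 1e-6
  st2 <- st + c(world_flow(st, c(0.2, -0.1), rep(0, 4), wp) * da)
  num <- (c(st2[1:2], tan(st2[1:2]), st2[3:6]) -
          c(st[1:2], tan(st[1:2]), st[3:6])) / da
  s2 <- sense(st, c(0.2, -0.1), rep(0, 4), wp)
  expect_equal(c(s2$proprio[, 2], s2$visual[, 2], s2$salience[, 2]), num,
               tolerance = 1e-4)
  expect_error(sense(c(1.6, 0, 0, 0, 0, 0), c(0, 0), rep(0, 4), wp),
               "domain")
})

test_that("sensor noise at log precision 16 has standard deviation exp(-8)", {
  wp <- world_params()
  z <- sample_smooth_noise(4096, 8, wp$noise_log_prec, wp$smoothness,
                           seed = 4, n_orders = 2)
  expect_equal(sd(z[, , 1]), exp(-8), tolerance = 0.2)
})
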