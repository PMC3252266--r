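L <- location_map()

test_that("reaction time reads the first capture-radius crossing", {
  sched <- cue_schedule(c(1, 2), interval = 12, amplitude = 1)
  # pointer starts on target 1, then moves to target 2 crossing its radius
  # at a known bin
  tr <- make_pointer_trace(list(c(1, 1), c(1, 1), c(1, -1), c(1, -1)),
                           bins_per_segment = 8L)
  rt <- reaction_time(tr, sched, radius = 0.25)
  expect_equal(rt[1], 0)           # already within radius at onset
  # segment 2 runs bins 8..16; radius 0.25 crossed 1/8 of ext distance
  # before the endpoint: position 2 - 2 * (b - 8) / 8 within 0.25 of -1
  # first integer bin with dist <= 0.25 is b = 15, i.e. 3 bins after onset 12
  expect_equal(rt[2], 3 * 64)
  expect_error(reaction_time(tr, sched, radius = -1), "radius")
})

test_that("a synthetic crossing five bins after onset gives 320 ms", {
  sched <- cue_schedule(c(1), interval = 12, amplitude = 1)
  path <- c(rep(2.5, 5), rep(1.1, 8))     # jumps within radius at bin 5
  tr <- make_pointer_trace(cbind(1, path), bins_per_segment = 1L)
  expect_equal(reaction_time(tr, sched, radius = 0.25)[1], 320)
})

test_that("accuracy is the bump-weighted inverse distance", {
  sched <- cue_schedule(c(1), interval = 12)
  parked <- make_pointer_trace(list(c(1, 1), c(1, 1), c(1, 1)),
                               bins_per_segment = 6L)
  expect_equal(accuracy(parked, sched, delta = 1e-2)[1], 100)
  d <- sqrt(2)  # constant distance: pointer parked at the origin
  origin <- make_pointer_trace(list(c(0, 0), c(0, 0), c(0, 0)),
                               bins_per_segment = 6L)
  expect_equal(accuracy(origin, sched, delta = 1e-2)[1], 1 / (d + 1e-2))
})

test_that("switch latency counts post-reversal cue windows to a sustained crossing", {
  sched <- make_schedule("paper_default")   # reversal at cue 6, onset 60
  # crossing begins during the 2nd post-reversal cue window and stays
  ctx <- c(rep(0.1, 75), rep(0.9, 53))
  expect_equal(switch_latency(context_trace(ctx), sched), 2L)
  # crossing that is never sustained
  ctx2 <- rep(0.1, 128)
  expect_true(is.na(switch_latency(context_trace(ctx2), sched)))
  # brief blips shorter than the sustain window do not count
  ctx3 <- rep(0.1, 128); ctx3[61:63] <- 0.9
  expect_true(is.na(switch_latency(context_trace(ctx3), sched)))
  # an all-clockwise schedule has nothing to switch to
  cw <- make_schedule("all_clockwise")
  expect_true(is.na(switch_latency(context_trace(ctx), cw)))
})

test_that("perseveration scores initial directions toward the clockwise-next target", {
  sched <- make_schedule("paper_default")
  # path that, after each post-reversal onset, first moves toward the
  # clockwise successor of the previous target
  pos <- matrix(0, 128, 2)
  for (k in 1:10) {
    o <- sched$onsets[k]
    prev <- if (k > 1) sched$order[k - 1] else sched$order[1]
    false_t <- prev %% 4L + 1L
    tgt <- L$ext[, sched$order[k]]
    start <- if (k > 1) L$ext[, prev] else c(0, 0)
    for (b in 0:11) {
      tt <- o + b + 1
      if (tt > 128) break
      pos[tt, ] <- if (k >= 6 && b < 4) {
        start + (b / 4) * 0.3 * (L$ext[, false_t] - start)
      } else {
        tgt
      }
    }
  }
  tr <- make_pointer_trace(pos, bins_per_segment = 1L)
  pers <- perseveration(tr, sched)
  expect_equal(pers$scorable, 4L)
  expect_equal(pers$count, 4L)
  # direct movement to the true target is not perseverative
  direct <- matrix(0, 128, 2)
  for (k in 1:10) {
    o <- sched$onsets[k]
    rows <- (o + 1):min(o + 12, 128)
    direct[rows, 1] <- L$ext[1, sched$order[k]]
    direct[rows, 2] <- L$ext[2, sched$order[k]]
  }
  tr2 <- make_pointer_trace(direct, bins_per_segment = 1L)
  pers2 <- perseveration(tr2, sched)
  expect_equal(pers2$count, 0L)
})

test_that("trial metrics bundle per-cue and run-level measures", {
  sched <- cue_schedule(c(1, 2), interval = 12, amplitude = 1)
  tr <- make_pointer_trace(list(c(1, 1), c(1, 1), c(1, -1), c(1, -1)),
                           bins_per_segment = 8L)
  tm <- trial_metrics(tr, sched, radius = 0.25)
  expect_equal(nrow(tm), 2L)
  expect_named(tm, c("trial", "target", "onset_bin", "rt_ms", "accuracy"))
  expect_s3_class(tm, "data.frame")
  expect_true(!is.null(attr(tm, "perseveration")))
})
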