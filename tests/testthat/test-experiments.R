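test_that("dopamine sweeps return a tidy per-trial table", {
  cfg <- sim_config(seed = 1, n_bins = 40, store_cov = FALSE)
  sched <- make_schedule("paper_default", n_cues = 3)
  tab <- dopamine_sweep("arm_state", 2, schedule = sched, config = cfg)
  expect_s3_class(tab, "data.frame")
  expect_equal(nrow(tab), 2 * 3)
  expect_true(all(c("site", "level", "log_prec", "trial", "rt_ms",
                    "accuracy", "switch_latency", "perseveration")
                  %in% names(tab)))
  expect_equal(unique(tab$log_prec), c(4, 2))
})

test_that("figure replication writes a deterministic plain-text archive", {
  cfg <- sim_config(seed = 5, n_bins = 40, store_cov = FALSE)
  sched <- make_schedule("paper_default", n_cues = 3)
  d1 <- tempfile("rep1_")
  d2 <- tempfile("rep2_")
  replicate_figure("fig5", out_dir = d1, config = cfg, schedule = sched)
  replicate_figure("fig5", out_dir = d2, config = cfg, schedule = sched)
  expect_true(file.exists(file.path(d1, "trial_metrics.csv")))
  expect_true(file.exists(file.path(d1, "meta.json")))
  expect_true(file.exists(file.path(d1, "trace_nominal", "world.csv")))
  for (f in c("trial_metrics.csv", file.path("trace_nominal", "world.csv"),
              file.path("trace_nominal", "mu.csv"))) {
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)))
  }
  unlink(c(d1, d2), recursive = TRUE)
})

test_that("run configuration files reproduce the constructor defaults", {
  cfgfile <- tempfile(fileext = ".yaml")
  writeLines(c(
    "model:",
    "  tau_reach: 2",
    "schedule:",
    "  preset: paper_default",
    "sim:",
    "  n_bins: 32",
    "  seed: 9",
    "lesions:",
    "  salience_sensory: 2.5"), cfgfile)
  rc <- load_run_config(cfgfile)
  expect_s3_class(rc$model, "af_model")
  expect_equal(rc$config$n_bins, 32L)
  expect_equal(rc$config$seed, 9L)
  expect_equal(unname(rc$lesions["salience_sensory"]), 2.5)
  lesioned <- apply_lesion(rc$model, rc$lesions)
  expect_equal(lesioned$streams$salience$log_prec, 2.5)
  unlink(cfgfile)
})
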