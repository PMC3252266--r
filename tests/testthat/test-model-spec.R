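test_that("the reaching model validates and broken models are diagnosed", {
  m <- build_reaching_model()
  expect_true(validate_model(m)$ok)

  bad <- m
  bad$levels[[2]]$obs <- function(x, v, p) c(softmax(x), 0)  # wrong dim
  d <- validate_model(bad)
  expect_false(d$ok)
  expect_match(paste(d$messages, collapse = " "), "dim_v")

  nan <- m
  nan$levels[[1]]$flow <- function(x, v, p) rep(NaN, 6)
  d2 <- validate_model(nan)
  expect_false(d2$ok)
  expect_match(paste(d2$messages, collapse = " "), "finite")
})

test_that("lesions replace log precisions and nothing else", {
  m <- build_reaching_model()
  expect_identical(apply_lesion(m, list()), m)

  l1 <- apply_lesion(m, lesion("salience_sensory", 2))
  expect_equal(l1$streams$salience$log_prec, 2)
  expect_equal(l1$streams$proprio$log_prec, 4)
  expect_equal(l1$streams$visual$log_prec, 4)
  expect_equal(l1$levels[[1]]$log_prec_state, c(arm = 4, affordance = 4))
  # everything except the lesioned number is structurally identical
  strip <- function(mm) {
    mm$streams$salience$log_prec <- NULL
    mm
  }
  expect_identical(strip(l1), strip(m))
  expect_identical(apply_lesion(l1, lesion("salience_sensory", 2)), l1)

  l2 <- apply_lesion(m, c(arm_state = 1.5, context_level = 3))
  expect_equal(l2$levels[[1]]$log_prec_state[["arm"]], 1.5)
  expect_equal(l2$levels[[2]]$log_prec_state[["context"]], 3)
  expect_equal(l2$levels[[2]]$log_prec_cause, 3)
  expect_error(apply_lesion(m, lesion("cerebellum", 2)), "unknown lesion site")
})

test_that("lesion sweeps span nominal to half nominal with even spacing", {
  sw <- lesion_sweep("salience_sensory", 6)
  lp <- vapply(sw, function(l) l$log_precision, 1)
  expect_equal(lp, c(4, 3.6, 3.2, 2.8, 2.4, 2))
  expect_equal(diff(lp), rep(diff(lp)[1], 5))
  two <- lesion_sweep("arm_state", 2, nominal = 6)
  expect_equal(vapply(two, `[[`, 1, "log_precision"), c(6, 3))
  expect_error(lesion_sweep("arm_state", 1), "n_levels")
})
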