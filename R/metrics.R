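# Behavioural metrics: per-cue reaction time and accuracy, the run-level
# set-switch latency and the perseveration count.

trace_extrinsic <- function(trace) {
  tan(trace$world[, 1:2, drop = FALSE])
}

trace_locations <- function(trace) {
  if (!is.null(trace$L)) return(trace$L)
  trace$model$levels[[1]]$params$L
}

#' Inferred context (softmax of the second-level states)
#'
#' The context the agent currently believes in: the softmax of the
#' conditional expectations of the second-level hidden states, i.e. the
#' predicted level-1 cause under the slow context cycle. Column 1 is the
#' sequential context, column 2 the random context. This is the slow,
#' evidence-integrating readout; the expectation of the level-1 cause
#' itself ([speed_cause()]) additionally carries the fast data-driven
#' deflections that drive the switch.
#'
#' @param trace An `af_trace` from [run_active_inference()].
#' @return A T x 2 matrix with rows on the simplex.
#' @export
context_cause <- function(trace) {
  x2cols <- trace$layout$levels[[2]]$x[1:2]
  t(apply(trace$mu[, x2cols, drop = FALSE], 1, softmax))
}

#' Expectation of the level-1 hidden cause (itinerance speed)
#'
#' Column 1 gates the speed of the affordance cycle (sequential context);
#' column 2 is its converse. Deflections of this cause below its prior
#' prediction are the prediction errors that drive set switching.
#'
#' @param trace An `af_trace`.
#' @return A T x 2 matrix.
#' @export
speed_cause <- function(trace) {
  cols <- trace$layout$levels[[1]]$v[1:2]
  trace$mu[, cols, drop = FALSE]
}

#' Default reaction-time radius
#'
#' One eighth of the inter-target extrinsic distance (the side of the target
#' square).
#'
#' @param L An [location_map()].
#' @return A scalar radius in extrinsic units.
#' @export
default_radius <- function(L = location_map()) {
  dd <- as.matrix(stats::dist(t(L$ext)))
  min(dd[dd > 0]) / 8
}

cue_windows <- function(trace, schedule) {
  T_ <- length(trace$time)
  onsets <- schedule$onsets + 1  # 1-based row index of the onset bin
  ends <- c(onsets[-1] - 1, min(T_, onsets[length(onsets)] + schedule$interval - 1))
  list(onsets = onsets, ends = pmin(ends, T_))
}

#' Per-cue reaction times
#'
#' For each cue, the time (ms) from cue onset to the first bin at which the
#' extrinsic pointing location falls within `radius` of the target; `NA` if
#' the target is not reached before the next onset.
#'
#' @param trace An `af_trace`.
#' @param schedule The [cue_schedule()] used (defaults to the one stored in
#'   the trace).
#' @param radius Extrinsic capture radius (> 0); default [default_radius()].
#' @return Numeric vector of length `n_cues` (ms; `NA` = never reached).
#' @export
reaction_time <- function(trace, schedule = trace$schedule,
                          radius = default_radius(trace_locations(trace))) {
  if (!is.finite(radius) || radius <= 0) stop("`radius` must be positive")
  L <- trace_locations(trace)
  ext <- trace_extrinsic(trace)
  win <- cue_windows(trace, schedule)
  out <- rep(NA_real_, schedule$n_cues)
  for (k in seq_len(schedule$n_cues)) {
    tgt <- L$ext[, schedule$order[k]]
    rows <- win$onsets[k]:win$ends[k]
    dd <- sqrt((ext[rows, 1] - tgt[1])^2 + (ext[rows, 2] - tgt[2])^2)
    hit <- which(dd <= radius)
    if (length(hit)) out[k] <- (hit[1] - 1) * trace$bin_ms
  }
  out
}

#' Per-cue pointing accuracy
#'
#' The salience-bump-weighted average of the inverse distance from the
#' pointing location to the target over each cue window:
#' `sum_t w(t) / (d(t) + delta) / sum_t w(t)`, with `w(t)` the cue's
#' Gaussian bump. Higher is better; the maximum `1 / delta` is attained by a
#' pointer parked on the target.
#'
#' @inheritParams reaction_time
#' @param delta Small guard added to the distance (extrinsic units).
#' @return Numeric vector of length `n_cues`.
#' @export
accuracy <- function(trace, schedule = trace$schedule, delta = 1e-2) {
  L <- trace_locations(trace)
  ext <- trace_extrinsic(trace)
  win <- cue_windows(trace, schedule)
  out <- rep(NA_real_, schedule$n_cues)
  for (k in seq_len(schedule$n_cues)) {
    tgt <- L$ext[, schedule$order[k]]
    rows <- win$onsets[k]:win$ends[k]
    tt <- rows - 1
    w <- schedule$amplitude *
      exp(-(tt - schedule$onsets[k])^2 / (2 * schedule$width^2))
    dd <- sqrt((ext[rows, 1] - tgt[1])^2 + (ext[rows, 2] - tgt[2])^2)
    out[k] <- sum(w / (dd + delta)) / sum(w)
  }
  out
}

reversal_index <- function(schedule) {
  ord <- schedule$order
  cw_next <- ord[-length(ord)] %% 4L + 1L
  viol <- which(ord[-1] != cw_next) + 1L
  if (length(viol)) viol[1] else NA_integer_
}

#' Set-switch latency
#'
#' The number of cue presentations after the first order-reversing cue until
#' the inferred random-context cause exceeds `threshold` for at least
#' `sustain` consecutive bins (half a cue interval by default): a crossing
#' sustained during the second post-reversal cue gives latency 2. `NA` if
#' the switch never happens (with a diagnostic attribute when the schedule
#' contains no reversal).
#'
#' @inheritParams reaction_time
#' @param threshold Confidence threshold on the random-context cause.
#' @param sustain Minimum number of consecutive supra-threshold bins.
#' @return Integer count, or `NA` if no sustained switch occurs.
#' @export
switch_latency <- function(trace, schedule = trace$schedule,
                           threshold = 0.5, sustain = 6L) {
  rev_k <- reversal_index(schedule)
  if (is.na(rev_k))
    return(structure(NA_integer_, no_reversal = TRUE))
  ctx <- context_cause(trace)[, 2]
  T_ <- length(ctx)
  onset <- schedule$onsets[rev_k] + 1
  above <- ctx > threshold
  start <- NA_integer_
  for (b in onset:(T_ - sustain + 1)) {
    if (all(above[b:(b + sustain - 1)])) { start <- b; break }
  }
  if (is.na(start)) return(NA_integer_)
  as.integer(floor((start - onset) / schedule$interval) + 1L)
}

#' Perseveration of initial movement directions after reversal
#'
#' For each scorable post-reversal cue, the initial movement direction (the
#' unit vector of extrinsic displacement over the first `bins` bins after
#' onset) is compared with the directions toward the falsely anticipated
#' target (the clockwise successor of the previous target) and the true
#' target; the trial counts as perseverative when it is closer to the false
#' one. Scorable trials are the post-reversal cues after the first reversed
#' cue (perseveration is the persistence of the old rule once the change is
#' observable) for which the false and true targets differ.
#'
#' @inheritParams reaction_time
#' @param bins Number of bins over which the initial displacement is taken.
#' @return `list(count =, scorable =, per_trial = named logical)`.
#' @export
perseveration <- function(trace, schedule = trace$schedule, bins = 3L) {
  rev_k <- reversal_index(schedule)
  if (is.na(rev_k) || rev_k + 1L > schedule$n_cues)
    return(list(count = 0L, scorable = 0L, per_trial = logical()))
  L <- trace_locations(trace)
  ext <- trace_extrinsic(trace)
  T_ <- nrow(ext)
  per <- logical(0)
  for (k in seq.int(rev_k + 1L, schedule$n_cues)) {
    prev <- schedule$order[k - 1]
    false_t <- prev %% 4L + 1L
    true_t <- schedule$order[k]
    o <- schedule$onsets[k] + 1
    if (false_t == true_t || o + bins > T_) next
    disp <- ext[o + bins, ] - ext[o, ]
    if (sqrt(sum(disp^2)) < 1e-9) {
      per[as.character(k)] <- FALSE
      next
    }
    u <- disp / sqrt(sum(disp^2))
    to_false <- L$ext[, false_t] - ext[o, ]
    to_true <- L$ext[, true_t] - ext[o, ]
    cos_false <- sum(u * to_false) / sqrt(sum(to_false^2))
    cos_true <- sum(u * to_true) / sqrt(sum(to_true^2))
    per[as.character(k)] <- cos_false > cos_true
  }
  list(count = sum(per), scorable = length(per), per_trial = per)
}

#' Per-trial and run-level behavioural metrics
#'
#' @inheritParams reaction_time
#' @param delta Accuracy distance guard.
#' @return A data frame with one row per cue (`trial`, `target`,
#'   `onset_bin`, `rt_ms`, `accuracy`) and attributes `switch_latency` and
#'   `perseveration`.
#' @export
trial_metrics <- function(trace, schedule = trace$schedule,
                          radius = default_radius(trace_locations(trace)),
                          delta = 1e-2) {
  df <- data.frame(trial = seq_len(schedule$n_cues),
                   target = schedule$order,
                   onset_bin = schedule$onsets,
                   rt_ms = reaction_time(trace, schedule, radius),
                   accuracy = accuracy(trace, schedule, delta))
  attr(df, "switch_latency") <- switch_latency(trace, schedule)
  attr(df, "perseveration") <- perseveration(trace, schedule)
  attr(df, "radius") <- radius
  df
}
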