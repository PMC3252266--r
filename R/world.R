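# The hidden real-world process the agent samples: a single jointed arm whose
# vertical and horizontal angular displacements are driven by a saturating
# (tanh) function of action and decay back to rest, plus the salience
# (illumination) of four cue locations driven by exogenous Gaussian bumps.
# Three sensory streams are produced: proprioceptive (joint angles), visual
# (the arm in extrinsic coordinates, via the tangent map) and salience.

#' World process parameters
#'
#' @param tau_arm Decay time constant of the arm toward its resting position
#'   (time bins). Chosen so a cued reach completes well within one 12-bin cue
#'   interval.
#' @param tau_sal Decay time constant of cue salience (time bins); small
#'   enough that salience pulses are near-disjoint across cues.
#' @param action_gain Gain of the reflex arc: the arm velocity responds as
#'   `tanh(action_gain * action)`. Small values make the motor plant the
#'   rate-limiting stage of a reach, so movement vigour depends on the
#'   precision of the sensory prediction errors driving action.
#' @param noise_log_prec Log precision of the random fluctuations on state
#'   motion and sensory input.
#' @param smoothness Correlation length of those fluctuations (time bins).
#' @return An object of class `af_world_params`.
#' @export
world_params <- function(tau_arm = 4, tau_sal = 2, action_gain = 0.3,
                         noise_log_prec = 16, smoothness = 0.5) {
  structure(list(tau_arm = tau_arm, tau_sal = tau_sal,
                 action_gain = action_gain,
                 noise_log_prec = noise_log_prec, smoothness = smoothness),
            class = "af_world_params")
}

#' Cue schedule
#'
#' Ordered target presentations as Gaussian bumps in time, one bump per cue.
#'
#' @param order Integer vector of target indices (values in 1..4), one per
#'   cue, in presentation order.
#' @param interval Bins between successive cue onsets (>= 1).
#' @param width Bump standard deviation (bins).
#' @param amplitude Bump peak.
#' @param peak_lag Bins between a cue's onset and the peak of its bump
#'   (default `1.5 * width`), so that illumination begins at the onset
#'   rather than acausally before it.
#' @param t0 Bin of the first onset.
#' @return An object of class `af_schedule`.
#' @export
cue_schedule <- function(order, interval = 12, width = 2, amplitude = 10,
                         peak_lag = 1.5 * width, t0 = 0) {
  if (interval < 1) stop("`interval` must be >= 1")
  if (any(!(order %in% 1:4))) stop("`order` entries must be in 1..4")
  structure(list(n_cues = length(order), order = as.integer(order),
                 interval = interval, width = width, amplitude = amplitude,
                 peak_lag = peak_lag, t0 = t0,
                 onsets = t0 + (seq_along(order) - 1) * interval),
            class = "af_schedule")
}

#' @export
print.af_schedule <- function(x, ...) {
  cat(sprintf("Cue schedule: %d cues every %g bins (width %g, amplitude %g)\n",
              x$n_cues, x$interval, x$width, x$amplitude))
  cat("  order:", paste(x$order, collapse = " "), "\n")
  invisible(x)
}

#' Exogenous cue causes at a point in time
#'
#' Component j at time t is the sum over cues presenting target j of
#' `amplitude * exp(-(t - onset)^2 / (2 width^2))`; always non-negative.
#'
#' @param t Time (bins); may be a vector.
#' @param schedule An [cue_schedule()] object.
#' @return A 4-vector for scalar `t`, otherwise a `length(t)` x 4 matrix.
#' @export
cue_causes <- function(t, schedule) {
  centres <- schedule$onsets + schedule$peak_lag
  bump <- outer(t, centres,
                function(tt, o) exp(-(tt - o)^2 / (2 * schedule$width^2)))
  out <- matrix(0, length(t), 4)
  for (j in 1:4) {
    sel <- schedule$order == j
    if (any(sel)) out[, j] <- rowSums(bump[, sel, drop = FALSE])
  }
  out <- schedule$amplitude * out
  if (length(t) == 1L) drop(out) else out
}

#' World equations of motion
#'
#' `d(arm)/dt = tanh(action) - arm / tau_arm`;
#' `d(salience)/dt = causes - salience / tau_sal`.
#'
#' @param state Numeric 6-vector `(arm[2], salience[4])`.
#' @param action 2-vector of angular forces.
#' @param causes 4-vector of exogenous cue causes.
#' @param wp An [world_params()] object.
#' @return The 6-vector state derivative.
#' @export
world_flow <- function(state, action, causes, wp) {
  c(tanh(wp$action_gain * action) - state[1:2] / wp$tau_arm,
    causes - state[3:6] / wp$tau_sal)
}

world_obs <- function(state) {
  c(state[1:2], tan(state[1:2]), state[3:6])
}

world_obs_jac <- function(state) {
  J <- matrix(0, 8, 6)
  J[1:2, 1:2] <- diag(2)
  J[3:4, 1:2] <- diag(1 / cos(state[1:2])^2, 2)
  J[5:8, 3:6] <- diag(4)
  J
}

#' Sample the sensory mapping of the world
#'
#' Produces the three sensory streams in generalized coordinates (value and
#' velocity): the order-0 block is the nonlinear observation of the true
#' state plus sensor noise; the order-1 block follows by the chain rule
#' through the world flow, using the state-noise path and the analytic
#' derivative of the sensor noise.
#'
#' @param state Numeric 6-vector `(arm[2], salience[4])`; arm angles must lie
#'   inside `(-pi/2, pi/2)`.
#' @param action Current 2-vector of action.
#' @param causes Current 4-vector of exogenous causes.
#' @param wp An [world_params()] object.
#' @param state_noise 6-vector of fluctuations on the state motion.
#' @param sens_noise 8 x 2 matrix of sensor noise (columns: value,
#'   derivative).
#' @return A list with elements `proprio` (2 x 2), `visual` (2 x 2) and
#'   `salience` (4 x 2); columns are derivative orders.
#' @export
sense <- function(state, action, causes, wp,
                  state_noise = rep(0, 6), sens_noise = matrix(0, 8, 2)) {
  if (any(abs(state[1:2]) >= pi / 2))
    stop("arm angles out of the tangent-map domain")
  s0 <- world_obs(state)
  xdot <- world_flow(state, action, causes, wp) + state_noise
  s1 <- drop(world_obs_jac(state) %*% xdot)
  s <- unname(cbind(s0, s1)) + sens_noise
  list(proprio = s[1:2, , drop = FALSE],
       visual = s[3:4, , drop = FALSE],
       salience = s[5:8, , drop = FALSE])
}

# Sensitivity of generalized sensory input to action (the reflex-arc
# channel): only the order-1 blocks of the proprioceptive and visual streams
# depend on action, through the tanh saturation of the arm drive.
sensory_action_jac <- function(state, action, wp) {
  g <- wp$action_gain
  da <- diag(g / cosh(g * action)^2, 2)  # d tanh(g a) / da
  vis <- diag(1 / cos(state[1:2])^2, 2) %*% da
  zero2 <- matrix(0, 2, 2)
  list(proprio = rbind(zero2, da),
       visual = rbind(zero2, vis),
       salience = matrix(0, 8, 2))
}
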