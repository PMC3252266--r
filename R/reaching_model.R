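# The agent's two-level generative model of cued sequential pointing.
#
# Level 1 hidden states: arm joint angles (2) and affordance states (4), one
# per target. The agent predicts proprioception as the arm state, vision as
# its tangent map, and (log-transformed) salience as exp of the affordances.
# Its prior flow draws the arm toward the location afforded by the softmax of
# the affordance states, while the affordances themselves run a winnerless
# competition whose speed is the first (sequential-context) component of the
# level-1 hidden cause.
#
# Level 2 hidden states: a two-state slow winnerless competition encoding the
# context (sequential vs. random cue order); its softmax is the predicted
# level-1 cause. The slow cycle runs at one eighth of the fast cycle's rate.

#' Configuration of the cued reaching model
#'
#' All tunable constants of the generative model in one place. The attractor
#' gains and time constants were tuned once (see the tuning script shipped
#' under `scripts/`) so that the free-running affordance cycle visits one
#' target per 12-bin cue interval, the context cycle is eight times slower,
#' and a cued reach completes well within a cue interval; they are frozen
#' here.
#'
#' @param tau_reach Time constant of the prior arm pull toward the afforded
#'   target (bins).
#' @param kappa Gain mapping the sequential-context cause onto the speed of
#'   the fast affordance cycle.
#' @param fast [attractor_params()] of the four-state affordance cycle.
#' @param slow [attractor_params()] of the two-state context cycle.
#' @param kappa_slow Fixed speed of the context cycle.
#' @param L [location_map()] of the four targets.
#' @param log_prec Named list of nominal log precisions per error stream.
#' @param n_states,n_causes Embedding orders for hidden states and causes.
#' @param smoothness Assumed correlation length of fluctuations (bins).
#' @return A list of class `af_reaching_config`.
#' @export
reaching_config <- function(tau_reach = 2,
                            kappa = 1,
                            fast = attractor_params(n = 4L, excite = 1.2,
                                                    inhibit = 1.1, decay = 8,
                                                    drive = 0.3),
                            slow = attractor_params(n = 2L, excite = 1.2,
                                                    inhibit = 1.1, decay = 64,
                                                    drive = 0.032),
                            kappa_slow = 0.061,
                            L = location_map(),
                            log_prec = list(proprio = 4, visual = 4,
                                            salience = 4, arm = 4,
                                            affordance = 4, context_cause = 4,
                                            context_state = 4, top = 4),
                            n_states = 6L, n_causes = 2L,
                            smoothness = 0.5) {
  structure(list(tau_reach = tau_reach, kappa = kappa, fast = fast,
                 slow = slow, kappa_slow = kappa_slow, L = L,
                 log_prec = log_prec, n_states = n_states,
                 n_causes = n_causes, smoothness = smoothness),
            class = "af_reaching_config")
}

#' Build the two-level generative model of cued reaching
#'
#' @param config An [reaching_config()] object.
#' @return An `af_model` that passes [validate_model()], with lesion sites
#'   `salience_sensory`, `proprio_sensory`, `visual_sensory`, `arm_state`,
#'   `affordance_state` and `context_level`.
#' @examples
#' m <- build_reaching_model()
#' validate_model(m)$ok
#' @export
build_reaching_model <- function(config = reaching_config()) {
  L <- config$L
  p1 <- list(tau_reach = config$tau_reach, kappa = config$kappa,
             fast = config$fast, A = wlc_transition(config$fast), L = L)
  p2 <- list(kappa_slow = config$kappa_slow, slow = config$slow,
             A = wlc_transition(config$slow))

  flow1 <- function(x, v, p) {
    th <- x[1:2]; al <- x[3:6]
    c((drop(p$L$int %*% softmax(al)) - th) / p$tau_reach,
      drop(p$kappa * v[1] * (p$A %*% softmax(al))) - al / p$fast$decay +
        p$fast$drive)
  }
  obs1 <- function(x, v, p) {
    c(x[1:2], tan(x[1:2]), exp(x[3:6]))
  }
  jac1 <- list(
    fx = function(x, v, p) {
      S <- softmax_jac(x[3:6])
      J <- matrix(0, 6, 6)
      J[1:2, 1:2] <- -diag(2) / p$tau_reach
      J[1:2, 3:6] <- (p$L$int %*% S) / p$tau_reach
      J[3:6, 3:6] <- p$kappa * v[1] * (p$A %*% S) - diag(4) / p$fast$decay
      J
    },
    fv = function(x, v, p) {
      J <- matrix(0, 6, 2)
      J[3:6, 1] <- p$kappa * (p$A %*% softmax(x[3:6]))
      J
    },
    gx = function(x, v, p) {
      J <- matrix(0, 8, 6)
      J[1:2, 1:2] <- diag(2)
      J[3:4, 1:2] <- diag(1 / cos(x[1:2])^2, 2)
      J[5:8, 3:6] <- diag(exp(x[3:6]), 4)
      J
    },
    gv = function(x, v, p) matrix(0, 8, 2)
  )
  curv1 <- list(
    f = function(x, v, ux, uv, p) {
      al <- x[3:6]; ua <- ux[3:6]
      M <- softmax_hvp(al, ua)
      S <- softmax_jac(al)
      dx <- matrix(0, 6, 6)
      dx[1:2, 3:6] <- (p$L$int %*% M) / p$tau_reach
      dx[3:6, 3:6] <- p$kappa * v[1] * (p$A %*% M) +
        p$kappa * uv[1] * (p$A %*% S)
      dv <- matrix(0, 6, 2)
      dv[3:6, 1] <- p$kappa * (p$A %*% (S %*% ua))
      list(dx = dx, dv = dv)
    },
    g = function(x, v, ux, uv, p) {
      dx <- matrix(0, 8, 6)
      th <- x[1:2]
      dx[3:4, 1:2] <- diag(2 * tan(th) / cos(th)^2 * ux[1:2], 2)
      dx[5:8, 3:6] <- diag(exp(x[3:6]) * ux[3:6], 4)
      list(dx = dx, dv = matrix(0, 8, 2))
    }
  )

  flow2 <- function(x, v, p) {
    drop(p$kappa_slow * (p$A %*% softmax(x))) - x / p$slow$decay +
      p$slow$drive
  }
  obs2 <- function(x, v, p) softmax(x)
  jac2 <- list(
    fx = function(x, v, p)
      p$kappa_slow * (p$A %*% softmax_jac(x)) - diag(2) / p$slow$decay,
    fv = function(x, v, p) matrix(0, 2, 1),
    gx = function(x, v, p) softmax_jac(x),
    gv = function(x, v, p) matrix(0, 2, 1)
  )
  curv2 <- list(
    f = function(x, v, ux, uv, p)
      list(dx = p$kappa_slow * (p$A %*% softmax_hvp(x, ux)),
           dv = matrix(0, 2, 1)),
    g = function(x, v, ux, uv, p)
      list(dx = softmax_hvp(x, ux), dv = matrix(0, 2, 1))
  )

  lp <- config$log_prec
  lev1 <- level_spec(
    dim_x = 6, dim_v = 2, flow = flow1, obs = obs1, jac = jac1, curv = curv1,
    state_partitions = list(arm = 1:2, affordance = 3:6),
    log_prec_state = c(arm = lp$arm, affordance = lp$affordance),
    params = p1)
  lev2 <- level_spec(
    dim_x = 2, dim_v = 1, flow = flow2, obs = obs2, jac = jac2, curv = curv2,
    state_partitions = list(context = 1:2),
    log_prec_state = c(context = lp$context_state),
    log_prec_cause = lp$context_cause,
    params = p2)

  streams <- list(
    proprio = list(idx = 1:2, log_prec = lp$proprio),
    visual = list(idx = 3:4, log_prec = lp$visual),
    salience = list(idx = 5:8, log_prec = lp$salience))

  sites <- list(
    salience_sensory = list(list(where = "stream", name = "salience")),
    proprio_sensory = list(list(where = "stream", name = "proprio")),
    visual_sensory = list(list(where = "stream", name = "visual")),
    arm_state = list(list(where = "state", level = 1L, name = "arm")),
    affordance_state = list(list(where = "state", level = 1L,
                                 name = "affordance")),
    context_level = list(list(where = "state", level = 2L, name = "context"),
                         list(where = "cause", level = 2L)))

  m <- hierarchical_model(
    levels = list(lev1, lev2), streams = streams,
    top_prior = list(mean = function(t) 0, log_prec = lp$top),
    lesion_sites = sites)
  m$config <- config
  m
}
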