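# The active-inference engine: generalized filtering (predictive coding in
# generalized coordinates of motion) jointly integrated with action and the
# world process.
#
# Conditional expectations mu~ descend the free-energy gradient while being
# carried along their own generalized motion, d(mu~)/dt = D mu~ - dF/dmu~,
# and action descends dF/da through the sensitivity of generalized sensory
# input to action (the reflex arc). Free energy is the precision-weighted sum
# of squared prediction errors over all streams (plus constant log-normalising
# terms under fixed precisions).
#
# Generalized predictions are evaluated by the first-order chain rule: block
# k >= 1 of g~ is J_x x_k + J_v v_k with the Jacobians evaluated at order 0
# (products of derivatives beyond first order are dropped, the convention for
# this scheme). The free-energy gradient differentiates these errors
# *exactly*, including the curvature of the order-0 Jacobians, so it matches
# finite differences of the implemented free energy. The Gauss-Newton
# Hessian J' Pi J (curvature-times-error terms dropped) supplies the
# integrator Jacobian and the conditional covariance used for credible
# intervals.

#' Embedding configuration
#'
#' Orders of generalized motion and the assumed smoothness of fluctuations.
#' Six orders for hidden states and two for causes/sensory streams are the
#' established defaults for generalized filtering; at least four state
#' orders are needed to filter smooth noise effectively.
#'
#' @param n_states Derivative orders carried for hidden states (>= n_causes).
#' @param n_causes Derivative orders for causes and sensory streams (>= 1).
#' @param smoothness Correlation length of fluctuations (time bins).
#' @param dt Bin duration in seconds (64 ms bins by default; used only for
#'   reporting).
#' @return An object of class `af_embedding`.
#' @export
embedding <- function(n_states = 6L, n_causes = 2L, smoothness = 0.5,
                      dt = 0.064) {
  if (n_causes < 1 || n_states < n_causes)
    stop("need n_states >= n_causes >= 1")
  if (smoothness <= 0 || dt <= 0) stop("`smoothness` and `dt` must be positive")
  structure(list(n_states = as.integer(n_states),
                 n_causes = as.integer(n_causes),
                 smoothness = smoothness, dt = dt),
            class = "af_embedding")
}

mu_layout <- function(model, embed) {
  n <- embed$n_states
  d <- embed$n_causes
  off <- 0L
  lay <- vector("list", length(model$levels))
  for (i in seq_along(model$levels)) {
    lev <- model$levels[[i]]
    xr <- if (lev$dim_x > 0) off + seq_len(lev$dim_x * n) else integer()
    off <- off + lev$dim_x * n
    vr <- if (lev$dim_v > 0) off + seq_len(lev$dim_v * d) else integer()
    off <- off + lev$dim_v * d
    lay[[i]] <- list(x = xr, v = vr)
  }
  list(levels = lay, p = off)
}

#' Initial posterior expectations (all zero)
#'
#' @param model An `af_model`.
#' @param embed An [embedding()] object.
#' @return A flat numeric vector of conditional expectations over all levels
#'   and derivative orders, with the layout attached as an attribute.
#' @export
mu_init <- function(model, embed = embedding()) {
  lay <- mu_layout(model, embed)
  structure(rep(0, lay$p), layout = lay)
}

# Generalized prediction of one level function (flow or obs) over K orders,
# together with the exact Jacobian of the stacked prediction with respect to
# the flattened (x~, v~) of that level. Columns: x block then v block.
gen_pred <- function(fun, Jx_fun, Jv_fun, curv_fun, xt, vt, K, params) {
  dim_x <- nrow(xt); n_x <- ncol(xt)
  dim_v <- nrow(vt); n_v <- ncol(vt)
  x0 <- xt[, 1]
  v0 <- if (dim_v > 0) vt[, 1] else numeric()
  f0 <- fun(x0, v0, params)
  m <- length(f0)
  JX <- Jx_fun(x0, v0, params)
  JV <- Jv_fun(x0, v0, params)
  px <- dim_x * n_x
  pv <- dim_v * n_v
  pred <- matrix(0, m, K)
  pred[, 1] <- f0
  J <- matrix(0, m * K, px + pv)
  xcols <- function(k) (k * dim_x + 1):((k + 1) * dim_x)
  vcols <- function(k) (px + k * dim_v + 1):(px + (k + 1) * dim_v)
  for (k in 0:(K - 1)) {
    rows <- (k * m + 1):((k + 1) * m)
    if (k < n_x) J[rows, xcols(k)] <- JX
    if (k < n_v && dim_v > 0) J[rows, vcols(k)] <- JV
    if (k >= 1) {
      xk <- if (k < n_x) xt[, k + 1] else rep(0, dim_x)
      vk <- if (k < n_v && dim_v > 0) vt[, k + 1] else rep(0, max(dim_v, 1L))
      pred[, k + 1] <- JX %*% xk + if (dim_v > 0) JV %*% vk else 0
      if (!is.null(curv_fun)) {
        cc <- curv_fun(x0, v0, xk, vk, params)
        J[rows, xcols(0)] <- J[rows, xcols(0)] + cc$dx
        if (dim_v > 0) J[rows, vcols(0)] <- J[rows, vcols(0)] + cc$dv
      }
    }
  }
  list(pred = pred, J = J)
}

# Precompute everything reusable across bins: layout, generalized-motion
# operator, per-group precisions and their log-determinant constants.
engine_context <- function(model, embed) {
  n <- embed$n_states
  d <- embed$n_causes
  lay <- mu_layout(model, embed)
  Rn_inv <- solve(deriv_autocorr(n, embed$smoothness))
  Rd_inv <- solve(deriv_autocorr(d, embed$smoothness))
  D <- matrix(0, lay$p, lay$p)
  for (i in seq_along(model$levels)) {
    lev <- model$levels[[i]]
    if (lev$dim_x > 0)
      D[lay$levels[[i]]$x, lay$levels[[i]]$x] <- shift_operator(n, lev$dim_x)
    if (lev$dim_v > 0)
      D[lay$levels[[i]]$v, lay$levels[[i]]$v] <- shift_operator(d, lev$dim_v)
  }
  prec <- list()
  for (nm in names(model$streams)) {
    st <- model$streams[[nm]]
    prec[[paste0("s_", nm)]] <-
      exp(st$log_prec) * kronecker(Rd_inv, diag(length(st$idx)))
  }
  L <- length(model$levels)
  if (L > 1) {
    for (i in seq_len(L - 1)) {
      lev_below <- model$levels[[i]]
      prec[[paste0("v_", i)]] <-
        exp(model$levels[[i + 1]]$log_prec_cause) *
        kronecker(Rd_inv, diag(lev_below$dim_v))
    }
  }
  top <- model$levels[[L]]
  if (top$dim_v > 0)
    prec[[paste0("v_", L)]] <-
      exp(model$top_prior$log_prec) * kronecker(Rd_inv, diag(top$dim_v))
  for (i in seq_len(L)) {
    lev <- model$levels[[i]]
    if (lev$dim_x > 0) {
      w <- rep(NA_real_, lev$dim_x)
      for (nm in names(lev$state_partitions))
        w[lev$state_partitions[[nm]]] <- exp(lev$log_prec_state[[nm]])
      prec[[paste0("x_", i)]] <- kronecker(Rn_inv, diag(w, lev$dim_x))
    }
  }
  log_det <- vapply(prec, function(P)
    as.numeric(determinant(P, logarithm = TRUE)$modulus), 1)
  n_tot <- sum(vapply(prec, nrow, 1L))
  fe_const <- -0.5 * sum(log_det) + 0.5 * n_tot * log(2 * pi)
  list(layout = lay, D = D, prec = prec, fe_const = fe_const,
       n = n, d = d)
}

# Evaluate all prediction errors, the free energy, its exact gradient and
# the Gauss-Newton Hessian at one set of expectations and sensory data.
error_system <- function(ctx, model, mu, sensory, t = 0) {
  n <- ctx$n; d <- ctx$d
  lay <- ctx$layout
  L <- length(model$levels)
  xt <- vt <- vector("list", L)
  for (i in seq_len(L)) {
    lev <- model$levels[[i]]
    xt[[i]] <- matrix(mu[lay$levels[[i]]$x], lev$dim_x, n)
    vt[[i]] <- matrix(mu[lay$levels[[i]]$v], lev$dim_v, d)
  }
  groups <- list()
  add_group <- function(name, eps, J, cols) {
    P <- ctx$prec[[name]]
    groups[[name]] <<- list(eps = eps, xi = drop(P %*% eps), J = J,
                            cols = cols)
  }
  # sensory cause errors (level-1 observation split into streams)
  lev1 <- model$levels[[1]]
  gp1 <- gen_pred(lev1$obs, lev1$jac$gx, lev1$jac$gv,
                  if (is.null(lev1$curv)) NULL else lev1$curv$g,
                  xt[[1]], vt[[1]], d, lev1$params)
  m1 <- nrow(gp1$pred)
  for (nm in names(model$streams)) {
    st <- model$streams[[nm]]
    rows <- as.vector(outer(st$idx, (0:(d - 1)) * m1, `+`))
    eps <- as.vector(sensory[[nm]]) - as.vector(gp1$pred[st$idx, ,
                                                         drop = FALSE])
    add_group(paste0("s_", nm), eps, -gp1$J[rows, , drop = FALSE],
              c(lay$levels[[1]]$x, lay$levels[[1]]$v))
  }
  # cause errors between levels, and the top-level prior
  if (L > 1) {
    for (i in seq_len(L - 1)) {
      levu <- model$levels[[i + 1]]
      gpu <- gen_pred(levu$obs, levu$jac$gx, levu$jac$gv,
                      if (is.null(levu$curv)) NULL else levu$curv$g,
                      xt[[i + 1]], vt[[i + 1]], d, levu$params)
      len <- model$levels[[i]]$dim_v * d
      eps <- as.vector(vt[[i]]) - as.vector(gpu$pred)
      J <- cbind(diag(len), -gpu$J)
      add_group(paste0("v_", i), eps, J,
                c(lay$levels[[i]]$v, lay$levels[[i + 1]]$x,
                  lay$levels[[i + 1]]$v))
    }
  }
  top <- model$levels[[L]]
  if (top$dim_v > 0) {
    pm <- model$top_prior$mean(t)
    prior <- matrix(0, top$dim_v, d)
    if (is.matrix(pm)) prior[, seq_len(ncol(pm))] <- pm else prior[, 1] <- pm
    len <- top$dim_v * d
    add_group(paste0("v_", L), as.vector(vt[[L]]) - as.vector(prior),
              diag(len), lay$levels[[L]]$v)
  }
  # state-motion errors
  for (i in seq_len(L)) {
    lev <- model$levels[[i]]
    if (lev$dim_x == 0) next
    fp <- gen_pred(lev$flow, lev$jac$fx, lev$jac$fv,
                   if (is.null(lev$curv)) NULL else lev$curv$f,
                   xt[[i]], vt[[i]], n, lev$params)
    Dn <- shift_operator(n, lev$dim_x)
    eps <- drop(Dn %*% as.vector(xt[[i]])) - as.vector(fp$pred)
    px <- lev$dim_x * n
    J <- -fp$J
    J[, seq_len(px)] <- J[, seq_len(px)] + Dn
    add_group(paste0("x_", i), eps, J,
              c(lay$levels[[i]]$x, lay$levels[[i]]$v))
  }
  # free energy, gradient, Gauss-Newton Hessian
  Fq <- 0
  grad <- rep(0, lay$p)
  H <- matrix(0, lay$p, lay$p)
  for (nm in names(groups)) {
    g <- groups[[nm]]
    Fq <- Fq + 0.5 * sum(g$eps * g$xi)
    grad[g$cols] <- grad[g$cols] + drop(crossprod(g$J, g$xi))
    PJ <- ctx$prec[[nm]] %*% g$J
    H[g$cols, g$cols] <- H[g$cols, g$cols] + crossprod(g$J, PJ)
  }
  list(groups = groups, F = Fq + ctx$fe_const, F_quad = Fq,
       grad = grad, H = H)
}

#' Prediction errors and precision-weighted errors
#'
#' Evaluates, at the supplied conditional expectations and sensory sample,
#' the raw prediction error `eps` and the precision-weighted error
#' `xi = Pi eps` for every error stream: the sensory streams, the cause
#' errors linking levels, the top-level prior error and the state-motion
#' errors per level.
#'
#' @param model An `af_model`.
#' @param mu Flat vector of expectations (see [mu_init()]).
#' @param sensory Named list of stream matrices (dim x n_causes orders).
#' @param embed An [embedding()] object.
#' @param t Time (bins) at which the top-level prior mean is evaluated.
#' @return A named list of streams, each `list(eps =, xi =)`.
#' @export
prediction_errors <- function(model, mu, sensory, embed = embedding(),
                              t = 0) {
  ctx <- engine_context(model, embed)
  es <- error_system(ctx, model, mu, sensory, t)
  lapply(es$groups, function(g) list(eps = g$eps, xi = g$xi))
}

#' Free energy of expectations given sensory data
#'
#' One half the precision-weighted sum of squared prediction errors over all
#' streams, plus the constant log-determinant and normalisation terms
#' (constant under fixed precisions).
#'
#' @inheritParams prediction_errors
#' @return A scalar (nats).
#' @export
free_energy <- function(model, mu, sensory, embed = embedding(), t = 0) {
  ctx <- engine_context(model, embed)
  error_system(ctx, model, mu, sensory, t)$F
}

#' Analytic gradient of free energy with respect to the expectations
#'
#' @inheritParams prediction_errors
#' @return A vector the length of `mu`.
#' @export
free_energy_gradient <- function(model, mu, sensory, embed = embedding(),
                                 t = 0) {
  ctx <- engine_context(model, embed)
  error_system(ctx, model, mu, sensory, t)$grad
}

# Local-linearization step: the increment over dt of du/dt = f0 + J (u - u0)
# is dt * phi1(J dt) f0 with phi1(z) = (exp(z) - 1) / z. The matrix phi1 is
# evaluated through the eigendecomposition of J, which is exact for the
# linearized system and remains accurate for the very stiff Jacobians that
# high precisions produce (where Pade scaling-and-squaring of the matrix
# exponential loses all accuracy). Falls back to an A-stable trapezoidal
# substep rule if the eigenvector basis is unusable.
ll_delta <- function(J, f0, dt) {
  ev <- tryCatch(eigen(J), error = function(e) NULL)
  if (!is.null(ev)) {
    co <- tryCatch(solve(ev$vectors, f0), error = function(e) NULL)
    if (!is.null(co)) {
      lam <- ev$values * dt
      lam <- complex(real = pmin(Re(lam), 40), imaginary = Im(lam))
      phi <- ifelse(abs(lam) < 1e-7, 1 + lam / 2, (exp(lam) - 1) / lam)
      delta <- Re(ev$vectors %*% (phi * co)) * dt
      if (all(is.finite(delta))) return(drop(delta))
    }
  }
  # trapezoidal (Crank-Nicolson) fallback over 32 substeps
  p <- length(f0)
  u <- rep(0, p)
  h <- dt / 32
  A <- diag(p) - (h / 2) * J
  for (k in seq_len(32)) {
    u <- drop(solve(A, u + h * f0 + (h / 2) * drop(J %*% u)))
  }
  u
}

#' Advance the conditional expectations one time bin
#'
#' Integrates `d(mu~)/dt = D mu~ - dF/dmu~` over one bin with the sensory
#' input held fixed. The default solver is local linearization (matrix
#' exponential of the Jacobian `D - H` with the Gauss-Newton Hessian `H`);
#' `solver = "rk4"` is a fixed-step Runge-Kutta cross-check.
#'
#' @inheritParams prediction_errors
#' @param dt Bin duration in integration time units (1 = one bin).
#' @param substeps Integration substeps per bin (>= 1).
#' @param solver `"ll"` (local linearization) or `"rk4"`.
#' @param static If `TRUE`, drop the generalized-motion term `D mu~` (the
#'   static-inference limit of the scheme): the update becomes a pure
#'   free-energy descent, under which free energy is non-increasing.
#' @return `list(mu =, free_energy =)` with the updated expectations and the
#'   free energy evaluated before the step.
#' @export
filtering_step <- function(model, mu, sensory, embed = embedding(), t = 0,
                           dt = 1, substeps = 1, solver = c("ll", "rk4"),
                           static = FALSE) {
  solver <- match.arg(solver)
  ctx <- engine_context(model, embed)
  if (static) ctx$D <- 0 * ctx$D
  step <- gf_step(ctx, model, mu, sensory, t, dt, substeps, solver)
  list(mu = step$mu, free_energy = step$F)
}

gf_step <- function(ctx, model, mu, sensory, t, dt, substeps, solver) {
  h <- dt / substeps
  F0 <- NA_real_
  for (k in seq_len(substeps)) {
    es <- error_system(ctx, model, mu, sensory, t)
    if (k == 1L) F0 <- es$F
    if (solver == "ll") {
      udot <- drop(ctx$D %*% mu) - es$grad
      J <- ctx$D - es$H
      mu <- mu + ll_delta(J, udot, h)
    } else {
      fu <- function(u) {
        e <- error_system(ctx, model, u, sensory, t)
        drop(ctx$D %*% u) - e$grad
      }
      k1 <- fu(mu)
      k2 <- fu(mu + h / 2 * k1)
      k3 <- fu(mu + h / 2 * k2)
      k4 <- fu(mu + h * k3)
      mu <- mu + h / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
    }
    if (any(!is.finite(mu)))
      stop(sprintf("filtering update became non-finite at t = %g", t))
  }
  list(mu = mu, F = F0, es = es)
}

# Sensitivity of generalized sensory input to the world state (first-order;
# curvature of the world observation Jacobian is dropped, as in the
# Gauss-Newton treatment of the integrator).
sensory_world_jac <- function(wstate, wp) {
  Jg <- world_obs_jac(wstate)
  Jw <- diag(c(rep(-1 / wp$tau_arm, 2), rep(-1 / wp$tau_sal, 4)))
  S0 <- Jg
  S1 <- Jg %*% Jw
  idx <- list(proprio = 1:2, visual = 3:4, salience = 5:8)
  lapply(idx, function(i) rbind(S0[i, , drop = FALSE], S1[i, , drop = FALSE]))
}

# Joint update of the world state, the conditional expectations and action
# over one bin: active inference closes the loop through the world within
# the bin, so the combined system (world, mu~, a) is advanced with one local
# linearization (or full Runge-Kutta in the cross-check mode) per substep.
# The random fluctuations are held at their bin values.
active_step <- function(ctx, model, wstate, mu, a, schedule, wp,
                        w_noise, z_noise, t, dt, substeps, solver) {
  p <- ctx$layout$p
  nw <- length(wstate)
  na <- length(a)
  h <- dt / substeps
  F0 <- NA_real_
  es0 <- NULL
  s0 <- NULL
  eval_sys <- function(wstate, mu, a, tt) {
    s <- sense(wstate, a, cue_causes(tt, schedule), wp, w_noise, z_noise)
    es <- error_system(ctx, model, mu, s, tt)
    list(s = s, es = es)
  }
  propose <- function(wstate, mu, a, tt, h) {
    sys <- eval_sys(wstate, mu, a, tt)
    es <- sys$es
    sa <- sensory_action_jac(wstate, a, wp)[names(model$streams)]
    sw <- sensory_world_jac(wstate, wp)[names(model$streams)]
    grad_a <- rep(0, na)
    H_aa <- matrix(0, na, na)
    H_ua <- matrix(0, p, na)
    H_uw <- matrix(0, p, nw)
    H_aw <- matrix(0, na, nw)
    for (nm in names(model$streams)) {
      gname <- paste0("s_", nm)
      g <- es$groups[[gname]]
      P <- ctx$prec[[gname]]
      grad_a <- grad_a + drop(crossprod(sa[[nm]], g$xi))
      PSa <- P %*% sa[[nm]]
      PSw <- P %*% sw[[nm]]
      H_aa <- H_aa + crossprod(sa[[nm]], PSa)
      H_aw <- H_aw + crossprod(sa[[nm]], PSw)
      H_ua[g$cols, ] <- H_ua[g$cols, ] + crossprod(g$J, PSa)
      H_uw[g$cols, ] <- H_uw[g$cols, ] + crossprod(g$J, PSw)
    }
    wdot <- world_flow(wstate, a, cue_causes(tt, schedule), wp) + w_noise
    udot <- c(wdot, drop(ctx$D %*% mu) - es$grad, -grad_a)
    if (solver == "ll") {
      Jw <- diag(c(rep(-1 / wp$tau_arm, 2), rep(-1 / wp$tau_sal, 4)))
      Jwa <- rbind(diag(wp$action_gain / cosh(wp$action_gain * a)^2, 2),
                   matrix(0, 4, 2))
      J <- rbind(
        cbind(Jw, matrix(0, nw, p), Jwa),
        cbind(-H_uw, ctx$D - es$H, -H_ua),
        cbind(-H_aw, -t(H_ua), -H_aa))
      delta <- ll_delta(J, udot, h)
    } else {
      f_all <- function(U) {
        ws_ <- U[seq_len(nw)]
        mu_ <- U[nw + seq_len(p)]
        a_ <- U[nw + p + seq_len(na)]
        sys_ <- eval_sys(ws_, mu_, a_, tt)
        sa_ <- sensory_action_jac(ws_, a_, wp)[names(model$streams)]
        ga <- rep(0, na)
        for (nm in names(model$streams))
          ga <- ga + drop(crossprod(sa_[[nm]],
                                    sys_$es$groups[[paste0("s_", nm)]]$xi))
        c(world_flow(ws_, a_, cue_causes(tt, schedule), wp) + w_noise,
          drop(ctx$D %*% mu_) - sys_$es$grad, -ga)
      }
      U <- c(wstate, mu, a)
      k1 <- f_all(U)
      k2 <- f_all(U + h / 2 * k1)
      k3 <- f_all(U + h / 2 * k2)
      k4 <- f_all(U + h * k3)
      delta <- h / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
    }
    list(delta = delta, sys = sys)
  }
  # advance by h, recursively halving the step while the proposed update is
  # too large for the local linearization to be trusted
  advance <- function(wstate, mu, a, tt, h, depth) {
    pr <- propose(wstate, mu, a, tt, h)
    big <- any(!is.finite(pr$delta)) || max(abs(pr$delta)) > 1.5
    if (big && depth >= 8L)
      stop(sprintf("update not integrable at t = %.3f", tt))
    if (big) {
      st <- advance(wstate, mu, a, tt, h / 2, depth + 1L)
      st2 <- advance(st$wstate, st$mu, st$a, tt + h / 2, h / 2, depth + 1L)
      st2$sys <- st$sys
      return(st2)
    }
    list(wstate = wstate + pr$delta[seq_len(nw)],
         mu = mu + pr$delta[nw + seq_len(p)],
         a = a + pr$delta[nw + p + seq_len(na)],
         sys = pr$sys)
  }
  for (k in seq_len(substeps)) {
    tt <- t + (k - 1) * h
    st <- advance(wstate, mu, a, tt, h, 0L)
    if (k == 1L) { F0 <- st$sys$es$F; es0 <- st$sys$es; s0 <- st$sys$s }
    wstate <- st$wstate
    mu <- st$mu
    a <- st$a
    if (any(!is.finite(c(wstate, mu, a))))
      stop(sprintf("active inference update became non-finite at t = %g", t))
  }
  list(wstate = wstate, mu = mu, a = a, F = F0, es = es0, s = s0)
}

#' Simulation configuration
#'
#' @param n_bins Total bins to simulate (128 covers ten 12-bin cue
#'   intervals).
#' @param substeps Integration substeps per bin for the expectations/action
#'   update.
#' @param world_substeps Runge-Kutta substeps per bin for the world process.
#' @param solver `"ll"` (local linearization, default) or `"rk4"`.
#' @param seed Integer seed for the random fluctuations.
#' @param embed An [embedding()] object.
#' @param wp An [world_params()] object.
#' @param store_cov Record conditional variances per bin (for credible
#'   intervals).
#' @return A list of class `af_sim_config`.
#' @export
sim_config <- function(n_bins = 128L, substeps = 4L, world_substeps = 8L,
                       solver = c("ll", "rk4"), seed = 1L,
                       embed = embedding(), wp = world_params(),
                       store_cov = TRUE) {
  solver <- match.arg(solver)
  if (substeps < 1) stop("`substeps` must be >= 1")
  structure(list(n_bins = as.integer(n_bins), substeps = as.integer(substeps),
                 world_substeps = as.integer(world_substeps), solver = solver,
                 seed = as.integer(seed), embed = embed, wp = wp,
                 store_cov = isTRUE(store_cov)),
            class = "af_sim_config")
}

world_rk4 <- function(state, a, t0, schedule, wp, noise, substeps) {
  h <- 1 / substeps
  fw <- function(tt, x) world_flow(x, a, cue_causes(tt, schedule), wp) + noise
  for (k in seq_len(substeps)) {
    tt <- t0 + (k - 1) * h
    k1 <- fw(tt, state)
    k2 <- fw(tt + h / 2, state + h / 2 * k1)
    k3 <- fw(tt + h / 2, state + h / 2 * k2)
    k4 <- fw(tt + h, state + h * k3)
    state <- state + h / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
  }
  state
}

#' Run the full active-inference simulation
#'
#' Jointly integrates the hidden world process, the generalized filtering of
#' the agent's expectations, and action, for `config$n_bins` bins, recording
#' everything. Reproducible bit-for-bit under a fixed seed.
#'
#' @param model An `af_model`, typically [build_reaching_model()].
#' @param schedule An [cue_schedule()]; default is the ten-cue
#'   clockwise-then-reversed presentation.
#' @param lesions Optional lesions passed to [apply_lesion()].
#' @param config An [sim_config()].
#' @return An object of class `af_trace`.
#' @export
run_active_inference <- function(model = build_reaching_model(),
                                 schedule = make_schedule("paper_default"),
                                 lesions = NULL,
                                 config = sim_config()) {
  model <- apply_lesion(model, lesions)
  diagv <- validate_model(model)
  if (!diagv$ok)
    stop("invalid model: ", paste(diagv$messages, collapse = "; "))
  embed <- config$embed
  wp <- config$wp
  ctx <- engine_context(model, embed)
  p <- ctx$layout$p
  T_ <- config$n_bins
  set.seed(config$seed)
  w <- sample_smooth_noise(T_, 6, wp$noise_log_prec, wp$smoothness,
                           seed = NULL, n_orders = 1)
  z <- sample_smooth_noise(T_, 8, wp$noise_log_prec, wp$smoothness,
                           seed = NULL, n_orders = 2)
  mu <- rep(0, p)
  a <- c(0, 0)
  wstate <- rep(0, 6)
  rec <- list(world = matrix(0, T_, 6), action = matrix(0, T_, 2),
              mu = matrix(0, T_, p), free_energy = rep(0, T_),
              cov = if (config$store_cov) matrix(0, T_, p))
  sens_rec <- lapply(model$streams, function(st)
    matrix(0, T_, length(st$idx) * embed$n_causes))
  eps_rec <- xi_rec <- NULL
  for (t_ in seq_len(T_)) {
    tb <- t_ - 1
    step <- tryCatch(
      active_step(ctx, model, wstate, mu, a, schedule, wp,
                  w[t_, , 1], z[t_, , ], tb, 1, config$substeps,
                  config$solver),
      error = function(e) stop(sprintf("integration failed at bin %d: %s",
                                       tb, conditionMessage(e)), call. = FALSE))
    s <- step$s
    if (is.null(eps_rec)) {
      eps_rec <- lapply(step$es$groups, function(g)
        matrix(0, T_, length(g$eps)))
      xi_rec <- eps_rec
    }
    for (nm in names(step$es$groups)) {
      eps_rec[[nm]][t_, ] <- step$es$groups[[nm]]$eps
      xi_rec[[nm]][t_, ] <- step$es$groups[[nm]]$xi
    }
    for (nm in names(model$streams)) sens_rec[[nm]][t_, ] <- as.vector(s[[nm]])
    rec$world[t_, ] <- wstate
    rec$free_energy[t_] <- step$F
    if (config$store_cov)
      rec$cov[t_, ] <- diag(solve(step$es$H + diag(1e-8, p)))
    mu <- step$mu
    a <- step$a
    wstate <- step$wstate
    rec$mu[t_, ] <- mu
    rec$action[t_, ] <- a
  }
  structure(list(time = seq_len(T_) - 1, bin_ms = embed$dt * 1000,
                 world = rec$world, sensory = sens_rec, mu = rec$mu,
                 cov = rec$cov, eps = eps_rec, xi = xi_rec,
                 action = rec$action, free_energy = rec$free_energy,
                 model = model, schedule = schedule, config = config,
                 layout = ctx$layout),
            class = "af_trace")
}

#' Run generalized filtering on a fixed sensory sequence
#'
#' Passive inversion (perception only, no action): the expectations are
#' advanced one bin per sensory sample.
#'
#' @param model An `af_model`.
#' @param sensory A list of length T; element t is a named list of stream
#'   matrices (dim x n_causes).
#' @param embed An [embedding()] object.
#' @param substeps,solver Passed to the integrator (see [filtering_step()]).
#' @param mu0 Optional initial expectations (default zeros).
#' @return `list(mu = T x p matrix, free_energy = numeric(T))`.
#' @export
run_generalized_filter <- function(model, sensory, embed = embedding(),
                                   substeps = 1, solver = "ll", mu0 = NULL) {
  ctx <- engine_context(model, embed)
  p <- ctx$layout$p
  mu <- if (is.null(mu0)) rep(0, p) else mu0
  T_ <- length(sensory)
  out <- matrix(0, T_, p)
  Fs <- rep(NA_real_, T_)
  for (t_ in seq_len(T_)) {
    step <- gf_step(ctx, model, mu, sensory[[t_]], t_ - 1, 1, substeps,
                    solver)
    mu <- step$mu
    out[t_, ] <- mu
    Fs[t_] <- step$F
  }
  list(mu = out, free_energy = Fs, layout = ctx$layout)
}

#' Action update through the reflex arc
#'
#' Advances action along `da/dt = -(ds~/da)' xi_sensory`: the sensitivity of
#' generalized sensory input to action (obtained by differentiating the
#' world process) projects the precision-weighted sensory errors back onto
#' the motor variables. Only streams with non-zero sensitivity (proprioception
#' and vision, through the arm) contribute.
#'
#' @param model An `af_model`.
#' @param mu Flat expectations.
#' @param sensory Named list of stream matrices.
#' @param wstate World state 6-vector.
#' @param a Current action 2-vector.
#' @param embed An [embedding()] object.
#' @param wp An [world_params()] object (for the reflex-arc sensitivity).
#' @param dt Integration time (bins).
#' @param t Time bin.
#' @return The updated action 2-vector (forward-Euler over `dt`).
#' @export
action_update <- function(model, mu, sensory, wstate, a,
                          embed = embedding(), wp = world_params(),
                          dt = 1, t = 0) {
  ctx <- engine_context(model, embed)
  es <- error_system(ctx, model, mu, sensory, t)
  sa <- sensory_action_jac(wstate, a, wp)[names(model$streams)]
  grad_a <- rep(0, length(a))
  for (nm in names(sa))
    grad_a <- grad_a + drop(crossprod(sa[[nm]], es$groups[[paste0("s_", nm)]]$xi))
  a - dt * grad_a
}
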