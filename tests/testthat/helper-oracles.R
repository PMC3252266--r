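# Shared oracles and small builders for the test suite.

# central finite differences of a scalar function
fd_grad <- function(f, x, h = 1e-5) {
  vapply(seq_along(x), function(j) {
    e <- rep(0, length(x))
    e[j] <- h
    (f(x + e) - f(x - e)) / (2 * h)
  }, numeric(1))
}

# random sensory sample for the reaching model, in generalized coordinates
random_sensory <- function(seed = 1) {
  set.seed(seed)
  list(proprio = matrix(rnorm(4, sd = 0.3), 2, 2),
       visual = matrix(rnorm(4, sd = 0.3), 2, 2),
       salience = matrix(abs(rnorm(8, sd = 0.5)), 4, 2))
}

# free-running winner sequence and period of a winnerless competition,
# integrated with the independent deSolve solver
wlc_run <- function(p, speed, t_max = 1200, by = 0.05, burn = 300) {
  rhs <- function(t, x, parms) list(wlc_flow(x, speed, p))
  x0 <- c(1, rep(-1, p$n - 1))
  out <- deSolve::ode(x0, seq(0, t_max, by = by), rhs, NULL, method = "rk4")
  x <- out[out[, 1] > burn, -1, drop = FALSE]
  win <- apply(x, 1, which.max)
  sw <- which(diff(win) != 0)
  if (length(sw) < 2 * p$n)
    return(list(period = Inf, order = integer(), x = x))
  list(period = mean(diff(sw)) * by * p$n, order = win[sw + 1], x = x)
}

# discrete-time Kalman filter oracle for the linear-Gaussian fixture
kalman_filter <- function(model, ys, v_fun) {
  p <- model$levels[[1]]$params
  dim_x <- model$levels[[1]]$dim_x
  Fm <- as.matrix(Matrix::expm(p$A))
  G <- solve(p$A, (Fm - diag(dim_x))) %*% p$B
  Q <- diag(dim_x) * exp(-model$levels[[1]]$log_prec_state[["state"]])
  R <- diag(dim_x) * exp(-model$streams$y$log_prec)
  xk <- rep(0, dim_x)
  Pk <- diag(dim_x)
  out <- matrix(0, length(ys), dim_x)
  for (t_ in seq_along(ys)) {
    y <- ys[[t_]]$y[, 1]
    S <- p$C %*% Pk %*% t(p$C) + R
    K <- Pk %*% t(p$C) %*% solve(S)
    xk <- xk + drop(K %*% (y - p$C %*% xk))
    Pk <- (diag(dim_x) - K %*% p$C) %*% Pk
    out[t_, ] <- xk
    xk <- drop(Fm %*% xk + G %*% v_fun(t_ - 1))
    Pk <- Fm %*% Pk %*% t(Fm) + Q
  }
  out
}

# minimal trace carrying only a context time series, for the switch metric
context_trace <- function(ctx_seq_random, interval = 12) {
  T_ <- length(ctx_seq_random)
  # second-level states whose softmax component 2 equals the requested series
  x2 <- cbind(0, log(ctx_seq_random / (1 - ctx_seq_random)))
  mu <- matrix(0, T_, 2)
  mu[, 1:2] <- x2
  structure(list(time = seq_len(T_) - 1, bin_ms = 64, mu = mu,
                 layout = list(levels = list(list(), list(x = 1:2)))),
            class = "af_trace")
}
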