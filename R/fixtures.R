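# Deterministic generators of small test inputs, so every module can be
# exercised in isolation without running the full engine.

#' Cue schedule presets
#'
#' `paper_default` presents ten cues every 12 bins, the first five in the
#' expected clockwise order and the last five traversing the targets
#' anticlockwise (continuing from the last clockwise target);
#' `all_clockwise` cycles clockwise throughout; `all_reversed` traverses
#' anticlockwise throughout.
#'
#' @param preset One of `"paper_default"`, `"all_clockwise"`,
#'   `"all_reversed"`.
#' @param n_cues,interval,width,amplitude,t0 Overrides passed to
#'   [cue_schedule()].
#' @return An [cue_schedule()] object.
#' @export
make_schedule <- function(preset = c("paper_default", "all_clockwise",
                                     "all_reversed"),
                          n_cues = 10L, interval = 12, width = 2,
                          amplitude = 10, t0 = 0) {
  preset <- match.arg(preset)
  cw <- function(k) (k - 1L) %% 4L + 1L        # 1 2 3 4 1 2 ...
  ccw <- function(start, len) (start - 1L - seq_len(len)) %% 4L + 1L
  ord <- switch(preset,
    all_clockwise = cw(seq_len(n_cues)),
    all_reversed = c(1L, ccw(1L, n_cues - 1L)),
    paper_default = {
      first <- cw(seq_len(ceiling(n_cues / 2)))
      last <- ccw(first[length(first)], n_cues - length(first))
      c(first, last)
    })
  cue_schedule(ord, interval = interval, width = width,
               amplitude = amplitude, t0 = t0)
}

#' Random stable one-level linear-Gaussian model
#'
#' A linear flow `dx/dt = A x + B v` with all eigenvalues of `A` in the left
#' half plane (spectral radius < 1 in discrete time), and a linear
#' observation `y = C x`. Used as the fixture on which generalized filtering
#' is compared with a conventional optimal linear (Kalman) filter.
#'
#' @param dim_x,dim_v State and cause dimensions (>= 1).
#' @param seed Integer seed; the same seed returns identical matrices.
#' @param log_prec_obs,log_prec_state,log_prec_cause Log precisions of the
#'   observation, state-motion and cause-prior errors.
#' @return An `af_model` with the matrices attached as `$params` of level 1.
#' @export
make_linear_gaussian_model <- function(dim_x = 2L, dim_v = 1L, seed = 1L,
                                       log_prec_obs = 8,
                                       log_prec_state = 4,
                                       log_prec_cause = 8) {
  set.seed(as.integer(seed))
  B0 <- matrix(stats::rnorm(dim_x * dim_x, sd = 0.5), dim_x, dim_x)
  A <- B0 - diag(max(Re(eigen(B0, only.values = TRUE)$values)) + 0.4, dim_x)
  while (max(Mod(eigen(diag(dim_x) + A, only.values = TRUE)$values)) >= 1)
    A <- A / 2   # shrink toward the origin; keeps all real parts negative
  B <- matrix(stats::rnorm(dim_x * dim_v, sd = 1), dim_x, dim_v)
  C <- diag(1, dim_x) + matrix(stats::rnorm(dim_x * dim_x, sd = 0.1),
                               dim_x, dim_x)
  prm <- list(A = A, B = B, C = C)
  lev <- level_spec(
    dim_x = dim_x, dim_v = dim_v,
    flow = function(x, v, p) drop(p$A %*% x + p$B %*% v),
    obs = function(x, v, p) drop(p$C %*% x),
    jac = list(fx = function(x, v, p) p$A,
               fv = function(x, v, p) p$B,
               gx = function(x, v, p) p$C,
               gv = function(x, v, p) matrix(0, nrow(p$C), length(v))),
    curv = NULL,
    log_prec_state = c(state = log_prec_state),
    params = prm)
  streams <- list(y = list(idx = seq_len(dim_x), log_prec = log_prec_obs))
  hierarchical_model(list(lev), streams,
                     top_prior = list(mean = function(t) rep(0, dim_v),
                                      log_prec = log_prec_cause))
}

#' Simulate the linear-Gaussian world of [make_linear_gaussian_model()]
#'
#' Integrates the linear flow driven by a known cause path and smooth
#' process noise, and produces generalized sensory samples (value and
#' derivative) with smooth observation noise — the data on which the
#' generalized and classical filters are compared.
#'
#' @param model The fixture model.
#' @param n_bins Number of bins.
#' @param v_fun Function of time (bins) returning the true cause vector.
#' @param seed Integer seed.
#' @param smoothness Noise correlation length (bins).
#' @param substeps RK4 substeps per bin.
#' @return `list(x = n_bins x dim_x truth, y = list of sensory samples,
#'   v = n_bins x dim_v)`.
#' @export
simulate_linear_gaussian <- function(model, n_bins, v_fun = function(t) 0,
                                     seed = 1L, smoothness = 0.5,
                                     substeps = 8L) {
  p <- model$levels[[1]]$params
  dim_x <- model$levels[[1]]$dim_x
  dim_v <- model$levels[[1]]$dim_v
  lp_w <- model$levels[[1]]$log_prec_state[["state"]]
  lp_z <- model$streams$y$log_prec
  set.seed(as.integer(seed))
  w <- sample_smooth_noise(n_bins, dim_x, lp_w, smoothness, NULL, 1)
  z <- sample_smooth_noise(n_bins, dim_x, lp_z, smoothness, NULL, 2)
  x <- rep(0, dim_x)
  xs <- matrix(0, n_bins, dim_x)
  vs <- matrix(0, n_bins, dim_v)
  ys <- vector("list", n_bins)
  h <- 1 / substeps
  for (t_ in seq_len(n_bins)) {
    tb <- t_ - 1
    v_now <- rep(v_fun(tb), length.out = dim_v)
    xdot <- drop(p$A %*% x + p$B %*% v_now) + w[t_, , 1]
    y0 <- drop(p$C %*% x) + z[t_, , 1]
    y1 <- drop(p$C %*% xdot) + z[t_, , 2]
    ys[[t_]] <- list(y = cbind(y0, y1))
    xs[t_, ] <- x
    vs[t_, ] <- v_now
    for (k in seq_len(substeps)) {
      tt <- tb + (k - 1) * h
      fw <- function(tt, xx)
        drop(p$A %*% xx + p$B %*% rep(v_fun(tt), length.out = dim_v)) +
          w[t_, , 1]
      k1 <- fw(tt, x); k2 <- fw(tt + h / 2, x + h / 2 * k1)
      k3 <- fw(tt + h / 2, x + h / 2 * k2); k4 <- fw(tt + h, x + h * k3)
      x <- x + h / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
    }
  }
  list(x = xs, y = ys, v = vs)
}

#' Synthetic pointer trace from waypoints
#'
#' Builds a minimal trace whose extrinsic arm position linearly interpolates
#' the supplied waypoints, with all non-kinematic fields zeroed — a
#' controlled input for the behavioural metrics.
#'
#' @param waypoints List (or 2-column matrix) of extrinsic positions.
#' @param bins_per_segment Bins between successive waypoints.
#' @param L An [location_map()] (targets used by the metrics).
#' @return An object of class `af_trace`.
#' @export
make_pointer_trace <- function(waypoints, bins_per_segment = 4L,
                               L = location_map()) {
  if (is.matrix(waypoints))
    waypoints <- lapply(seq_len(nrow(waypoints)), function(i) waypoints[i, ])
  n_seg <- length(waypoints) - 1L
  if (n_seg < 1) stop("need at least two waypoints")
  pos <- do.call(rbind, lapply(seq_len(n_seg), function(s) {
    a <- waypoints[[s]]; b <- waypoints[[s + 1L]]
    frac <- seq(0, 1, length.out = bins_per_segment + 1L)[-(bins_per_segment + 1L)]
    t(vapply(frac, function(f) (1 - f) * a + f * b, numeric(2)))
  }))
  pos <- rbind(pos, waypoints[[length(waypoints)]])
  if (any(!is.finite(atan(pos))) || any(abs(pos) > tan(pi / 2 - 1e-6)))
    stop("waypoint outside the tangent-map range")
  T_ <- nrow(pos)
  world <- cbind(atan(pos), matrix(0, T_, 4))
  structure(list(time = seq_len(T_) - 1, bin_ms = 64,
                 world = world, sensory = NULL, mu = NULL, cov = NULL,
                 eps = NULL, xi = NULL, action = matrix(0, T_, 2),
                 free_energy = rep(0, T_), model = NULL, schedule = NULL,
                 config = NULL, layout = NULL, L = L),
            class = "af_trace")
}
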