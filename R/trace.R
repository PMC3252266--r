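# Methods and accessors for simulation traces.

#' @export
print.af_trace <- function(x, ...) {
  cat(sprintf("Active-inference trace: %d bins of %g ms\n",
              length(x$time), x$bin_ms))
  if (!is.null(x$schedule))
    cat(sprintf("  cues: %d every %g bins, order %s\n", x$schedule$n_cues,
                x$schedule$interval, paste(x$schedule$order, collapse = " ")))
  if (!is.null(x$free_energy))
    cat(sprintf("  free energy: first %.2f, last %.2f nats\n",
                x$free_energy[1], x$free_energy[length(x$free_energy)]))
  if (!is.null(x$mu)) {
    sl <- switch_latency(x)
    cat("  switch latency:",
        if (is.na(sl)) "none" else sprintf("%d trial(s)", sl), "\n")
  }
  invisible(x)
}

#' Conditional expectations of hidden states at one level
#'
#' @param trace An `af_trace`.
#' @param what `"x"` (hidden states) or `"v"` (hidden causes).
#' @param level Hierarchical level.
#' @param order Derivative order (0 = value).
#' @return A T x dim matrix of expectations.
#' @export
mu_series <- function(trace, what = c("x", "v"), level = 1L, order = 0L) {
  what <- match.arg(what)
  lev <- trace$model$levels[[level]]
  dim <- if (what == "x") lev$dim_x else lev$dim_v
  cols <- trace$layout$levels[[level]][[what]][order * dim + seq_len(dim)]
  trace$mu[, cols, drop = FALSE]
}

#' Marginal 90% credible intervals for expectations
#'
#' Half-widths from the local curvature (Gauss-Newton Hessian) of free
#' energy at each bin.
#'
#' @inheritParams mu_series
#' @return A T x dim matrix of interval half-widths, or `NULL` when the
#'   trace was run without `store_cov`.
#' @export
mu_ci90 <- function(trace, what = c("x", "v"), level = 1L, order = 0L) {
  if (is.null(trace$cov)) return(NULL)
  what <- match.arg(what)
  lev <- trace$model$levels[[level]]
  dim <- if (what == "x") lev$dim_x else lev$dim_v
  cols <- trace$layout$levels[[level]][[what]][order * dim + seq_len(dim)]
  stats::qnorm(0.95) * sqrt(pmax(trace$cov[, cols, drop = FALSE], 0))
}

#' Plot a simulation trace
#'
#' Four panels: predicted sensory input with precision-weighted sensory
#' errors; conditional expectations of the level-1 hidden states; the
#' context causes at the second level; and the movement trajectory in
#' extrinsic coordinates with the cue locations.
#'
#' @param x An `af_trace` from [run_active_inference()].
#' @param ... Unused.
#' @return Invisibly, `x`.
#' @export
plot.af_trace <- function(x, ...) {
  op <- graphics::par(mfrow = c(2, 2), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(op))
  tt <- x$time
  pred <- do.call(cbind, lapply(names(x$sensory), function(nm) {
    d <- ncol(x$sensory[[nm]]) / 2
    x$sensory[[nm]][, seq_len(d)] - x$eps[[paste0("s_", nm)]][, seq_len(d)]
  }))
  graphics::matplot(tt, pred, type = "l", lty = 1, col = "grey40",
                    xlab = "time (bins)", ylab = "prediction",
                    main = "sensory predictions and errors")
  err <- do.call(cbind, lapply(names(x$sensory), function(nm) {
    d <- ncol(x$sensory[[nm]]) / 2
    x$eps[[paste0("s_", nm)]][, seq_len(d)]
  }))
  graphics::matlines(tt, err, lty = 1, col = "red")
  xs <- mu_series(x, "x", 1)
  graphics::matplot(tt, xs, type = "l", lty = 1,
                    xlab = "time (bins)", ylab = "expectation",
                    main = "hidden states (level 1)")
  ctx <- context_cause(x)
  graphics::matplot(tt, ctx, type = "l", lty = 1, col = c("blue", "darkgreen"),
                    ylim = c(-0.2, 1.2), xlab = "time (bins)",
                    ylab = "context cause",
                    main = "context (blue seq / green random)")
  graphics::abline(h = 0.5, lty = 3)
  ext <- trace_extrinsic(x)
  L <- trace_locations(x)
  graphics::plot(ext[, 1], ext[, 2], type = "l", lty = 3,
                 xlim = range(c(ext[, 1], L$ext[1, ])) + c(-0.2, 0.2),
                 ylim = range(c(ext[, 2], L$ext[2, ])) + c(-0.2, 0.2),
                 xlab = "x (extrinsic)", ylab = "y (extrinsic)",
                 main = "trajectory")
  graphics::points(L$ext[1, ], L$ext[2, ], col = "darkgreen", cex = 3)
  graphics::text(L$ext[1, ], L$ext[2, ], labels = 1:4, col = "darkgreen")
  invisible(x)
}
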