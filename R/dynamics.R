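# Concrete nonlinearities of the reaching model: softmax selection (with its
# analytic first and second derivatives, needed for exact free-energy
# gradients), Lotka-Volterra winnerless competition among attractor states,
# the intrinsic (joint angle) <-> extrinsic (visual) tangent map, and the
# affordance-to-location readout.

#' Softmax function
#'
#' Numerically stable softmax; strictly positive, sums to one and preserves
#' the ordering of its input.
#'
#' @param x Real vector.
#' @return A vector on the probability simplex.
#' @export
softmax <- function(x) {
  if (any(!is.finite(x))) stop("`x` must be finite")
  e <- exp(x - max(x))
  e / sum(e)
}

#' Jacobian of the softmax function
#'
#' @param x Real vector.
#' @return The matrix `diag(s) - s s'` where `s = softmax(x)`.
#' @export
softmax_jac <- function(x) {
  s <- softmax(x)
  diag(s, length(s)) - tcrossprod(s)
}

# Contraction of the softmax Hessian with a direction u:
# M[i, j] = sum_l d2 s_i / (dx_l dx_j) u_l.  Closed form below; verified
# against finite differences of softmax_jac in the test suite.
softmax_hvp <- function(x, u) {
  s <- softmax(x)
  b <- u - sum(s * u)
  sb <- s * b
  diag(sb, length(s)) - tcrossprod(sb, s) - tcrossprod(s, sb)
}

#' Winnerless-competition attractor parameters
#'
#' Parameters of the generalized Lotka-Volterra flow used as a central
#' pattern generator: each attractor state rises in turn, exciting its cyclic
#' successor and suppressing the others, so the trajectory visits the states
#' in a fixed order (a stable heteroclinic channel).
#'
#' Defaults (for the fast, four-state affordance cycle) were tuned once so
#' that, inside the full agent at nominal precision, one state is visited per
#' 12-bin cue interval; they are frozen here and fully config-overridable.
#'
#' @param n Number of attractor states.
#' @param excite Gain of the cyclic next-state excitation (> 0).
#' @param inhibit Gain of the lateral inhibition (> 0).
#' @param decay Leak time constant, in time bins (> 0).
#' @param drive Constant offset of the flow.
#' @return An object of class `af_attractor`.
#' @export
attractor_params <- function(n = 4L, excite = 1.2, inhibit = 1.1,
                             decay = 8, drive = 0.3) {
  if (excite <= 0 || inhibit <= 0 || decay <= 0)
    stop("`excite`, `inhibit` and `decay` must be positive")
  structure(list(n = as.integer(n), excite = excite, inhibit = inhibit,
                 decay = decay, drive = drive),
            class = "af_attractor")
}

#' Transition matrix of the winnerless competition
#'
#' Builds `A = excite * C - inhibit * (J - I)` where `C` is the cyclic
#' next-state permutation matrix, `J` the all-ones matrix and `I` the
#' identity: the current winner excites its successor and inhibits the rest.
#'
#' @param p An [attractor_params()] object.
#' @return An `n` x `n` matrix.
#' @export
wlc_transition <- function(p) {
  n <- p$n
  C <- matrix(0, n, n)
  C[cbind(seq_len(n) %% n + 1L, seq_len(n))] <- 1
  p$excite * C - p$inhibit * (matrix(1, n, n) - diag(n))
}

#' Winnerless-competition flow
#'
#' The equation of motion `dx/dt = speed * A softmax(x) - x / decay + drive`.
#' The speed variable scales only the coupling through the transition matrix
#' `A`, so it controls how fast the unstable fixed points are visited.
#'
#' @param x State vector of length `p$n`.
#' @param speed Non-negative scalar scaling the transition matrix.
#' @param p An [attractor_params()] object.
#' @return The flow `dx/dt`.
#' @export
wlc_flow <- function(x, speed, p) {
  if (length(x) != p$n) stop("`x` must have length `p$n`")
  A <- wlc_transition(p)
  drop(speed * (A %*% softmax(x))) - x / p$decay + p$drive
}

#' Target location map
#'
#' Extrinsic (visual) coordinates of the four reach targets, clockwise from
#' the upper-right corner of a square centred on the resting position, and
#' the corresponding intrinsic joint angles under the inverse tangent map.
#'
#' @param half_width Half the side of the target square in extrinsic units.
#' @return An object of class `af_locations` with fields `ext` and `int`
#'   (2 x 4 matrices, column j = target j).
#' @export
location_map <- function(half_width = 1) {
  ext <- half_width * rbind(c(1, 1, -1, -1),
                            c(1, -1, -1, 1))
  structure(list(ext = ext, int = atan(ext)), class = "af_locations")
}

#' Intrinsic to extrinsic coordinate map
#'
#' The elementwise tangent map from joint angles (intrinsic, proprioceptive
#' frame) to positions (extrinsic, visual frame); strictly monotone with
#' inverse [extrinsic_to_intrinsic()].
#'
#' @param angles Vector of joint angles in `(-pi/2, pi/2)`.
#' @return Extrinsic coordinates, same length as `angles`.
#' @export
intrinsic_to_extrinsic <- function(angles) {
  if (any(!is.finite(angles)) || any(abs(angles) >= pi / 2))
    stop("angles must lie strictly inside (-pi/2, pi/2)")
  tan(angles)
}

#' Extrinsic to intrinsic coordinate map
#'
#' @param pos Vector of extrinsic coordinates.
#' @return Joint angles in `(-pi/2, pi/2)`.
#' @export
extrinsic_to_intrinsic <- function(pos) atan(pos)

#' Location afforded by a set of affordance states
#'
#' The softmax-weighted combination of the target joint angles: the hidden
#' state with the largest affordance predominates, so the readout lies in the
#' convex hull of the four target angle pairs.
#'
#' @param x_aff Affordance state vector (length 4 for the default map).
#' @param L An [location_map()] object.
#' @return A 2-vector of intrinsic joint angles.
#' @export
afforded_target <- function(x_aff, L) {
  drop(L$int %*% softmax(x_aff))
}
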