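# Algebra of generalized coordinates of motion: a time-varying quantity is
# represented by its value and successive temporal derivatives ("~" variables).
# A generalized vector of embedding order K over a base dimension m is stored
# as an m x K matrix (column k+1 = k-th derivative) or, flattened column-wise,
# as a vector with K contiguous order blocks.

#' Block-shift (derivative) operator over generalized coordinates
#'
#' Returns the matrix differential operator `D` that maps a flattened
#' generalized vector onto its generalized motion: every derivative block is
#' shifted up one order and the top block is zeroed. `D` is nilpotent of
#' index `order`.
#'
#' @param order Number of derivative orders carried (>= 1).
#' @param dim Base dimension of the quantity (>= 1).
#' @return A square matrix of size `order * dim`.
#' @examples
#' D <- shift_operator(2, 1)
#' D %*% c(1, 5)  # (value, velocity) -> (velocity, 0)
#' @export
shift_operator <- function(order, dim) {
  if (length(order) != 1L || !is.finite(order) || order < 1)
    stop("`order` must be a positive integer")
  if (length(dim) != 1L || !is.finite(dim) || dim < 1)
    stop("`dim` must be a positive integer")
  order <- as.integer(order)
  dim <- as.integer(dim)
  S <- matrix(0, order, order)
  if (order > 1L) {
    idx <- seq_len(order - 1L)
    S[cbind(idx, idx + 1L)] <- 1
  }
  kronecker(S, diag(dim))
}

double_factorial <- function(k) {
  # (2k-1)!! with the usual convention (-1)!! = 1
  if (k <= 0) return(1)
  prod(seq(1, 2 * k - 1, by = 2))
}

#' Covariance of derivative orders under a Gaussian autocorrelation
#'
#' For fluctuations with autocorrelation \eqn{\rho(t) = \exp(-t^2 / (2 s^2))}
#' the vector of temporal derivatives \eqn{(z, z', z'', \dots)} has covariance
#' \eqn{C_{ij} = (-1)^i \rho^{(i+j)}(0)}, which vanishes for odd \eqn{i + j}
#' and equals \eqn{(2k-1)!! / s^{2k}} in magnitude for \eqn{i + j = 2k}.
#'
#' @param order Number of derivative orders (>= 1).
#' @param smoothness Correlation length `s` of the fluctuations, in time bins.
#' @return An `order` x `order` covariance (correlation) matrix.
#' @export
deriv_autocorr <- function(order, smoothness) {
  if (length(smoothness) != 1L || !is.finite(smoothness) || smoothness <= 0)
    stop("`smoothness` must be positive")
  if (order < 1) stop("`order` must be a positive integer")
  order <- as.integer(order)
  S <- matrix(0, order, order)
  for (i in 0:(order - 1L)) {
    for (j in 0:(order - 1L)) {
      if ((i + j) %% 2L == 0L) {
        k <- (i + j) / 2
        S[i + 1L, j + 1L] <-
          (-1)^i * (-1)^k * double_factorial(k) / smoothness^(2 * k)
      }
    }
  }
  S
}

#' Precision over generalized coordinates
#'
#' Extends a base precision \eqn{e^{\lambda}} across derivative orders, under
#' the assumption that the fluctuations are analytic with a Gaussian
#' autocorrelation of the stated smoothness: the generalized precision is the
#' Kronecker product of the inverse derivative-order correlation matrix with
#' the base precision. The result is symmetric positive definite.
#'
#' @param base_log_precision Log precision \eqn{\lambda} of the order-0
#'   fluctuations (precision is \eqn{e^{\lambda}}).
#' @param order Number of derivative orders (>= 1).
#' @param smoothness Correlation length of the fluctuations (time bins).
#' @param dim Base dimension of the error stream (default 1); the same scalar
#'   precision is applied to every component.
#' @return A square matrix of size `order * dim` acting on flattened
#'   generalized vectors (order blocks contiguous).
#' @export
generalized_precision <- function(base_log_precision, order, smoothness,
                                  dim = 1L) {
  if (order < 1) stop("`order` must be a positive integer")
  if (length(smoothness) != 1L || !is.finite(smoothness) || smoothness <= 0)
    stop("`smoothness` must be positive")
  # invert the unit-smoothness correlation matrix and rescale derivative
  # orders afterwards: the direct inverse is numerically singular for small
  # smoothness at high orders, the rescaled one is not
  C <- deriv_autocorr(order, 1)
  Dsc <- diag(smoothness^(seq_len(order) - 1), order)
  R <- Dsc %*% solve(C) %*% Dsc
  P <- exp(base_log_precision) * kronecker(R, diag(as.integer(dim)))
  (P + t(P)) / 2
}

smooth_kernel <- function(order, tt, sig) {
  # order-th derivative of exp(-t^2 / (2 sig^2)), up to the common Gaussian
  k0 <- exp(-tt^2 / (2 * sig^2))
  switch(as.character(order),
    "0" = k0,
    "1" = (-tt / sig^2) * k0,
    "2" = (tt^2 / sig^4 - 1 / sig^2) * k0,
    stop("smooth noise supports derivative orders 0..2")
  )
}

#' Sample smooth (analytic) random fluctuations
#'
#' Generates Gaussian noise whose autocorrelation is Gaussian with the stated
#' smoothness and whose order-0 marginal variance is \eqn{e^{-\lambda}},
#' together with its temporal derivatives. Paths are produced by convolving a
#' white-noise sequence with a Gaussian kernel (and the kernel's analytic
#' derivatives), so value and derivative blocks describe one underlying
#' analytic path.
#'
#' @param n_bins Number of time bins to sample (>= 1).
#' @param dim Number of independent components.
#' @param log_precision Log precision \eqn{\lambda}; the marginal standard
#'   deviation of the order-0 path is \eqn{e^{-\lambda/2}}.
#' @param smoothness Correlation length of the autocorrelation (time bins).
#' @param seed Integer seed; identical seeds give bit-identical paths. `NULL`
#'   leaves the random number generator state untouched.
#' @param n_orders Number of derivative orders to return (1..3).
#' @return An array of dimension `n_bins x dim x n_orders`.
#' @export
sample_smooth_noise <- function(n_bins, dim, log_precision, smoothness,
                                seed = NULL, n_orders = 1L) {
  if (length(n_bins) != 1L || n_bins < 1) stop("`n_bins` must be >= 1")
  if (smoothness <= 0) stop("`smoothness` must be positive")
  if (n_orders < 1 || n_orders > 3) stop("`n_orders` must be in 1..3")
  n_bins <- as.integer(n_bins)
  dim <- as.integer(dim)
  if (!is.null(seed)) set.seed(as.integer(seed))
  sig <- smoothness / sqrt(2)           # kernel width giving autocorr width s
  m <- max(3L, as.integer(ceiling(6 * sig)))
  tt <- seq.int(-m, m)
  k0 <- smooth_kernel(0, tt, sig)
  scale <- exp(-log_precision / 2) / sqrt(sum(k0^2))
  kernels <- lapply(seq_len(n_orders) - 1L, function(r)
    scale * smooth_kernel(r, tt, sig))
  out <- array(0, c(n_bins, dim, n_orders))
  for (j in seq_len(dim)) {
    w <- stats::rnorm(n_bins + 2L * m)
    for (r in seq_len(n_orders)) {
      # filter() computes sum_i kern[i] * w[t + m + 1 - i]: a convolution, so
      # the derivative kernels yield the derivative of the order-0 path
      y <- stats::filter(w, kernels[[r]], method = "convolution", sides = 2)
      out[, j, r] <- y[(m + 1L):(m + n_bins)]
    }
  }
  out
}
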