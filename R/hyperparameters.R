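#' Convert the shrinkage weight alpha to the matrix-F degrees of freedom nu
#'
#' The hierarchical matrix-F prior is parameterized either by the Wishart
#' degrees of freedom \eqn{\nu > p - 1} or, more interpretably, by the
#' shrinkage weight \eqn{\alpha = (\nu - p - 1)/(\nu + n - p - 1) \in [0, 1)}
#' that blends the prior target \eqn{\Phi} with the sample covariance in the
#' conditional mode of the precision matrix. This function inverts that map:
#' \deqn{\nu = p + 1 + \alpha n / (1 - \alpha).}
#'
#' @param alpha Shrinkage weight in `[0, 1)`. `alpha = 0` corresponds to the
#'   minimally informative prior (`nu = p + 1`); values near 1 shrink hard
#'   towards the hierarchical target.
#' @param n Number of samples (positive integer).
#' @param p Number of variables (positive integer).
#' @return The degrees of freedom `nu` (a scalar `> p - 1`).
#' @seealso [delta_from_beta()], [hmf_control()]
#' @export
#' @examples
#' nu_from_alpha(0.5, n = 100, p = 10)  # 111
nu_from_alpha <- function(alpha, n, p) {
  stopifnot(is.numeric(alpha), length(alpha) == 1L, is.finite(alpha))
  if (alpha < 0 || alpha >= 1) {
    stop("`alpha` must lie in [0, 1); got ", alpha, call. = FALSE)
  }
  stopifnot(n >= 1, p >= 1)
  p + 1 + alpha * n / (1 - alpha)
}

#' Convert the off-diagonal shrinkage weight beta to the tail parameter delta
#'
#' The second degree-of-freedom parameter of the matrix-F prior, \eqn{\delta >
#' 0}, controls the tails; its interpretable counterpart is \eqn{\beta =
#' (\delta + p - 1)/(\delta + \nu - 2)}, the weight placed on the diagonal
#' target matrix B in the conditional mode of \eqn{\Phi}. Inversion gives
#' \deqn{\delta = (\beta(\nu - 2) - (p - 1)) / (1 - \beta),}
#' which is positive only when \eqn{\beta > (p - 1)/(\nu - 2)}: the admissible
#' range of `beta` depends on `nu`.
#'
#' @param beta Shrinkage weight in `(0, 1)`.
#' @param nu Degrees of freedom, `> p - 1` (see [nu_from_alpha()]).
#' @param p Number of variables.
#' @return The tail parameter `delta` (a positive scalar).
#' @export
#' @examples
#' delta_from_beta(0.9, nu = 111, p = 10)  # 891
delta_from_beta <- function(beta, nu, p) {
  stopifnot(is.numeric(beta), length(beta) == 1L, is.finite(beta))
  if (beta <= 0 || beta >= 1) {
    stop("`beta` must lie in (0, 1); got ", beta, call. = FALSE)
  }
  if (abs(nu - (p + 1)) < .Machine$double.eps^0.5) {
    stop("degenerate parameterization: with nu = p + 1 the map beta(delta) ",
         "is constant (= 1) and cannot be inverted", call. = FALSE)
  }
  delta <- (beta * (nu - 2) - (p - 1)) / (1 - beta)
  if (delta <= 0) {
    stop(sprintf(
      "beta = %g is below the admissible lower bound (p-1)/(nu-2) = %g; delta would be <= 0",
      beta, (p - 1) / (nu - 2)), call. = FALSE)
  }
  delta
}

#' Hyperparameters and convergence controls for the hierarchical matrix-F model
#'
#' Bundles the two shrinkage weights with the gamma-prior constants on the
#' diagonal target and the GEM stopping rule. Defaults follow the model's
#' reference settings: `beta = 0.9`, `epsilon1 = epsilon2 = 0.001`,
#' `stop_criterion = 1e-6` (relative Frobenius change), `max_iters = 1000`.
#'
#' @param alpha Shrinkage weight for the precision-matrix update, in `[0, 1)`.
#' @param beta Shrinkage weight for the scale-matrix update, in `(0, 1]`.
#' @param epsilon1,epsilon2 Shape and rate of the Gamma prior on the diagonal
#'   entries of the target matrix B; small values approximate a flat prior on
#'   the log scale while keeping the posterior proper.
#' @param max_iters Maximum number of GEM iterations.
#' @param stop_criterion Convergence tolerance on the relative Frobenius
#'   change of the precision matrix between iterations.
#' @return An object of class `"hmf_control"`.
#' @export
hmf_control <- function(alpha = 0.5, beta = 0.9,
                        epsilon1 = 0.001, epsilon2 = 0.001,
                        max_iters = 1000L, stop_criterion = 1e-6) {
  stopifnot(is.numeric(alpha), length(alpha) == 1L,
            is.numeric(beta), length(beta) == 1L,
            epsilon1 > 0, epsilon2 > 0,
            max_iters >= 1, stop_criterion > 0)
  if (alpha < 0 || alpha >= 1) stop("`alpha` must lie in [0, 1)", call. = FALSE)
  if (beta <= 0 || beta > 1) stop("`beta` must lie in (0, 1]", call. = FALSE)
  structure(
    list(alpha = alpha, beta = beta,
         epsilon1 = epsilon1, epsilon2 = epsilon2,
         max_iters = as.integer(max_iters),
         stop_criterion = stop_criterion),
    class = "hmf_control")
}

#' @export
print.hmf_control <- function(x, ...) {
  cat("Hierarchical matrix-F hyperparameters\n")
  cat(sprintf("  alpha = %g, beta = %g\n", x$alpha, x$beta))
  cat(sprintf("  gamma prior on diag(B): shape %g, rate %g\n",
              x$epsilon1, x$epsilon2))
  cat(sprintf("  GEM: max %d iters, stop at relative F-norm < %g\n",
              x$max_iters, x$stop_criterion))
  invisible(x)
}
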