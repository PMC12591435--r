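# Symmetric positive-definite inverse via Cholesky; symmetrized on return to
# suppress floating-point asymmetry.
inv_spd <- function(M, what = "matrix") {
  ch <- tryCatch(chol(M), error = function(e) NULL)
  if (is.null(ch)) {
    stop("matrix to invert (", what, ") is not positive definite; ",
         "for singular sample covariances (p > n) use alpha > 0",
         call. = FALSE)
  }
  Minv <- chol2inv(ch)
  (Minv + t(Minv)) / 2
}

#' Conditional mode of the precision matrix
#'
#' The full conditional of the precision matrix \eqn{\Omega} is Wishart; in
#' the \eqn{(\alpha, \beta)} parameterization its mode is the inverse of a
#' linear blend of the hierarchical target and the sample covariance,
#' \deqn{\mathrm{Mode}(\Omega \mid \cdot) = (\alpha\Phi + (1-\alpha)S)^{-1},}
#' a form closely resembling Ledoit-Wolf linear shrinkage.
#'
#' @param phi Symmetric positive-definite p x p target matrix.
#' @param S Sample covariance matrix (divisor n).
#' @param alpha Shrinkage weight in `[0, 1]` (within the GEM loop `alpha < 1`).
#' @return The symmetrized mode, a symmetric positive-definite matrix.
#' @export
conditional_mode_omega <- function(phi, S, alpha) {
  inv_spd(alpha * phi + (1 - alpha) * S, what = "alpha*Phi + (1-alpha)*S")
}

#' Conditional mode of the hierarchical scale matrix
#'
#' The full conditional of the auxiliary scale matrix \eqn{\Phi} is Wishart
#' with mode
#' \deqn{\mathrm{Mode}(\Phi \mid \cdot) = (\beta B + (1-\beta)\Omega)^{-1},}
#' where B is the diagonal target whose entries carry gamma priors.
#'
#' @param omega Symmetric positive-definite p x p precision matrix.
#' @param b_diag Positive vector: the diagonal of B.
#' @param beta Shrinkage weight in `(0, 1]`.
#' @return The symmetrized mode.
#' @export
conditional_mode_phi <- function(omega, b_diag, beta) {
  if (any(b_diag <= 0)) stop("`b_diag` entries must be positive", call. = FALSE)
  M <- (1 - beta) * omega
  diag(M) <- diag(M) + beta * b_diag
  inv_spd(M, what = "beta*B + (1-beta)*Omega")
}

#' Conditional mode of the diagonal target entries
#'
#' Each diagonal entry `b_ii` of the target matrix has a gamma full
#' conditional with shape \eqn{(\delta + p - 1)/2 + \epsilon_1} and rate
#' \eqn{(\delta + p - 1)\phi_{ii}/2 + \epsilon_2}; its mode is
#' `(shape - 1) / rate`, defined only when the shape exceeds 1.
#'
#' @param phi_diag Positive vector, the diagonal of the current scale matrix.
#' @param delta Tail parameter of the matrix-F prior (`> 0`).
#' @param p Number of variables.
#' @param eps1,eps2 Gamma-prior shape and rate constants.
#' @return Positive vector of conditional modes.
#' @export
update_b_diag <- function(phi_diag, delta, p, eps1 = 0.001, eps2 = 0.001) {
  if (any(phi_diag <= 0)) stop("`phi_diag` entries must be positive", call. = FALSE)
  shape <- (delta + p - 1) / 2 + eps1
  if (shape <= 1) {
    stop("gamma full-conditional shape <= 1: the mode is undefined ",
         "(need delta + p - 1 > 2)", call. = FALSE)
  }
  rate <- (delta + p - 1) * phi_diag / 2 + eps2
  (shape - 1) / rate
}

#' Fit the hierarchical matrix-F model by generalized EM
#'
#' Computes the maximum a posteriori (MAP) precision matrix by iterated
#' conditional modes: starting from \eqn{B = \Phi = \Omega = I}, each sweep
#' updates the diagonal target entries `b_ii`, then the scale matrix
#' \eqn{\Phi}, then the precision matrix \eqn{\Omega}, each at the mode of its
#' full conditional. Iteration stops when the relative Frobenius change of
#' \eqn{\Omega} falls below `stop_criterion`. The algorithm is deterministic
#' (fixed identity initialization) and, because every update is a conditional
#' maximization of the posterior, is a generalized EM / ICM scheme; it visits
#' the same conditionals as the Gibbs sampler ([gibbs_fit()]) but takes modes
#' instead of draws.
#'
#' @param moments An [sample_moments()] object, or a raw data matrix (then
#'   standardized by default).
#' @param control An [hmf_control()] object with `alpha`, `beta`, the gamma
#'   constants and the stopping rule.
#' @param init Optional warm start: a list with elements `omega`, `phi`,
#'   `b_diag` (as returned in an `"hmf_fit"`), used by the condition-number
#'   search to seed consecutive fits. Default identity start.
#' @return An object of class `"hmf_fit"`: list with `omega` (MAP precision),
#'   `phi`, `b_diag`, `w` (the matrix \eqn{\hat W = (nS + (\nu-p-1)\hat\Phi)^{-1}}
#'   used by [edge_variances()]), `nu`, `delta`, `n_iters`, `converged`,
#'   `rel_change`, plus the `control` and `moments` used.
#' @seealso [edge_variances()], [select_alpha_cc()], [hmf_network()]
#' @export
#' @examples
#' net <- generate_scale_free(p = 12, seed = 1)
#' Y <- sample_mvn(net, n = 80, seed = 2)
#' fit <- gem_fit(Y, hmf_control(alpha = 0.3))
#' fit
gem_fit <- function(moments, control = hmf_control(), init = NULL) {
  moments <- as_moments(moments)
  S <- moments$S; n <- moments$n; p <- moments$p
  alpha <- control$alpha; beta <- control$beta
  nu <- nu_from_alpha(alpha, n, p)
  # beta = 1 is admissible as a pure limit (Phi target = B); delta is then
  # unbounded and the b/Phi updates use the limiting weights directly.
  delta <- if (control$beta < 1) delta_from_beta(beta, nu, p) else Inf
  dp1 <- if (is.finite(delta)) delta + p - 1 else Inf

  if (is.null(init)) {
    b_diag <- rep(1, p)
    phi <- diag(p)
    omega <- diag(p)
  } else {
    b_diag <- init$b_diag; phi <- init$phi; omega <- init$omega
    stopifnot(length(b_diag) == p, all(dim(phi) == p), all(dim(omega) == p))
  }

  core <- .gem_core(S, alpha, beta, delta,
                    control$epsilon1, control$epsilon2,
                    control$max_iters, control$stop_criterion,
                    b_diag, phi, omega)

  w <- inv_spd(n * S + (nu - p - 1) * core$phi, what = "nS + (nu-p-1)*Phi")
  structure(
    list(omega = core$omega, phi = core$phi, b_diag = as.numeric(core$b_diag),
         w = w, nu = nu, delta = delta,
         n_iters = core$n_iters, converged = core$converged,
         rel_change = core$rel_change,
         control = control, moments = moments),
    class = "hmf_fit")
}

#' @export
print.hmf_fit <- function(x, ...) {
  cat("Hierarchical matrix-F GGM fit (GEM)\n")
  cat(sprintf("  p = %d variables, n = %d samples\n", x$moments$p, x$moments$n))
  cat(sprintf("  alpha = %.4g, beta = %.3g (nu = %.4g, delta = %.4g)\n",
              x$control$alpha, x$control$beta, x$nu, x$delta))
  cat(sprintf("  %d iterations, %s (final relative F-norm change %.3g)\n",
              x$n_iters,
              if (x$converged) "converged" else "NOT converged", x$rel_change))
  invisible(x)
}
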