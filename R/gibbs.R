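#' Reference Gibbs sampler for the hierarchical matrix-F model
#'
#' Cycles the three full conditionals in the same order as the GEM sweep:
#' \deqn{b_{ii} \mid \cdot \sim \mathrm{Gamma}\big((\delta+p-1)/2 + \epsilon_1,\;
#'   (\delta+p-1)\phi_{ii}/2 + \epsilon_2\big),}
#' \deqn{\Phi \mid \cdot \sim W\big(\delta+\nu+p-1,\;
#'   ((\delta+p-1)B + (\nu-p-1)\Omega)^{-1}\big),}
#' \deqn{\Omega \mid \cdot \sim W\big(\nu+n,\; ((\nu-p-1)\Phi + nS)^{-1}\big).}
#' Taking the mode of each conditional instead of a draw reproduces
#' [gem_fit()] exactly; the sampler is the reference for the posterior shape
#' (credible intervals) that the GEM point estimate alone cannot provide.
#' Wishart draws use `stats::rWishart` (Bartlett decomposition), so runs are
#' reproducible given `seed`.
#'
#' @inheritParams gem_fit
#' @param n_iters Total Gibbs iterations (default 5000).
#' @param burn_in Iterations discarded from the front (default half).
#' @param seed Integer seed for reproducibility.
#' @param keep_phi Also store the `phi` draws (memory heavy; default `FALSE`).
#' @return An object of class `"hmf_draws"`: list with `omega_draws`
#'   (p x p x n_kept array of post-burn-in precision draws), `n_draws`,
#'   `burn_in`, `seed`, `nu`, `delta`, and the `control`/`moments` used.
#' @export
gibbs_fit <- function(moments, control = hmf_control(), n_iters = 5000L,
                      burn_in = floor(n_iters / 2), seed = 1L,
                      keep_phi = FALSE) {
  moments <- as_moments(moments)
  S <- moments$S; n <- moments$n; p <- moments$p
  stopifnot(n_iters > 0, burn_in >= 0, burn_in < n_iters)
  alpha <- control$alpha; beta <- control$beta
  nu <- nu_from_alpha(alpha, n, p)
  delta <- delta_from_beta(beta, nu, p)
  dp1 <- delta + p - 1
  shape <- dp1 / 2 + control$epsilon1

  set.seed(as.integer(seed))
  phi <- diag(p); omega <- diag(p)
  n_keep <- n_iters - burn_in
  omega_draws <- array(NA_real_, c(p, p, n_keep))
  phi_draws <- if (keep_phi) array(NA_real_, c(p, p, n_keep)) else NULL
  nS <- n * S

  for (it in seq_len(n_iters)) {
    b_diag <- stats::rgamma(p, shape = shape,
                            rate = dp1 * diag(phi) / 2 + control$epsilon2)
    scale_phi <- inv_spd(diag(dp1 * b_diag, p) + (nu - p - 1) * omega,
                         what = "Phi conditional scale")
    phi <- stats::rWishart(1L, df = delta + nu + p - 1, Sigma = scale_phi)[, , 1L]
    phi <- (phi + t(phi)) / 2
    scale_omega <- inv_spd((nu - p - 1) * phi + nS,
                           what = "Omega conditional scale")
    omega <- stats::rWishart(1L, df = nu + n, Sigma = scale_omega)[, , 1L]
    omega <- (omega + t(omega)) / 2
    if (it > burn_in) {
      omega_draws[, , it - burn_in] <- omega
      if (keep_phi) phi_draws[, , it - burn_in] <- phi
    }
  }

  structure(
    list(omega_draws = omega_draws, phi_draws = phi_draws,
         n_draws = n_keep, burn_in = as.integer(burn_in),
         seed = as.integer(seed), nu = nu, delta = delta,
         control = control, moments = moments),
    class = "hmf_draws")
}

#' @export
print.hmf_draws <- function(x, ...) {
  cat("Hierarchical matrix-F GGM posterior draws (Gibbs)\n")
  cat(sprintf("  p = %d, n = %d; %d kept draws after burn-in %d (seed %d)\n",
              x$moments$p, x$moments$n, x$n_draws, x$burn_in, x$seed))
  invisible(x)
}

#' Equal-tailed credible intervals from Gibbs draws
#'
#' Per-entry empirical quantile intervals of the precision-matrix draws, used
#' to validate the normal approximation of [credible_interval()].
#'
#' @param draws An `"hmf_draws"` object.
#' @param gamma Credible mass in `[0, 1)`.
#' @return List of two p x p matrices, `lo` and `hi`.
#' @export
gibbs_ci <- function(draws, gamma = 0.9) {
  stopifnot(inherits(draws, "hmf_draws"), gamma >= 0, gamma < 1)
  probs <- c((1 - gamma) / 2, (1 + gamma) / 2)
  qs <- apply(draws$omega_draws, c(1L, 2L), stats::quantile, probs = probs)
  list(lo = qs[1L, , ], hi = qs[2L, , ])
}
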