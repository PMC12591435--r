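#' Condition number of a symmetric positive-definite matrix
#'
#' Ratio of the largest to the smallest eigenvalue, from a symmetric
#' eigendecomposition. Used as the well-conditioning criterion that drives
#' the shrinkage-weight selection.
#'
#' @param omega Symmetric positive-definite matrix.
#' @return A scalar `>= 1`.
#' @export
condition_number <- function(omega) {
  ev <- eigen(omega, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 0) {
    stop("matrix is not positive definite (smallest eigenvalue ",
         format(min(ev)), ")", call. = FALSE)
  }
  max(ev) / min(ev)
}

#' Ledoit-Wolf linear-shrinkage covariance estimate
#'
#' The classic linear shrinkage estimator: a convex combination of the sample
#' covariance (divisor n, after centering) and the scaled identity
#' \eqn{\mu I} with \eqn{\mu = \mathrm{tr}(S)/p}, with analytically estimated
#' shrinkage intensity. Always positive definite, also when `p > n`.
#'
#' @param Y Numeric data matrix, samples in rows. Columns are centered; set
#'   `standardize = TRUE` to also scale them to unit variance.
#' @param standardize Scale columns to unit SD before estimating.
#' @return A list with `sigma` (the shrunken covariance), `shrinkage` (the
#'   estimated intensity in `[0, 1]`), and `mu`.
#' @export
ledoit_wolf_cov <- function(Y, standardize = FALSE) {
  Y <- as.matrix(Y)
  n <- nrow(Y); p <- ncol(Y)
  stopifnot(n >= 2, p >= 1)
  X <- sweep(Y, 2L, colMeans(Y), "-")
  if (standardize) {
    sds <- sqrt(colMeans(X^2))
    if (any(sds == 0)) stop("constant column: cannot standardize", call. = FALSE)
    X <- sweep(X, 2L, sds, "/")
  }
  S <- crossprod(X) / n
  mu <- sum(diag(S)) / p
  if (mu == 0) stop("degenerate data: zero total variance", call. = FALSE)
  delta2 <- sum((S - diag(mu, p))^2) / p
  # dispersion of the per-sample outer products around S:
  # (1/n^2) sum_k ||x_k x_k' - S||_F^2 / p, computed without forming the
  # n outer products: sum_k ||x_k x_k'||^2 = sum_k (x_k'x_k)^2 and the cross
  # term sums to n ||S||^2.
  sq_norms <- rowSums(X^2)
  beta_bar2 <- (sum(sq_norms^2) - n * sum(S^2)) / (n^2 * p)
  b2 <- min(beta_bar2, delta2)
  rho <- if (delta2 > 0) b2 / delta2 else 1
  sigma <- rho * diag(mu, p) + (1 - rho) * S
  list(sigma = (sigma + t(sigma)) / 2, shrinkage = rho, mu = mu)
}

#' Condition-number benchmark from the Ledoit-Wolf estimate
#'
#' Computes the Ledoit-Wolf linear-shrinkage covariance of the data and
#' returns its condition number, which serves as the upper limit
#' \eqn{\kappa_{\max}} in the condition-number-constraint (CC) selection of
#' the shrinkage weight. The condition number is identical for the covariance
#' and its inverse (the eigenvalue ratio is reciprocal-invariant), so no
#' inversion is needed.
#'
#' @inheritParams ledoit_wolf_cov
#' @return A scalar condition number `> 1`.
#' @export
lw_condition_bound <- function(Y, standardize = TRUE) {
  lw <- ledoit_wolf_cov(Y, standardize = standardize)
  condition_number(lw$sigma)
}

#' Heuristic shrinkage weight for cluster-friendly estimates
#'
#' The fixed rule \eqn{\alpha = 10p/(10p + n)}: deliberately larger than the
#' CC-selected weight, trading edge-recovery accuracy for denser, more
#' clustered estimates that help community detection.
#'
#' @param n,p Sample size and number of variables.
#' @return A scalar in `(0, 1)`.
#' @export
alpha_heuristic <- function(n, p) 10 * p / (10 * p + n)

#' Select the shrinkage weight by the condition-number constraint (CC method)
#'
#' Chooses the smallest shrinkage weight \eqn{\alpha} whose MAP precision
#' matrix satisfies \eqn{\mathrm{Cond}(\hat\Omega_\alpha) < \kappa_{\max}},
#' by bisection over a bracket in `(0, 1)`. By default the limit
#' \eqn{\kappa_{\max}} is the condition number of the Ledoit-Wolf estimate of
#' the same data ([lw_condition_bound()]). Consecutive GEM fits are
#' warm-started from the previous solution, which changes runtime only: the
#' returned weight agrees with a cold-start search to within `alpha_tol`.
#' Bisection assumes the condition number is non-increasing in `alpha`; if an
#' inverted bracket is detected (feasible low end, infeasible high end) the
#' search falls back to a grid scan with a warning.
#'
#' @inheritParams gem_fit
#' @param kappa_max The constraint (`> 1`); default computed from the data by
#'   [lw_condition_bound()].
#' @param alpha_tol Bracket width at which bisection stops (default 0.005).
#' @param bracket Search interval for `alpha` (default `c(0.001, 0.999)`).
#' @param control Hyperparameters for each GEM fit; its `alpha` is ignored.
#' @return An object of class `"hmf_alpha_cc"`: list with `alpha_hat` (the
#'   upper, guaranteed-feasible end of the final bracket), `kappa_max`,
#'   `achieved_condition`, `n_gem_calls`, `search_trace` (data frame of
#'   `(alpha, condition)` pairs), and `fit`, the converged GEM fit at
#'   `alpha_hat` (reusable downstream without refitting).
#' @export
#' @examples
#' net <- generate_scale_free(p = 15, seed = 1)
#' Y <- sample_mvn(net, n = 60, seed = 2)
#' sel <- select_alpha_cc(Y)
#' sel$alpha_hat
select_alpha_cc <- function(moments, control = hmf_control(),
                            kappa_max = NULL, alpha_tol = 0.005,
                            bracket = c(0.001, 0.999)) {
  moments <- as_moments(moments)
  if (is.null(kappa_max)) kappa_max <- lw_condition_bound(moments$Y, standardize = FALSE)
  if (kappa_max <= 1) stop("`kappa_max` must exceed 1", call. = FALSE)
  stopifnot(length(bracket) == 2L, bracket[1] > 0, bracket[2] < 1,
            bracket[1] < bracket[2], alpha_tol > 0)
  # the admissible range of beta depends on nu (hence on alpha): delta > 0
  # requires nu > (p-1)/beta + 2. Intersect the bracket with the admissible
  # alpha region for the fixed beta so every GEM call is well defined.
  if (control$beta < 1) {
    t0 <- (moments$p - 1) / control$beta + 1 - moments$p
    if (t0 > 0) {
      alpha_min <- (t0 / (moments$n + t0)) * (1 + 1e-6) + 1e-9
      if (alpha_min >= bracket[2]) {
        stop("beta = ", control$beta, " admits no alpha inside the bracket",
             call. = FALSE)
      }
      bracket[1] <- max(bracket[1], alpha_min)
    }
  }

  trace_a <- numeric(0); trace_c <- numeric(0)
  n_calls <- 0L
  warm <- NULL
  eval_alpha <- function(alpha) {
    ctl <- control; ctl$alpha <- alpha
    fit <- gem_fit(moments, ctl, init = warm)
    warm <<- fit
    n_calls <<- n_calls + 1L
    cond <- condition_number(fit$omega)
    trace_a <<- c(trace_a, alpha); trace_c <<- c(trace_c, cond)
    list(fit = fit, cond = cond)
  }

  lo <- bracket[1]; hi <- bracket[2]
  at_hi <- eval_alpha(hi)
  if (at_hi$cond >= kappa_max) {
    at_lo <- eval_alpha(lo)
    stop(sprintf(
      "condition-number constraint infeasible on the bracket: Cond = %.3g at alpha = %g and %.3g at alpha = %g, kappa_max = %.3g",
      at_lo$cond, lo, at_hi$cond, hi, kappa_max), call. = FALSE)
  }
  at_lo <- eval_alpha(lo)
  if (at_lo$cond < kappa_max) {
    # constraint non-binding: smallest bracketed alpha already feasible
    out <- list(alpha_hat = lo, kappa_max = kappa_max,
                achieved_condition = at_lo$cond, n_gem_calls = n_calls,
                search_trace = data.frame(alpha = trace_a, condition = trace_c),
                fit = at_lo$fit)
    class(out) <- "hmf_alpha_cc"
    return(out)
  }

  best <- at_hi
  best_alpha <- hi
  while (hi - lo > alpha_tol) {
    mid <- (lo + hi) / 2
    at_mid <- eval_alpha(mid)
    if (at_mid$cond < kappa_max) {
      hi <- mid; best <- at_mid; best_alpha <- mid
    } else {
      lo <- mid
    }
  }

  out <- list(alpha_hat = best_alpha, kappa_max = kappa_max,
              achieved_condition = best$cond, n_gem_calls = n_calls,
              search_trace = data.frame(alpha = trace_a, condition = trace_c),
              fit = best$fit)
  class(out) <- "hmf_alpha_cc"
  out
}

#' @export
print.hmf_alpha_cc <- function(x, ...) {
  cat("CC-method shrinkage-weight selection\n")
  cat(sprintf("  alpha_hat = %.4g (Cond = %.4g < kappa_max = %.4g)\n",
              x$alpha_hat, x$achieved_condition, x$kappa_max))
  cat(sprintf("  %d GEM fits during the search\n", x$n_gem_calls))
  invisible(x)
}
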