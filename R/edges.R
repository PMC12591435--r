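#' Approximate posterior variances of the precision-matrix entries
#'
#' The posterior of each off-diagonal entry \eqn{\omega_{ij}} is approximated
#' by a normal distribution centered at the MAP with variance taken from the
#' Wishart full conditional of \eqn{\Omega}:
#' \deqn{\widehat{\mathrm{Var}}(\hat\omega_{ij}) =
#'   (\nu + n)(\hat w_{ij}^2 + \hat w_{ii}\hat w_{jj}),\qquad
#'   \hat W = (nS + (\nu - p - 1)\hat\Phi)^{-1}.}
#'
#' @param fit An `"hmf_fit"` from [gem_fit()].
#' @return Symmetric p x p matrix of approximate variances (diagonal included,
#'   following the Wishart formula; only off-diagonal entries are used for
#'   edge selection).
#' @export
edge_variances <- function(fit) {
  stopifnot(inherits(fit, "hmf_fit"))
  w <- fit$w
  if (!all(is.finite(w))) stop("non-finite entries in W", call. = FALSE)
  v <- (fit$nu + fit$moments$n) * (w^2 + tcrossprod(diag(w)))
  (v + t(v)) / 2
}

#' Normal-approximation credible interval for one entry
#'
#' Equal-tailed interval of the approximating normal posterior:
#' \eqn{\hat\omega_{ij} \pm \Phi^{-1}((1+\gamma)/2)\sqrt{\widehat{\mathrm{Var}}}}.
#'
#' @param omega_ij MAP estimate of the entry.
#' @param var_ij Approximate posterior variance (`> 0`).
#' @param gamma Credible mass in `[0, 1)`; `gamma = 0` gives a zero-width
#'   interval at the MAP.
#' @return Numeric vector `c(lo, hi)`.
#' @export
credible_interval <- function(omega_ij, var_ij, gamma) {
  if (any(var_ij <= 0)) stop("`var_ij` must be positive", call. = FALSE)
  stopifnot(gamma >= 0, gamma < 1)
  half <- stats::qnorm((1 + gamma) / 2) * sqrt(var_ij)
  c(omega_ij - half, omega_ij + half)
}

#' Adjacency matrix at a given credible level
#'
#' Declares an edge wherever zero falls outside the entry's approximate
#' credible interval, equivalently wherever
#' \eqn{|\hat\omega_{ij}|/\mathrm{sd}_{ij} > \Phi^{-1}((1+\gamma)/2)}.
#' The diagonal is forced to zero.
#'
#' @param omega MAP precision matrix (or any symmetric matrix of estimates).
#' @param sd Matching matrix of approximate posterior standard deviations.
#' @param gamma Credible mass in `[0, 1)`.
#' @return Symmetric binary matrix with zero diagonal.
#' @export
adjacency_at_gamma <- function(omega, sd, gamma) {
  stopifnot(all(dim(omega) == dim(sd)), gamma >= 0, gamma < 1)
  z <- stats::qnorm((1 + gamma) / 2)
  a <- (abs(omega) > z * sd) * 1L
  diag(a) <- 0L
  a
}

#' Permute variable values within each sample
#'
#' The permutation null for false-positive estimation: every row of the data
#' is independently shuffled, preserving each sample's multiset of values
#' exactly while destroying all between-variable correlation. Assumes the
#' variables are on a similar scale (standardize first).
#'
#' @param Y Numeric data matrix, samples in rows.
#' @param seed Integer seed.
#' @return Matrix of the same shape, each row a uniform-random permutation of
#'   the corresponding input row.
#' @export
permute_within_samples <- function(Y, seed) {
  Y <- as.matrix(Y)
  set.seed(as.integer(seed))
  p <- ncol(Y)
  if (p == 1L) return(Y)
  t(apply(Y, 1L, function(row) row[sample.int(p)]))
}

# Upper-triangle |omega|/sd z-scores of a fit, as a vector.
fit_z_scores <- function(fit) {
  sd <- sqrt(edge_variances(fit))
  z <- abs(fit$omega) / sd
  z[upper.tri(z)]
}

#' Permutation-estimated false-positive curve
#'
#' For each of `n_perm` permutation replicates the data rows are shuffled
#' ([permute_within_samples()]), the model is refit with the *same*
#' `(alpha, beta)` as the observed-data fit, and the number of edges selected
#' at every candidate credible level is counted. The false-positive estimate
#' at each level is the median count across replicates (all edges found in
#' permuted data are false by construction).
#'
#' Rather than a fixed grid of credible levels, the per-edge z-scores
#' \eqn{|\hat\omega_{ij}|/\mathrm{sd}_{ij}} of the observed fit are used as
#' the exhaustive set of decision thresholds: every achievable graph is
#' evaluated exactly, and a threshold maps back to the credible mass
#' \eqn{\gamma = 2\Phi(t) - 1}. Replicate k uses the deterministic child seed
#' `seed + k`, so results do not depend on execution order.
#'
#' @param fit The observed-data `"hmf_fit"` (carries the data and
#'   hyperparameters used for the refits).
#' @param n_perm Number of permutation replicates (default 50).
#' @param seed Master seed for the permutation streams.
#' @param gamma_grid Optional explicit vector of credible levels; default
#'   `NULL` scans the exact per-edge thresholds of the observed fit.
#' @return An object of class `"hmf_fp_curve"`: list with `thresholds`
#'   (decision z-thresholds, decreasing edge count), `gamma` (corresponding
#'   credible masses), `edge_counts` (observed-data edges at each threshold),
#'   `fp_hat` (median permutation counts), `per_permutation_counts`
#'   (n_thresholds x n_perm matrix), `n_perm`, `seed`.
#' @export
estimate_fp_curve <- function(fit, n_perm = 50L, seed = 1L, gamma_grid = NULL) {
  stopifnot(inherits(fit, "hmf_fit"), n_perm >= 1)
  moments <- fit$moments
  if (!moments$standardized) {
    warning("data were not standardized; the within-sample permutation null ",
            "assumes comparably scaled variables", call. = FALSE)
  }
  z_obs <- fit_z_scores(fit)

  if (is.null(gamma_grid)) {
    # thresholds between consecutive sorted observed z-scores: one per
    # achievable edge count, plus one above the maximum (empty graph)
    zs <- sort(unique(z_obs), decreasing = TRUE)
    thresholds <- c(zs[1] + 1, if (length(zs) > 1) (zs[-1] + zs[-length(zs)]) / 2,
                    max(zs[length(zs)] - 1, zs[length(zs)] / 2))
  } else {
    stopifnot(all(gamma_grid >= 0), all(gamma_grid < 1))
    thresholds <- stats::qnorm((1 + sort(gamma_grid, decreasing = TRUE)) / 2)
  }
  count_above <- function(z, thr) {
    # for each threshold, how many z exceed it (strictly)
    zs <- sort(z)
    length(z) - findInterval(thr, zs, left.open = FALSE)
  }
  edge_counts <- count_above(z_obs, thresholds)

  n_thr <- length(thresholds)
  counts <- matrix(NA_real_, n_thr, n_perm)
  ok <- logical(n_perm)
  for (k in seq_len(n_perm)) {
    res <- tryCatch({
      Yp <- permute_within_samples(moments$Y, seed = as.integer(seed) + k)
      # rows of moments$Y are already centered/scaled; refit on the permuted
      # copy without re-standardizing a second time
      mp <- sample_moments(Yp, standardize = moments$standardized)
      fp_fit <- gem_fit(mp, fit$control)
      count_above(fit_z_scores(fp_fit), thresholds)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      warning("permutation replicate ", k, " failed and was dropped: ",
              conditionMessage(res), call. = FALSE)
    } else {
      counts[, k] <- res
      ok[k] <- TRUE
    }
  }
  if (mean(ok) < 0.8) {
    stop("more than 20% of permutation replicates failed", call. = FALSE)
  }
  fp_hat <- apply(counts[, ok, drop = FALSE], 1L, stats::median)

  structure(
    list(thresholds = thresholds,
         gamma = pmax(2 * stats::pnorm(thresholds) - 1, 0),
         edge_counts = edge_counts, fp_hat = fp_hat,
         per_permutation_counts = counts[, ok, drop = FALSE],
         n_perm = sum(ok), seed = as.integer(seed)),
    class = "hmf_fp_curve")
}

#' @export
print.hmf_fp_curve <- function(x, ...) {
  cat(sprintf("Permutation false-positive curve: %d thresholds, %d permutations (seed %d)\n",
              length(x$thresholds), x$n_perm, x$seed))
  invisible(x)
}

#' Credible level meeting a target false discovery rate
#'
#' Returns the smallest credible level (narrowest interval, hence the most
#' discoveries) whose estimated FDR, `fp_hat / edge_counts`, does not exceed
#' the target. An empty graph has estimated FDR 0 by convention.
#'
#' @param edge_counts,fp_hat Curves on a common set of levels, as in
#'   [estimate_fp_curve()] (ordered by decreasing threshold / increasing
#'   edge count is not required).
#' @param gamma Credible masses matching the curves.
#' @param fdr_target Target FDR in `(0, 1)`.
#' @return List with `gamma` (selected level), `index` (position in the
#'   supplied curves), `fdr_hat` (estimated FDR there).
#' @export
gamma_for_target_fdr <- function(edge_counts, fp_hat, gamma, fdr_target) {
  stopifnot(length(edge_counts) == length(fp_hat),
            length(gamma) == length(edge_counts),
            fdr_target > 0, fdr_target < 1)
  fdr_hat <- ifelse(edge_counts > 0, fp_hat / edge_counts, 0)
  feasible <- which(fdr_hat <= fdr_target)
  if (length(feasible) == 0L) {
    warning("no credible level meets the target FDR; returning the widest ",
            "interval (near-empty graph)", call. = FALSE)
    idx <- which.max(gamma)
  } else {
    idx <- feasible[which.min(gamma[feasible])]
  }
  list(gamma = gamma[idx], index = idx, fdr_hat = fdr_hat[idx])
}

#' Credible level maximizing the permutation-estimated F1-score
#'
#' With \eqn{\widehat{TP} = \mathrm{edges} - \widehat{FP}} and
#' \eqn{\widehat{FN} = K - \widehat{TP}} (K the expected number of true
#' edges; rule of thumb K = p), the estimated score is
#' \deqn{\hat F_1 = 2\widehat{TP} / (2\widehat{TP} + \widehat{FP} + \widehat{FN}).}
#' Returns the level with maximal \eqn{\hat F_1}; ties break towards the
#' larger level (sparser graph).
#'
#' @inheritParams gamma_for_target_fdr
#' @param K Expected number of true edges (`>= 1`).
#' @return List with `gamma`, `index`, `f1_hat` (the estimated F1 there), and
#'   `f1_curve`.
#' @export
gamma_max_f1 <- function(edge_counts, fp_hat, gamma, K) {
  stopifnot(length(edge_counts) == length(fp_hat),
            length(gamma) == length(edge_counts), K >= 1)
  # the estimated counts are used as-is: when the graph holds more true
  # edges than the working guess K, the estimated FN goes negative and the
  # estimated F1 exceeds 1, which keeps the selector from capping the graph
  # at K edges; the argmax is still well defined
  tp_hat <- edge_counts - fp_hat
  fn_hat <- K - tp_hat
  denom <- 2 * tp_hat + fp_hat + fn_hat
  f1 <- ifelse(denom > 0, 2 * tp_hat / denom, 0)
  if (all(f1 <= 0)) {
    warning("estimated F1 is zero everywhere; returning the widest interval",
            call. = FALSE)
    idx <- which.max(gamma)
  } else {
    best <- which(f1 == max(f1))
    idx <- best[which.max(gamma[best])]
  }
  list(gamma = gamma[idx], index = idx, f1_hat = f1[idx], f1_curve = f1)
}
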