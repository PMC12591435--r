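#' Sample moments for the Gaussian graphical model
#'
#' Centers (and optionally standardizes) the columns of a samples-by-variables
#' matrix and computes the sample covariance with divisor `n`,
#' \eqn{S = Y^\top Y / n} after centering, matching the `nS` term of the
#' Gaussian likelihood the model is built on. The model assumes zero-mean
#' data, so centering is always applied.
#'
#' @param Y Numeric matrix (or data frame coercible to one), samples in rows,
#'   variables in columns. No missing values.
#' @param standardize Scale every column to unit standard deviation
#'   (divisor-`n` SD, so `diag(S) = 1`). Default `TRUE`: downstream
#'   permutation-based selection assumes comparably scaled variables.
#' @return An object of class `"hmf_moments"`: a list with `S` (p x p sample
#'   covariance), `n`, `p`, `standardized`, and `Y` (the centered/scaled data,
#'   kept for permutation refits and shrinkage benchmarks).
#' @export
#' @examples
#' Y <- matrix(rnorm(40), 10, 4)
#' m <- sample_moments(Y)
#' m$S[1:2, 1:2]
sample_moments <- function(Y, standardize = TRUE) {
  Y <- as.matrix(Y)
  if (!is.numeric(Y)) stop("`Y` must be numeric", call. = FALSE)
  if (anyNA(Y)) stop("`Y` contains missing values", call. = FALSE)
  n <- nrow(Y); p <- ncol(Y)
  if (n < 2L || p < 2L) stop("need n >= 2 samples and p >= 2 variables", call. = FALSE)
  Yc <- sweep(Y, 2L, colMeans(Y), "-")
  if (standardize) {
    sds <- sqrt(colMeans(Yc^2))
    if (any(sds == 0)) {
      bad <- which(sds == 0)
      nm <- colnames(Y)[bad]
      lbl <- if (is.null(nm)) paste(bad, collapse = ", ") else paste(nm, collapse = ", ")
      stop("cannot standardize constant column(s): ", lbl, call. = FALSE)
    }
    Yc <- sweep(Yc, 2L, sds, "/")
  }
  S <- crossprod(Yc) / n
  S <- (S + t(S)) / 2
  structure(
    list(S = S, n = n, p = p, standardized = isTRUE(standardize), Y = Yc),
    class = "hmf_moments")
}

#' @export
print.hmf_moments <- function(x, ...) {
  cat(sprintf("Sample moments: n = %d, p = %d%s\n", x$n, x$p,
              if (x$standardized) " (standardized)" else ""))
  invisible(x)
}

# Internal: accept either a data matrix or an hmf_moments object.
as_moments <- function(x, standardize = TRUE) {
  if (inherits(x, "hmf_moments")) x else sample_moments(x, standardize = standardize)
}
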