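# Small deterministic fixtures shared across test files.

# an SPD matrix with moderate correlation structure
ar_cov <- function(p, rho = 0.6) rho^abs(outer(seq_len(p), seq_len(p), "-"))

# moments object from a fixed-seed Gaussian draw
make_moments <- function(n, p, rho = 0.5, seed = 1, standardize = TRUE) {
  set.seed(seed)
  Y <- MASS::mvrnorm(n, rep(0, p), ar_cov(p, rho))
  sample_moments(Y, standardize = standardize)
}

# hand-built "hmf_fit" shell for formula-level tests of edge_variances
fake_fit <- function(w, nu, n) {
  p <- nrow(w)
  moments <- structure(list(S = diag(p), n = n, p = p,
                            standardized = TRUE, Y = NULL),
                       class = "hmf_moments")
  structure(list(omega = diag(p), phi = diag(p), b_diag = rep(1, p),
                 w = w, nu = nu, delta = 10, n_iters = 1L, converged = TRUE,
                 rel_change = 0, control = hmf_control(alpha = 0.5),
                 moments = moments),
            class = "hmf_fit")
}

# independent plain-R fixed-point iteration of the three conditional-mode
# updates (the oracle for the GEM core)
reference_gem <- function(S, n, alpha, beta, eps1 = 0.001, eps2 = 0.001,
                          iters = 5000) {
  p <- nrow(S)
  nu <- p + 1 + alpha * n / (1 - alpha)
  delta <- (beta * (nu - 2) - (p - 1)) / (1 - beta)
  dp1 <- delta + p - 1
  b <- rep(1, p); phi <- diag(p); omega <- diag(p)
  for (i in seq_len(iters)) {
    b <- (dp1 / 2 + eps1 - 1) / (dp1 * diag(phi) / 2 + eps2)
    phi <- solve(beta * diag(b, p) + (1 - beta) * omega)
    omega <- solve(alpha * phi + (1 - alpha) * S)
  }
  list(omega = omega, phi = phi, b = b)
}
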