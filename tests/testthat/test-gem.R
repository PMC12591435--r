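test_that("conditional modes reduce to their closed-form limits", {
  set.seed(2)
  A <- crossprod(matrix(rnorm(25), 5, 5)) + diag(5)
  S <- crossprod(matrix(rnorm(40, sd = 0.5), 8, 5)) / 8 + diag(5) * 0.2

  expect_equal(conditional_mode_omega(A, S, alpha = 1), solve(A), tolerance = 1e-10)
  expect_equal(conditional_mode_omega(A, S, alpha = 0), solve(S), tolerance = 1e-10)
  expect_equal(conditional_mode_omega(diag(5), diag(5), 0.37), diag(5))

  expect_equal(conditional_mode_phi(A, rep(1, 5), beta = 1), diag(5))
  expect_equal(conditional_mode_phi(A, rep(1, 5), beta = 0), solve(A), tolerance = 1e-10)
  # diagonal closure of the Phi update
  D <- diag(c(1, 2, 3))
  res <- conditional_mode_phi(D, c(2, 2, 2), beta = 0.5)
  expect_equal(res, diag(diag(res)))

  expect_error(conditional_mode_phi(A, c(1, -1, 1, 1, 1), 0.5), "positive")
  # alpha = 0 with a singular S cannot be inverted
  S_sing <- crossprod(matrix(rnorm(10), 2, 5)) / 2
  expect_error(conditional_mode_omega(A, S_sing, 0), "alpha")
})

test_that("diagonal-target update is the mode of the gamma full conditional", {
  expect_equal(update_b_diag(1, delta = 1000 - 4, p = 5, eps1 = 0.001, eps2 = 0.001),
               (500.001 - 1) / 500.001)
  # rate dominates for large phi_ii
  expect_lt(update_b_diag(1e9, delta = 100, p = 5), 1e-6)
  # grid-search oracle: the returned value maximizes the gamma log-density
  delta <- 37; p <- 6; phi_ii <- 2.3
  shape <- (delta + p - 1) / 2 + 0.001
  rate <- (delta + p - 1) * phi_ii / 2 + 0.001
  b_hat <- update_b_diag(phi_ii, delta, p)
  grid <- seq(b_hat * 0.5, b_hat * 1.5, length.out = 20001)
  ll <- stats::dgamma(grid, shape = shape, rate = rate, log = TRUE)
  expect_equal(grid[which.max(ll)], b_hat, tolerance = 1e-3)
  expect_error(update_b_diag(1, delta = 0.5, p = 2), "undefined")
})

test_that("GEM preserves diagonality for diagonal sample covariances", {
  p <- 5
  moments <- structure(list(S = diag(p), n = 100L, p = p,
                            standardized = TRUE, Y = NULL),
                       class = "hmf_moments")
  fit <- gem_fit(moments, hmf_control(alpha = 0.5, beta = 0.9))
  off <- fit$omega[upper.tri(fit$omega)]
  expect_identical(unname(off), rep(0, p * (p - 1) / 2))
  expect_true(fit$converged)
})

test_that("GEM agrees with an independent fixed-point implementation", {
  set.seed(7)
  S <- crossprod(matrix(rnorm(30), 10, 3)) / 10
  moments <- structure(list(S = S, n = 10L, p = 3L,
                            standardized = FALSE, Y = NULL),
                       class = "hmf_moments")
  fit <- gem_fit(moments, hmf_control(alpha = 0.5, beta = 0.9,
                                      stop_criterion = 1e-13, max_iters = 10000))
  ref <- reference_gem(S, n = 10, alpha = 0.5, beta = 0.9)
  expect_equal(fit$omega, ref$omega, tolerance = 1e-8)
  expect_equal(fit$phi, ref$phi, tolerance = 1e-8)
})

test_that("GEM satisfies the fixed-point equations and positive definiteness", {
  for (seed in 1:3) {
    m <- make_moments(60, 8, seed = seed)
    ctl <- hmf_control(alpha = 0.4, beta = 0.9)
    fit <- gem_fit(m, ctl)
    expect_true(fit$converged)
    # fixed-point consistency at the stop tolerance
    expect_equal(fit$omega, conditional_mode_omega(fit$phi, m$S, 0.4),
                 tolerance = 1e-5)
    expect_equal(fit$phi, conditional_mode_phi(fit$omega, fit$b_diag, 0.9),
                 tolerance = 1e-5)
    ev <- eigen(fit$omega, symmetric = TRUE, only.values = TRUE)$values
    expect_gt(min(ev), 0)
    ev_phi <- eigen(fit$phi, symmetric = TRUE, only.values = TRUE)$values
    expect_gt(min(ev_phi), 0)
    # W is symmetric
    expect_equal(fit$w, t(fit$w))
  }
})

test_that("increasing beta shrinks off-diagonal estimates towards zero", {
  m <- make_moments(40, 10, rho = 0.6, seed = 5)
  # beta's admissible range depends on nu: use alpha large enough
  maxes <- vapply(c(0.7, 0.8, 0.9, 0.99), function(beta) {
    fit <- gem_fit(m, hmf_control(alpha = 0.8, beta = beta))
    max(abs(fit$omega[upper.tri(fit$omega)]))
  }, numeric(1))
  expect_true(all(diff(maxes) <= 1e-8))
})

test_that("warm starts change the path, not the solution", {
  m <- make_moments(50, 6, seed = 9)
  ctl <- hmf_control(alpha = 0.5)
  cold <- gem_fit(m, ctl)
  other <- gem_fit(m, hmf_control(alpha = 0.7))
  warm <- gem_fit(m, ctl, init = other)
  expect_equal(cold$omega, warm$omega, tolerance = 1e-4)
})
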