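test_that("edge variances follow the Wishart-based formula", {
  # Var = (nu + n)(w_ij^2 + w_ii w_jj)
  f <- fake_fit(diag(2), nu = 3, n = 7)            # nu + n = 10
  expect_equal(edge_variances(f)[1, 2], 10)
  f2 <- fake_fit(diag(c(2, 3)), nu = 4, n = 6)
  expect_equal(edge_variances(f2)[1, 2], 10 * (0 + 2 * 3))
  # a nontrivial W
  W <- matrix(c(2, 0.5, 0.5, 1.5), 2, 2)
  f3 <- fake_fit(W, nu = 10, n = 10)
  expect_equal(edge_variances(f3)[1, 2], 20 * (0.25 + 3))
})

test_that("credible intervals use the probit quantile on the SD scale", {
  expect_equal(credible_interval(0.7, 0.04, gamma = 0), c(0.7, 0.7))
  gamma2 <- 2 * pnorm(2) - 1                        # z = 2
  expect_equal(credible_interval(0.5, 0.01, gamma2), c(0.3, 0.7), tolerance = 1e-12)
  expect_error(credible_interval(0.5, -1, 0.9), "positive")
})

test_that("interval containment and z-thresholding select identical edges", {
  set.seed(16)
  p <- 12
  omega <- matrix(rnorm(p * p, sd = 0.4), p, p); omega <- (omega + t(omega)) / 2
  sdm <- matrix(runif(p * p, 0.1, 0.5), p, p); sdm <- (sdm + t(sdm)) / 2
  for (gamma in c(0, 0.5, 0.9, 0.99)) {
    a_thr <- adjacency_at_gamma(omega, sdm, gamma)
    a_ci <- matrix(0L, p, p)
    for (i in 1:(p - 1)) for (j in (i + 1):p) {
      ci <- credible_interval(omega[i, j], sdm[i, j]^2, gamma)
      inside <- ci[1] <= 0 && 0 <= ci[2]
      a_ci[i, j] <- a_ci[j, i] <- as.integer(!inside)
    }
    expect_identical(a_thr, a_ci)
  }
  # gamma = 0: every nonzero entry is an edge; gamma -> 1: empty graph
  expect_equal(sum(adjacency_at_gamma(omega, sdm, 0)), p * p - p)
  expect_equal(sum(adjacency_at_gamma(omega, sdm, 1 - 1e-15)), 0)
  # an exactly-zero estimate is never selected
  omega[1, 2] <- omega[2, 1] <- 0
  expect_equal(adjacency_at_gamma(omega, sdm, 0)[1, 2], 0L)
})

test_that("within-sample permutation preserves row multisets and kills correlation", {
  set.seed(17)
  Y <- matrix(rnorm(20 * 6), 20, 6)
  Yp <- permute_within_samples(Y, seed = 1)
  for (i in 1:20) expect_equal(sort(Yp[i, ]), sort(Y[i, ]))
  expect_identical(permute_within_samples(Y, seed = 1),
                   permute_within_samples(Y, seed = 1))
  expect_identical(permute_within_samples(Y[, 1, drop = FALSE], seed = 2),
                   Y[, 1, drop = FALSE])
  # permuted iid data: off-diagonal correlations concentrate near zero
  Y2 <- matrix(rnorm(300 * 8), 300, 8)
  Y2p <- permute_within_samples(Y2, seed = 3)
  r <- cor(Y2p)
  expect_lt(mean(abs(r[upper.tri(r)])), 4 / sqrt(300))
})

test_that("the permutation FP curve is monotone and uses the median across replicates", {
  m <- make_moments(60, 15, rho = 0.45, seed = 18)
  fit <- gem_fit(m, hmf_control(alpha = 0.5))
  fc <- estimate_fp_curve(fit, n_perm = 5, seed = 4)
  # interval widening: both curves non-increasing in gamma
  ord <- order(fc$gamma)
  expect_true(all(diff(fc$edge_counts[ord]) <= 0))
  expect_true(all(diff(fc$fp_hat[ord]) <= 0))
  expect_true(all(fc$fp_hat <= 15 * 14 / 2))
  expect_equal(fc$fp_hat, apply(fc$per_permutation_counts, 1, median))
  # a single replicate: the median is that replicate
  fc1 <- estimate_fp_curve(fit, n_perm = 1, seed = 4)
  expect_equal(fc1$fp_hat, as.numeric(fc1$per_permutation_counts[, 1]))
  # explicit gamma grid interface
  fcg <- estimate_fp_curve(fit, n_perm = 2, seed = 4, gamma_grid = c(0.5, 0.9, 0.99))
  expect_equal(sort(fcg$gamma), c(0.5, 0.9, 0.99))
})

test_that("target-FDR selection picks the narrowest qualifying interval", {
  sel <- gamma_for_target_fdr(c(100, 80, 50), c(30, 12, 5),
                              gamma = c(0.8, 0.9, 0.95), fdr_target = 0.2)
  expect_equal(sel$gamma, 0.9)                      # 12/80 = 0.15 <= 0.2; 30/100 > 0.2
  expect_equal(sel$fdr_hat, 0.15)
  # fp identically zero: constraint met everywhere, smallest gamma wins
  sel0 <- gamma_for_target_fdr(c(10, 5), c(0, 0), c(0.5, 0.9), 0.2)
  expect_equal(sel0$gamma, 0.5)
  # every edge false: only empty graphs qualify (ratio defined as 0)
  sel1 <- gamma_for_target_fdr(c(10, 5, 0), c(10, 5, 0), c(0.5, 0.9, 0.99), 0.2)
  expect_equal(sel1$gamma, 0.99)
  expect_warning(gamma_for_target_fdr(c(10, 5), c(10, 5), c(0.5, 0.9), 0.2),
                 "target")
})

test_that("estimated-F1 maximization matches brute force and breaks ties sparsely", {
  expect_equal(gamma_max_f1(60, 10, gamma = 0.9, K = 100)$f1_hat,
               100 / (100 + 10 + 50))               # TP=50, FP=10, K=100
  expect_equal(gamma_max_f1(100, 0, gamma = 0.9, K = 100)$f1_hat, 1)
  set.seed(19)
  for (rep in 1:5) {
    edges <- sort(sample(0:200, 20), decreasing = TRUE)
    fp <- pmin(edges, sort(sample(0:100, 20), decreasing = TRUE))
    gam <- seq(0.5, 0.99, length.out = 20)
    K <- 80
    got <- gamma_max_f1(edges, fp, gam, K)
    tp <- edges - fp
    f1 <- 2 * tp / (2 * tp + fp + (K - tp))
    best <- max(f1)
    expect_equal(got$f1_hat, best)
    expect_equal(got$gamma, max(gam[f1 == best]))   # tie -> larger gamma
  }
})
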