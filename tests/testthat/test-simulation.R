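test_that("scale-free truths are trees with PD precision and exact support", {
  for (seed in c(1, 7, 23)) {
    for (w in c("fixed", "random")) {
      net <- generate_scale_free(50, weights = w, seed = seed)
      expect_equal(sum(net$adjacency) / 2, 49)      # attachment tree
      ev <- eigen(net$omega_true, symmetric = TRUE, only.values = TRUE)$values
      expect_gt(min(ev), 0)
      expect_equal(diag(net$sigma_true), rep(1, 50), tolerance = 1e-10)
      # support fidelity both ways
      off <- upper.tri(net$omega_true)
      on_edge <- abs(net$omega_true[off])[net$adjacency[off] == 1]
      off_edge <- abs(net$omega_true[off])[net$adjacency[off] == 0]
      expect_true(all(on_edge > 1e-8))
      expect_true(all(off_edge == 0))
      # omega and sigma are inverses
      expect_equal(net$omega_true %*% net$sigma_true, diag(50), tolerance = 1e-8)
    }
  }
})

test_that("scale-free degree distributions are heavy-tailed", {
  degs <- sapply(1:20, function(s) {
    net <- generate_scale_free(100, seed = s)
    d <- rowSums(net$adjacency)
    c(max = max(d), med = median(d))
  })
  expect_gt(mean(degs["max", ]), 8)                 # hubs emerge
  expect_true(all(degs["med", ] <= 2))              # most nodes are leaves
  small <- sapply(1:20, function(s) max(rowSums(generate_scale_free(20, seed = s)$adjacency)))
  expect_gt(mean(degs["max", ]), mean(small))       # hub size grows with p
})

test_that("random-weight trees carry a wide partial-correlation spectrum", {
  pcs <- unlist(lapply(1:10, function(s) {
    net <- generate_scale_free(100, "random", seed = s)
    pc <- -cov2cor(net$omega_true)
    abs(pc[upper.tri(pc) & net$adjacency == 1])
  }))
  # a sizeable weak-edge fraction and a sizeable strong-edge fraction
  expect_gt(mean(pcs < 0.15), 0.2)
  expect_gt(mean(pcs > 0.4), 0.15)
  # fixed weights: all partial correlations equal
  netf <- generate_scale_free(50, "fixed", seed = 3)
  pcf <- -cov2cor(netf$omega_true)
  pcf <- pcf[upper.tri(pcf) & netf$adjacency == 1]
  expect_lt(diff(range(pcf)), 1e-8)
})

test_that("cluster truths have exactly five components aligned with labels", {
  for (w in c("fixed", "random")) {
    net <- generate_cluster(100, weights = w, seed = 11)
    g <- igraph::graph_from_adjacency_matrix(net$adjacency != 0, mode = "undirected")
    comp <- igraph::components(g)
    expect_equal(comp$no, 5)
    expect_equal(nmi(as.integer(comp$membership), net$cluster_labels), 1)
    # between-cluster blocks identically zero in the precision matrix
    for (a in 1:4) for (b in (a + 1):5) {
      blk <- net$omega_true[net$cluster_labels == a, net$cluster_labels == b]
      expect_true(all(blk == 0))
    }
  }
  expect_error(generate_cluster(100, density = 0), "density")
})

test_that("calibrated cluster densities reproduce the reference clustering levels", {
  acc <- function(w) mean(sapply(1:50, function(s)
    average_clustering_coefficient(generate_cluster(100, weights = w, seed = s)$adjacency)))
  expect_equal(acc("fixed"), 0.303, tolerance = 0.05 / 0.303)
  expect_equal(acc("random"), 0.195, tolerance = 0.05 / 0.195)
})

test_that("Gaussian sampling is faithful to the truth and reproducible", {
  net <- generate_scale_free(5, seed = 21)
  Y1 <- sample_mvn(net, 200, seed = 5)
  expect_identical(Y1, sample_mvn(net, 200, seed = 5))
  expect_equal(colMeans(sample_mvn(net, 5000, seed = 6)), rep(0, 5), tolerance = 0.06)
  Y <- sample_mvn(net, 100000, seed = 7)
  S <- crossprod(sweep(Y, 2, colMeans(Y))) / nrow(Y)
  se <- sqrt((tcrossprod(diag(net$sigma_true)) + net$sigma_true^2) / 100000)
  expect_true(all(abs(S - net$sigma_true) < 3.5 * se))
})

test_that("the nonparanormal transform Gaussianizes while preserving ranks", {
  set.seed(22)
  Y <- matrix(rexp(500 * 4), 500, 4)
  Z <- nonparanormal_transform(Y)
  for (j in 1:4) {
    # monotone per column (ties allowed where the shrunken ECDF truncates)
    expect_true(all(diff(Z[order(Y[, j]), j]) >= 0))
    skew <- mean((Z[, j] - mean(Z[, j]))^3) / sd(Z[, j])^3
    kurt <- mean((Z[, j] - mean(Z[, j]))^4) / sd(Z[, j])^4
    expect_lt(abs(skew), 0.3)
    expect_lt(abs(kurt - 3), 1)
  }
  # already-normal input is nearly unchanged
  Yn <- matrix(rnorm(1000), 1000, 1)
  Zn <- nonparanormal_transform(Yn)
  expect_gt(cor(Yn[, 1], Zn[, 1]), 0.99)
  expect_warning(nonparanormal_transform(cbind(rep(1, 10), rnorm(10))), "distinct")
})
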