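rand_adj <- function(p, prob, seed) {
  set.seed(seed)
  a <- matrix(0L, p, p)
  a[upper.tri(a)] <- rbinom(p * (p - 1) / 2, 1, prob)
  a + t(a)
}

test_that("confusion counts match a brute-force pair loop", {
  a <- rand_adj(20, 0.2, 31)
  b <- rand_adj(20, 0.3, 32)
  cts <- confusion(a, b)
  tp <- fp <- fn <- tn <- 0
  for (i in 1:19) for (j in (i + 1):20) {
    if (a[i, j] && b[i, j]) tp <- tp + 1
    else if (a[i, j] && !b[i, j]) fp <- fp + 1
    else if (!a[i, j] && b[i, j]) fn <- fn + 1
    else tn <- tn + 1
  }
  expect_equal(cts, list(tp = tp, fp = fp, fn = fn, tn = tn))
  expect_equal(with(cts, tp + fp + fn + tn), 20 * 19 / 2)

  same <- confusion(a, a)
  expect_equal(same$fp, 0); expect_equal(same$fn, 0)
  compl <- 1L - b; diag(compl) <- 0L
  opp <- confusion(compl, b)
  expect_equal(opp$tp, 0); expect_equal(opp$tn, 0)
  expect_error(confusion(a, rand_adj(10, 0.2, 1)), "shapes")
})

test_that("scores implement the textbook formulas with safe degenerate corners", {
  perfect <- scores(list(tp = 10, fp = 0, fn = 0, tn = 35))
  expect_equal(perfect[c("mcc", "f1", "tpr", "fdr")],
               list(mcc = 1, f1 = 1, tpr = 1, fdr = 0))
  s <- scores(list(tp = 50, fp = 10, fn = 50, tn = 0))
  expect_equal(s$f1, 0.625)
  expect_equal(s$fdr, 1 / 6)
  expect_equal(s$tpr, 0.5)
  # conventions at empty/degenerate corners
  expect_equal(scores(list(tp = 0, fp = 0, fn = 5, tn = 5))$fdr, 0)
  expect_equal(scores(list(tp = 0, fp = 0, fn = 0, tn = 10))$f1, 0)
  expect_equal(scores(list(tp = 0, fp = 0, fn = 0, tn = 10))$mcc, 0)
  # formula oracle on random counts
  set.seed(33)
  for (k in 1:100) {
    v <- as.list(sample(0:50, 4, replace = TRUE))
    names(v) <- c("tp", "fp", "fn", "tn")
    got <- scores(v)
    tp <- v$tp; fp <- v$fp; fn <- v$fn; tn <- v$tn
    if (tp + fp > 0) expect_equal(got$fdr, fp / (tp + fp))
    if (2 * tp + fp + fn > 0) expect_equal(got$f1, 2 * tp / (2 * tp + fp + fn))
    den <- (tp + fp) * (tp + fn) * (tn + fp) * (tn + fn)
    if (den > 0) expect_equal(got$mcc, (tp * tn - fp * fn) / sqrt(den))
  }
})

test_that("average clustering coefficient matches triangle counting", {
  tri <- matrix(1L, 3, 3); diag(tri) <- 0L
  expect_equal(average_clustering_coefficient(tri), 1)
  star <- matrix(0L, 5, 5); star[1, 2:5] <- star[2:5, 1] <- 1L
  expect_equal(average_clustering_coefficient(star), 0)
  # brute force: per node, closed triangles over neighbour pairs
  a <- rand_adj(15, 0.3, 34)
  local <- sapply(1:15, function(i) {
    nb <- which(a[i, ] == 1)
    if (length(nb) < 2) return(0)
    pairs <- combn(nb, 2)
    closed <- sum(a[cbind(pairs[1, ], pairs[2, ])])
    closed / ncol(pairs)
  })
  expect_equal(average_clustering_coefficient(a), mean(local))
})

test_that("community labelling handles cliques, empty graphs and components", {
  two_tri <- matrix(0L, 6, 6)
  two_tri[1:3, 1:3] <- 1L; two_tri[4:6, 4:6] <- 1L; diag(two_tri) <- 0L
  expect_equal(length(unique(cluster_labels(two_tri, "components"))), 2)
  expect_equal(length(unique(cluster_labels(two_tri, "modularity"))), 2)
  empty <- matrix(0L, 4, 4)
  expect_equal(length(unique(cluster_labels(empty, "components"))), 4)
  five <- matrix(0L, 15, 15)
  for (k in 0:4) five[3 * k + 1:3, 3 * k + 1:3] <- 1L
  diag(five) <- 0L
  expect_equal(length(unique(cluster_labels(five, "components"))), 5)
})

test_that("NMI uses the mean-entropy normalization and is symmetric in [0, 1]", {
  a <- c(1, 1, 2, 2, 3, 3)
  expect_equal(nmi(a, a), 1)
  expect_equal(nmi(a, c(7, 7, 5, 5, 9, 9)), 1)      # relabelling-invariant
  expect_equal(nmi(1:6, rep(1, 6)), 0)              # singletons vs one group
  expect_error(nmi(1:3, 1:4), "lengths")
  set.seed(35)
  for (k in 1:10) {
    x <- sample(1:4, 30, replace = TRUE)
    y <- sample(1:3, 30, replace = TRUE)
    got <- nmi(x, y)
    expect_gte(got, 0); expect_lte(got, 1)
    expect_equal(got, nmi(y, x))
    # independent cross-check: igraph's Danon-style NMI (same normalization)
    expect_equal(got, igraph::compare(x, y, method = "nmi"), tolerance = 1e-10)
  }
})

test_that("recovery metrics are invariant to simultaneous node permutation", {
  a <- rand_adj(12, 0.25, 36)
  b <- rand_adj(12, 0.25, 37)
  set.seed(38)
  perm <- sample(12)
  s1 <- scores(confusion(a, b))
  s2 <- scores(confusion(a[perm, perm], b[perm, perm]))
  expect_equal(s1, s2)
  expect_equal(average_clustering_coefficient(a),
               average_clustering_coefficient(a[perm, perm]))
})
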