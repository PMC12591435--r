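# Exact G-Wishart(b, I) draw of a precision matrix whose support is a tree.
# Trees are decomposable, so no MCMC is needed: under a perfect elimination
# ordering (children before parents) the Cholesky factor of K has independent
# free entries — chi_{b + #later-neighbours} on the diagonal, N(0,1) on the
# edge positions, zero elsewhere (no fill-in for a tree).
gwishart_tree <- function(adj, b = 3) {
  p <- nrow(adj)
  deg <- rowSums(adj)
  if (sum(adj) / 2 != p - 1) stop("adjacency is not a tree", call. = FALSE)
  # BFS from node 1 to get parents, then order children before parents
  parent <- rep(NA_integer_, p)
  visited <- logical(p); visited[1L] <- TRUE
  queue <- 1L; order_bfs <- integer(0)
  while (length(queue) > 0L) {
    v <- queue[1L]; queue <- queue[-1L]
    order_bfs <- c(order_bfs, v)
    nb <- which(adj[v, ] == 1L & !visited)
    parent[nb] <- v
    visited[nb] <- TRUE
    queue <- c(queue, nb)
  }
  if (!all(visited)) stop("tree adjacency is disconnected", call. = FALSE)
  ord <- rev(order_bfs)                       # root (node 1) last
  pos <- match(seq_len(p), ord)
  phi <- matrix(0, p, p)
  for (i in seq_len(p)) {
    v <- ord[i]
    nu_i <- if (is.na(parent[v])) 0 else 1    # the parent is the later neighbour
    phi[i, i] <- sqrt(stats::rchisq(1L, df = b + nu_i))
    if (!is.na(parent[v])) phi[i, pos[parent[v]]] <- stats::rnorm(1L)
  }
  K_ord <- crossprod(phi)
  K <- matrix(0, p, p)
  K[ord, ord] <- K_ord
  K
}

# Turn a binary adjacency into a ground-truth precision/covariance pair.
#
# fixed scheme (emulating the equal-partial-correlation generator): the
# off-diagonals are v * a_ij, the diagonal is inflated to |lambda_min| + 0.1
# + u so the matrix is PD with a p-dependent implied partial correlation.
# random scheme (emulating the random-partial-correlation generator): for a
# tree support, an exact G-Wishart(3, I) draw (what the reference generator
# samples; trees are decomposable so the draw is closed-form); otherwise
# each edge weight is uniform on (-1, 1) and the diagonal is set by strict
# diagonal dominance (row sum of |off-diagonals| + margin).
#
# In both schemes the covariance is the correlation-rescaled inverse, so the
# variables have unit variance; the returned precision is the inverse of that
# rescaled covariance (a diagonal rescaling, which preserves the support).
weight_network <- function(adj, weights = c("fixed", "random"),
                           v = 0.3, u = 0.1, w = 1, margin = 0.1,
                           tree_exact = FALSE) {
  weights <- match.arg(weights)
  p <- nrow(adj)
  is_tree <- tree_exact && sum(adj) / 2 == p - 1
  if (weights == "fixed") {
    omega <- v * adj
    ev_min <- min(eigen(omega, symmetric = TRUE, only.values = TRUE)$values)
    diag(omega) <- abs(ev_min) + 0.1 + u
  } else if (is_tree) {
    omega <- gwishart_tree(adj, b = 3)
  } else {
    omega <- matrix(0, p, p)
    up <- which(upper.tri(adj) & adj == 1)
    wts <- stats::runif(length(up), -1, 1) * w
    # keep every edge numerically present
    tiny <- abs(wts) < 1e-6
    if (any(tiny)) wts[tiny] <- sign(wts[tiny] + (wts[tiny] == 0)) * 1e-6
    omega[up] <- wts
    omega <- omega + t(omega)
    diag(omega) <- rowSums(abs(omega)) + margin
  }
  sigma <- stats::cov2cor(solve(omega))
  sigma <- (sigma + t(sigma)) / 2
  omega_true <- solve(sigma)
  omega_true <- (omega_true + t(omega_true)) / 2
  # exact zeros where there is no edge (the diagonal rescaling cannot create
  # support, but floating-point noise can)
  omega_true[adj == 0 & row(adj) != col(adj)] <- 0
  list(omega = omega_true, sigma = sigma)
}

new_true_network <- function(adj, wn, labels, generator) {
  structure(
    list(adjacency = adj, omega_true = wn$omega, sigma_true = wn$sigma,
         cluster_labels = labels, generator = generator),
    class = "hmf_true_network")
}

#' @export
print.hmf_true_network <- function(x, ...) {
  g <- x$generator
  cat(sprintf("True network: %s structure, %s weights, p = %d, %d edges (seed %d)\n",
              g$structure, g$weights, g$p, sum(x$adjacency) / 2, g$seed))
  invisible(x)
}

#' Generate a scale-free ground-truth network
#'
#' The adjacency comes from preferential attachment with one edge per new
#' node, i.e. a tree with exactly `p - 1` edges and a heavy-tailed degree
#' distribution (few hubs, many leaves). Partial-correlation weights follow
#' one of two schemes emulating the two common reference generators:
#' `"fixed"` gives every edge the same raw weight (v = 0.3) with the diagonal
#' inflated for positive definiteness, so all implied partial correlations
#' are equal; `"random"` draws the precision matrix from the G-Wishart(3, I)
#' distribution restricted to the tree (an exact closed-form draw, since
#' trees are decomposable), so partial correlations range from negligible to
#' strong — a substantial fraction of edges is essentially undetectable at
#' moderate sample sizes, as with the reference generator being emulated.
#'
#' @param p Number of variables (`>= 3`).
#' @param weights `"fixed"` or `"random"` weighting scheme.
#' @param seed Integer seed.
#' @return An object of class `"hmf_true_network"`: list with `adjacency`,
#'   `omega_true` (PD precision whose support equals the adjacency),
#'   `sigma_true` (its inverse, rescaled to unit diagonal), `cluster_labels`
#'   (`NULL` for scale-free), and a `generator` descriptor.
#' @export
generate_scale_free <- function(p, weights = c("fixed", "random"), seed = 1L) {
  weights <- match.arg(weights)
  stopifnot(p >= 3)
  set.seed(as.integer(seed))
  g <- igraph::sample_pa(p, power = 1, m = 1, directed = FALSE)
  adj <- as.matrix(igraph::as_adjacency_matrix(g, sparse = FALSE))
  adj <- (adj > 0) * 1L
  wn <- weight_network(adj, weights, tree_exact = TRUE)
  new_true_network(adj, wn, NULL,
                   list(structure = "scale_free", weights = weights,
                        p = p, params = list(), seed = as.integer(seed)))
}

# Uniform-ish random spanning tree on m labelled nodes via a random Pruefer
# sequence; returns a 2-column edge matrix (1-based, local indices).
random_tree_edges <- function(m) {
  if (m == 1L) return(matrix(integer(0), 0, 2))
  if (m == 2L) return(matrix(c(1L, 2L), 1, 2))
  pruefer <- sample.int(m, m - 2L, replace = TRUE)
  degree <- tabulate(pruefer, nbins = m) + 1L
  edges <- matrix(0L, m - 1L, 2L)
  for (k in seq_len(m - 2L)) {
    leaf <- which(degree == 1L)[1L]
    v <- pruefer[k]
    edges[k, ] <- c(leaf, v)
    degree[leaf] <- 0L      # removed from the tree
    degree[v] <- degree[v] - 1L
  }
  edges[m - 1L, ] <- which(degree == 1L)
  edges
}

#' Generate a five-cluster ground-truth network
#'
#' Variables are split into `n_clusters` near-equal groups with zero edges
#' between groups, so the true graph has exactly `n_clusters` connected
#' components. Within each cluster the topology is a random spanning tree
#' (guaranteeing connectivity) plus independent extra edges, with the edge
#' probability chosen so the expected within-cluster edge density equals
#' `density`. The default densities are calibrated per weighting scheme so
#' that the mean average clustering coefficient of the true networks at
#' p = 100 is about 0.30 (fixed) and 0.20 (random), mirroring the two
#' reference generators' cluster styles.
#'
#' @param p Number of variables.
#' @param n_clusters Number of disconnected clusters (default 5).
#' @param weights `"fixed"` or `"random"` scheme, as in
#'   [generate_scale_free()].
#' @param density Expected within-cluster edge density in `(0, 1]`; default
#'   depends on the weighting scheme (see above).
#' @param seed Integer seed.
#' @return An `"hmf_true_network"` with `cluster_labels` set.
#' @export
generate_cluster <- function(p, n_clusters = 5L,
                             weights = c("fixed", "random"),
                             density = NULL, seed = 1L) {
  weights <- match.arg(weights)
  if (is.null(density)) {
    density <- if (weights == "fixed") 0.315 else 0.222
  }
  if (density <= 0 || density > 1) {
    stop("`density` must lie in (0, 1]", call. = FALSE)
  }
  stopifnot(p >= 2 * n_clusters)
  set.seed(as.integer(seed))
  sizes <- rep(p %/% n_clusters, n_clusters)
  extra <- p %% n_clusters
  if (extra > 0) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L
  labels <- rep(seq_len(n_clusters), sizes)
  adj <- matrix(0L, p, p)
  offset <- 0L
  for (cl in seq_len(n_clusters)) {
    m <- sizes[cl]
    idx <- offset + seq_len(m)
    tree <- random_tree_edges(m)
    for (r in seq_len(nrow(tree))) {
      i <- idx[tree[r, 1L]]; j <- idx[tree[r, 2L]]
      adj[i, j] <- adj[j, i] <- 1L
    }
    n_pairs <- m * (m - 1) / 2
    q <- (n_pairs * density - (m - 1)) / (n_pairs - (m - 1))
    if (q > 0) {
      for (a in seq_len(m - 1L)) for (b in seq((a + 1L), m)) {
        i <- idx[a]; j <- idx[b]
        if (adj[i, j] == 0L && stats::runif(1) < q) adj[i, j] <- adj[j, i] <- 1L
      }
    }
    offset <- offset + m
  }
  wn <- weight_network(adj, weights)
  new_true_network(adj, wn, labels,
                   list(structure = "cluster", weights = weights, p = p,
                        params = list(n_clusters = n_clusters, density = density),
                        seed = as.integer(seed)))
}

#' Draw multivariate-normal data from a ground-truth network
#'
#' i.i.d. samples from \eqn{N(0, \Sigma_{\mathrm{true}})}, reproducible given
#' the seed.
#'
#' @param net An `"hmf_true_network"`.
#' @param n Number of samples.
#' @param seed Integer seed.
#' @return An `n x p` numeric matrix.
#' @export
sample_mvn <- function(net, n, seed = 1L) {
  stopifnot(inherits(net, "hmf_true_network"), n >= 1)
  set.seed(as.integer(seed))
  MASS::mvrnorm(n, mu = rep(0, ncol(net$sigma_true)), Sigma = net$sigma_true)
}

#' Nonparanormal (rank-Gaussianizing) transform
#'
#' Per-column Gaussianization for data that violate the normality assumption:
#' ranks are converted to a shrunken empirical CDF — the ECDF `r/n` truncated
#' at \eqn{\delta_n = 1/(4 n^{1/4}\sqrt{\pi \log n})} from both ends — then
#' mapped through standard-normal quantiles and rescaled to unit sample
#' variance. Monotone within each column, so order statistics are preserved.
#'
#' @param Y Numeric data matrix, samples in rows (`n >= 3`).
#' @return Matrix of the same shape with approximately Gaussian columns.
#' @export
nonparanormal_transform <- function(Y) {
  Y <- as.matrix(Y)
  n <- nrow(Y)
  stopifnot(n >= 3)
  ties <- apply(Y, 2L, function(col) length(unique(col)) < 3L)
  if (any(ties)) {
    warning("column(s) with fewer than 3 distinct values: ",
            paste(which(ties), collapse = ", "),
            "; the rank transform is degenerate there", call. = FALSE)
  }
  delta_n <- 1 / (4 * n^0.25 * sqrt(pi * log(n)))
  out <- apply(Y, 2L, function(col) {
    u <- rank(col, ties.method = "average") / n
    u <- pmin(pmax(u, delta_n), 1 - delta_n)
    z <- stats::qnorm(u)
    s <- stats::sd(z)
    if (s > 0) z / s else z
  })
  dimnames(out) <- dimnames(Y)
  out
}
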