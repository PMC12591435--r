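check_adjacency_pair <- function(adj_hat, adj_true) {
  if (!all(dim(adj_hat) == dim(adj_true))) {
    stop("adjacency matrices have different shapes", call. = FALSE)
  }
}

#' Edge confusion counts between an estimated and a true network
#'
#' Counts true/false positives and negatives over the unordered off-diagonal
#' pairs (upper triangle) of two adjacency matrices.
#'
#' @param adj_hat,adj_true Symmetric binary matrices with zero diagonal.
#' @return A list with integer fields `tp`, `fp`, `fn`, `tn`; they sum to
#'   `p(p-1)/2`.
#' @export
confusion <- function(adj_hat, adj_true) {
  check_adjacency_pair(adj_hat, adj_true)
  up <- upper.tri(adj_hat)
  h <- adj_hat[up] != 0
  t <- adj_true[up] != 0
  list(tp = sum(h & t), fp = sum(h & !t), fn = sum(!h & t), tn = sum(!h & !t))
}

#' Network-recovery scores from confusion counts
#'
#' Matthews correlation coefficient, F1-score, false discovery rate and true
#' positive rate, with the degenerate-corner conventions: FDR = 0 when no
#' edges are declared, F1 = 0 when `2tp + fp + fn = 0`, MCC = 0 when any
#' marginal of the confusion table is 0, TPR = 0 when there are no true
#' edges.
#'
#' @param counts A list as returned by [confusion()].
#' @return Named list `mcc`, `f1`, `fdr`, `tpr`.
#' @export
scores <- function(counts) {
  tp <- as.numeric(counts$tp); fp <- as.numeric(counts$fp)
  fn <- as.numeric(counts$fn); tn <- as.numeric(counts$tn)
  stopifnot(tp >= 0, fp >= 0, fn >= 0, tn >= 0)
  fdr <- if (tp + fp > 0) fp / (tp + fp) else 0
  f1 <- if (2 * tp + fp + fn > 0) 2 * tp / (2 * tp + fp + fn) else 0
  tpr <- if (tp + fn > 0) tp / (tp + fn) else 0
  denom <- (tp + fp) * (tp + fn) * (tn + fp) * (tn + fn)
  mcc <- if (denom > 0) (tp * tn - fp * fn) / sqrt(denom) else 0
  list(mcc = mcc, f1 = f1, fdr = fdr, tpr = tpr)
}

#' Average clustering coefficient of a network
#'
#' Mean over nodes of the local clustering coefficient (realized triangles
#' among each node's neighbour pairs); nodes of degree below 2 contribute 0.
#'
#' @param adj Symmetric binary matrix with zero diagonal.
#' @return A scalar in `[0, 1]`.
#' @export
average_clustering_coefficient <- function(adj) {
  g <- igraph::graph_from_adjacency_matrix(adj != 0, mode = "undirected")
  local <- igraph::transitivity(g, type = "local", isolates = "zero")
  mean(local)
}

#' Cluster labels of a network's nodes
#'
#' Assigns a community label to every node, either as connected components or
#' via greedy modularity maximization (the default: robust to a few spurious
#' bridge edges between otherwise separate groups). In an empty graph every
#' node is its own community under both methods.
#'
#' @param adj Symmetric binary matrix with zero diagonal.
#' @param method `"modularity"` (greedy) or `"components"`.
#' @return Integer vector of length p.
#' @export
cluster_labels <- function(adj, method = c("modularity", "components")) {
  method <- match.arg(method)
  g <- igraph::graph_from_adjacency_matrix(adj != 0, mode = "undirected")
  if (method == "components") {
    as.integer(igraph::components(g)$membership)
  } else {
    as.integer(igraph::membership(igraph::cluster_fast_greedy(g)))
  }
}

#' Normalized mutual information between two partitions
#'
#' Mutual information of the two label vectors normalized by the arithmetic
#' mean of their entropies, \eqn{\mathrm{NMI} = 2I(A;B)/(H(A)+H(B))};
#' invariant to relabelling, in `[0, 1]`, and 1 for identical partitions.
#' When both partitions are trivial (a single group, or all singletons
#' against all singletons with zero entropy) the convention NMI = 0 applies
#' unless the partitions are identical, in which case NMI = 1.
#'
#' @param labels_a,labels_b Equal-length label vectors.
#' @return A scalar in `[0, 1]`.
#' @export
nmi <- function(labels_a, labels_b) {
  if (length(labels_a) != length(labels_b)) {
    stop("label vectors have different lengths", call. = FALSE)
  }
  n <- length(labels_a)
  tab <- table(labels_a, labels_b)
  pij <- tab / n
  pi_ <- rowSums(pij); pj_ <- colSums(pij)
  nz <- pij > 0
  mi <- sum(pij[nz] * log(pij[nz] / (pi_[row(pij)[nz]] * pj_[col(pij)[nz]])))
  ha <- -sum(pi_[pi_ > 0] * log(pi_[pi_ > 0]))
  hb <- -sum(pj_[pj_ > 0] * log(pj_[pj_ > 0]))
  if (ha + hb == 0) {
    # both partitions carry no information; identical iff both are the
    # single-group partition
    return(if (identical(unname(as.integer(factor(labels_a))),
                         unname(as.integer(factor(labels_b))))) 1 else 0)
  }
  max(0, min(1, 2 * mi / (ha + hb)))
}
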