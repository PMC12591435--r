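#' Read a samples-by-variables matrix from delimited text
#'
#' Accepts CSV or TSV (sniffed from the first line unless `sep` is given),
#' with an optional header row of variable names. All cells must be numeric.
#'
#' @param path Path to the file.
#' @param sep Field separator; `NULL` (default) sniffs `,` vs tab.
#' @param header Does the first row hold variable names? Default `TRUE`.
#' @return A numeric matrix.
#' @export
read_data_matrix <- function(path, sep = NULL, header = TRUE) {
  if (!file.exists(path)) stop("input file not found: ", path, call. = FALSE)
  if (is.null(sep)) {
    first <- readLines(path, n = 1L)
    sep <- if (grepl("\t", first)) "\t" else ","
  }
  df <- utils::read.table(path, sep = sep, header = header,
                          stringsAsFactors = FALSE, check.names = FALSE)
  m <- as.matrix(df)
  if (!is.numeric(m)) stop("non-numeric cells in ", path, call. = FALSE)
  if (nrow(m) < 3L) stop("need at least 3 samples (rows) in ", path, call. = FALSE)
  m
}

#' Write a recovered network to standard files
#'
#' Writes, under a common prefix: an edge-list TSV (`node_i`, `node_j`,
#' `omega_hat`, `z_score`), the adjacency matrix as CSV, a GraphML file for
#' network viewers, and a JSON run report (hyperparameters, selected
#' credible level, edge count, selector curves, seed).
#'
#' @param network An `"hmf_network"`.
#' @param prefix Output path prefix; files get `_edges.tsv`,
#'   `_adjacency.csv`, `.graphml`, `_report.json` appended.
#' @return Invisibly, the vector of written paths.
#' @export
write_network <- function(network, prefix) {
  stopifnot(inherits(network, "hmf_network"))
  edges <- tidy(network)
  paths <- c(edges = paste0(prefix, "_edges.tsv"),
             adjacency = paste0(prefix, "_adjacency.csv"),
             graphml = paste0(prefix, ".graphml"),
             report = paste0(prefix, "_report.json"))
  utils::write.table(as.data.frame(edges), paths[["edges"]], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.csv(network$adjacency, paths[["adjacency"]], row.names = FALSE)
  g <- igraph::graph_from_adjacency_matrix(network$adjacency != 0,
                                           mode = "undirected")
  igraph::write_graph(g, paths[["graphml"]], format = "graphml")
  report <- list(
    alpha = network$alpha, alpha_mode = network$alpha_mode,
    beta = network$fit$control$beta,
    gamma = network$gamma, selection = network$selection,
    n_edges = network$n_edges, n_iters = network$fit$n_iters,
    converged = network$fit$converged, seed = network$seed,
    p = network$fit$moments$p, n = network$fit$moments$n)
  if (!is.null(network$fdr_hat)) {
    report$fdr_hat <- network$fdr_hat; report$fdr_target <- network$fdr_target
  }
  if (!is.null(network$f1_hat)) {
    report$f1_hat <- network$f1_hat; report$K <- network$K
  }
  if (!is.null(network$fp_curve)) {
    report$curves <- list(gamma = network$fp_curve$gamma,
                          edge_counts = network$fp_curve$edge_counts,
                          fp_hat = network$fp_curve$fp_hat)
  }
  jsonlite::write_json(report, paths[["report"]], auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(paths)
}

#' Write a simulated ground truth to files
#'
#' Writes the data matrix, true adjacency, true precision matrix, cluster
#' labels (if any) and a JSON generator descriptor under a common prefix.
#'
#' @param net An `"hmf_true_network"`.
#' @param Y The data matrix drawn from it (see [sample_mvn()]).
#' @param prefix Output path prefix.
#' @return Invisibly, the vector of written paths.
#' @export
write_simulation <- function(net, Y, prefix) {
  stopifnot(inherits(net, "hmf_true_network"))
  paths <- c(data = paste0(prefix, "_data.csv"),
             adjacency = paste0(prefix, "_true_adjacency.csv"),
             omega = paste0(prefix, "_true_omega.csv"),
             descriptor = paste0(prefix, "_descriptor.json"))
  utils::write.csv(Y, paths[["data"]], row.names = FALSE)
  utils::write.csv(net$adjacency, paths[["adjacency"]], row.names = FALSE)
  utils::write.csv(net$omega_true, paths[["omega"]], row.names = FALSE)
  if (!is.null(net$cluster_labels)) {
    paths <- c(paths, labels = paste0(prefix, "_labels.tsv"))
    utils::write.table(
      data.frame(node = seq_along(net$cluster_labels),
                 cluster = net$cluster_labels),
      paths[["labels"]], sep = "\t", quote = FALSE, row.names = FALSE)
  }
  jsonlite::write_json(net$generator, paths[["descriptor"]],
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(paths)
}
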