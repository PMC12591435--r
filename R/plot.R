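#' Plot the permutation selection curves
#'
#' Edge count, estimated false positives, estimated FDR and (optionally)
#' estimated F1 as functions of the credible mass, as computed by
#' [estimate_fp_curve()]. Requires ggplot2.
#'
#' @param curve An `"hmf_fp_curve"`.
#' @param K Expected number of true edges; when given, the estimated-F1
#'   curve is drawn as well.
#' @return A ggplot object.
#' @export
plot_selection_curves <- function(curve, K = NULL) {
  stopifnot(inherits(curve, "hmf_fp_curve"))
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop("plot_selection_curves() needs the ggplot2 package", call. = FALSE)
  }
  tab <- tidy(curve)
  pieces <- list(
    data.frame(gamma = tab$gamma, value = tab$edge_counts, what = "edges"),
    data.frame(gamma = tab$gamma, value = tab$fp_hat, what = "estimated FP"),
    data.frame(gamma = tab$gamma, value = tab$fdr_hat, what = "estimated FDR"))
  if (!is.null(K)) {
    f1 <- gamma_max_f1(curve$edge_counts, curve$fp_hat, curve$gamma, K)$f1_curve
    pieces <- c(pieces, list(
      data.frame(gamma = tab$gamma, value = f1, what = "estimated F1")))
  }
  df <- do.call(rbind, pieces)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$gamma, y = .data$value)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~what, scales = "free_y") +
    ggplot2::labs(x = "credible mass", y = NULL,
                  title = "Permutation-based credible-level selection") +
    ggplot2::theme_minimal()
}

#' Plot a recovered network
#'
#' Node-link diagram of the selected graph via igraph, optionally coloured
#' by group labels (e.g. true cluster memberships or taxa).
#'
#' @param x An `"hmf_network"`.
#' @param groups Optional integer/factor vector of node groups for colours.
#' @param ... Passed on to `plot.igraph`.
#' @export
plot.hmf_network <- function(x, groups = NULL, ...) {
  g <- igraph::graph_from_adjacency_matrix(x$adjacency != 0, mode = "undirected")
  args <- list(g, vertex.size = 4, vertex.label = NA, ...)
  if (!is.null(groups)) {
    args$vertex.color <- as.integer(as.factor(groups))
  }
  do.call(plot, args)
  invisible(x)
}
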