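#' Convert a network to an igraph object
#'
#' Nodes are modules; a directed edge `j -> i` is created for every nonzero
#' off-diagonal connection coefficient `r[i, j]`, carrying its `weight`, its
#' `sign` (`"+"`/`"-"`) and, when a CI table is supplied, a `significant`
#' flag (interval excludes 0). The -1 diagonal is a normalization, not an
#' interaction, so no self-loops are created.
#'
#' @param net An `mra_network`.
#' @param ci Optional `mra_ci` from [bootstrap_network()], indexed by the
#'   same modules.
#' @param min_abs_weight Drop edges with `|weight|` below this threshold.
#' @return An igraph graph.
#' @export
as_mra_igraph <- function(net, ci = NULL, min_abs_weight = 0) {
  stopifnot(inherits(net, "mra_network"))
  edges <- tidy(net, ci = ci)
  edges <- edges[abs(edges$coefficient) > min_abs_weight, , drop = FALSE]
  g <- igraph::graph_from_data_frame(
    dplyr::transmute(edges, from = .data$from, to = .data$to,
                     weight = .data$coefficient, sign = .data$sign),
    directed = TRUE,
    vertices = data.frame(name = net$modules))
  if (!is.null(ci)) {
    igraph::E(g)$significant <- as.logical(edges$significant)
  }
  g
}

#' Export a network as GraphML or GML
#'
#' Writes a standard GraphML or GML document loadable by Cytoscape, yEd or
#' any generic graph reader. Edge attributes: `weight` (connection
#' coefficient), `sign`, and `significant` when a CI table is given.
#'
#' @inheritParams as_mra_igraph
#' @param path Output file path.
#' @param format `"graphml"` or `"gml"`.
#' @return `path`, invisibly.
#' @export
export_graph <- function(net, path, format = c("graphml", "gml"), ci = NULL,
                         min_abs_weight = 0) {
  format <- match.arg(format)
  g <- as_mra_igraph(net, ci = ci, min_abs_weight = min_abs_weight)
  if (format == "gml" && "significant" %in% igraph::edge_attr_names(g)) {
    # GML has no boolean type; encode as 0/1
    igraph::E(g)$significant <- as.integer(igraph::E(g)$significant)
  }
  igraph::write_graph(g, path, format = format)
  invisible(path)
}
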