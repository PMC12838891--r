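#' Construct an undirected interaction graph
#'
#' Thin wrapper over an undirected igraph: self-loops and duplicate
#' edges are removed, an optional `weight` edge attribute holds
#' association confidences in `[0, 1]`.
#'
#' @param edges Two-column character matrix/data.frame of symbol pairs.
#' @param nodes Optional character vector of node symbols (isolated nodes
#'   allowed).
#' @param weight Optional numeric vector of edge confidences in `[0, 1]`.
#' @return An igraph with class `interaction_graph` prepended.
#' @export
interaction_graph <- function(edges, nodes = NULL, weight = NULL) {
  edges <- as.matrix(edges)
  if (ncol(edges) != 2L) stop_validation("`edges` must have two columns")
  storage.mode(edges) <- "character"
  if (!is.null(weight)) {
    if (length(weight) != nrow(edges))
      stop_validation("`weight` must have one value per edge")
    if (any(weight < 0 | weight > 1, na.rm = TRUE))
      stop_validation("edge weights must lie in [0, 1]")
  }
  nodes <- unique(c(nodes, as.vector(t(edges))))
  g <- igraph::graph_from_data_frame(
    if (is.null(weight)) data.frame(from = edges[, 1], to = edges[, 2])
    else data.frame(from = edges[, 1], to = edges[, 2], weight = weight),
    directed = FALSE, vertices = nodes)
  as_interaction_graph(igraph::simplify(g, edge.attr.comb = "max"))
}

as_interaction_graph <- function(g) {
  class(g) <- unique(c("interaction_graph", class(g)))
  g
}

#' Read a STRING-style TSV edge list
#'
#' Accepts 2- or 3-column files (`nodeA`, `nodeB`, optional numeric
#' confidence). When a third column is present, edges below
#' `min_confidence` are dropped (default 0.4, the usual medium-confidence
#' threshold for STRING exports).
#'
#' @param path File path.
#' @param min_confidence Confidence threshold applied to a third column.
#' @param header Whether the file has a header line.
#' @return An [interaction_graph()].
#' @export
read_edge_list <- function(path, min_confidence = 0.4, header = FALSE) {
  df <- utils::read.table(path, sep = "\t", header = header,
                          stringsAsFactors = FALSE)
  if (ncol(df) < 2L) stop_validation("edge list needs at least two columns")
  w <- NULL
  if (ncol(df) >= 3L && is.numeric(df[[3]])) {
    keep <- df[[3]] >= min_confidence
    df <- df[keep, , drop = FALSE]
    w <- df[[3]]
  }
  interaction_graph(df[, 1:2], weight = w)
}

#' Write an interaction graph as a TSV edge list
#'
#' @param g An `interaction_graph`.
#' @param path Output path.
#' @export
write_edge_list <- function(g, path) {
  el <- igraph::as_edgelist(g)
  df <- data.frame(nodeA = el[, 1], nodeB = el[, 2])
  if ("weight" %in% igraph::edge_attr_names(g)) df$score <- igraph::E(g)$weight
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Basic statistics of an interaction graph
#'
#' Average degree is `2E/N`; the average local clustering coefficient is
#' the mean over all nodes of the triangle density of each node's
#' neighborhood, with nodes of degree < 2 contributing 0 (kept in the
#' mean, not excluded).
#'
#' @param g An `interaction_graph` (or plain igraph).
#' @return A `network_stats` list: `n_nodes`, `n_edges`, `avg_degree`,
#'   `avg_local_clustering`.
#' @examples
#' tri <- interaction_graph(cbind(c("a", "b", "c"), c("b", "c", "a")))
#' graph_stats(tri)
#' @export
graph_stats <- function(g) {
  if (igraph::vcount(g) < 1L) stop_validation("graph_stats: empty graph")
  n <- igraph::vcount(g)
  e <- igraph::ecount(g)
  cc <- igraph::transitivity(g, type = "local", isolates = "zero")
  cc[is.na(cc)] <- 0  # degree-1 nodes
  structure(list(n_nodes = n, n_edges = e,
                 avg_degree = 2 * e / n,
                 avg_local_clustering = mean(cc)),
            class = "network_stats")
}

#' @export
print.network_stats <- function(x, ...) {
  cat(sprintf("nodes %d, edges %d, average degree %.2f, clustering %.3f\n",
              x$n_nodes, x$n_edges, x$avg_degree, x$avg_local_clustering))
  invisible(x)
}

#' Write MCODE modules to TSV
#'
#' Columns: `module_id`, `rank`, `score`, `members` (semicolon-joined).
#'
#' @param modules Result of [mcode()].
#' @param path Output path.
#' @export
write_modules_tsv <- function(modules, path) {
  df <- data.frame(
    module_id = seq_along(modules),
    rank = seq_along(modules),
    score = vapply(modules, `[[`, numeric(1), "score"),
    members = vapply(modules, function(m) paste(m$nodes, collapse = ";"),
                     character(1)),
    stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
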