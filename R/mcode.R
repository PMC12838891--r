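#' MCODE parameters
#'
#' The molecular-complex-detection defaults: degree cutoff 2, node score
#' cutoff 0.2, k-core 2, haircut on, fluff off.
#'
#' @param degree_cutoff Minimum degree for a node to be weighted (>= 1).
#' @param node_score_cutoff Score tolerance in `[0, 1]` for admitting
#'   neighbors during complex expansion.
#' @param k_core Minimum k-core a reported complex must contain (>= 2).
#' @param haircut Remove singly-connected nodes from complexes.
#' @param fluff Not implemented beyond the published default (off);
#'   requesting it errors.
#' @return An `mcode_params` list.
#' @export
mcode_params <- function(degree_cutoff = 2L, node_score_cutoff = 0.2,
                         k_core = 2L, haircut = TRUE, fluff = FALSE) {
  degree_cutoff <- assert_count(degree_cutoff, "degree_cutoff", min = 1L)
  node_score_cutoff <- assert_prob(node_score_cutoff, "node_score_cutoff")
  k_core <- assert_count(k_core, "k_core", min = 2L)
  if (isTRUE(fluff))
    stop_validation("fluff expansion is not implemented; use fluff = FALSE")
  structure(list(degree_cutoff = degree_cutoff,
                 node_score_cutoff = node_score_cutoff,
                 k_core = k_core, haircut = isTRUE(haircut), fluff = FALSE),
            class = "mcode_params")
}

# density of an undirected simple graph: 2E / (n (n-1)); single node -> 0
graph_density <- function(g) {
  n <- igraph::vcount(g)
  if (n < 2L) return(0)
  2 * igraph::ecount(g) / (n * (n - 1))
}

# MCODE vertex weighting: for each node, take the induced subgraph of its
# closed neighborhood, find the highest k-core within it, and set
# weight = k_max * density(highest core) ("core-clustering coefficient").
# Nodes with degree below the cutoff weigh 0.
mcode_weights <- function(g, degree_cutoff) {
  deg <- igraph::degree(g)
  vapply(seq_len(igraph::vcount(g)), function(v) {
    if (deg[v] < degree_cutoff) return(0)
    nb <- c(v, as.integer(igraph::neighbors(g, v)))
    sub <- igraph::induced_subgraph(g, nb)
    core <- igraph::coreness(sub)
    kmax <- max(core)
    if (kmax < 1L) return(0)
    top <- igraph::induced_subgraph(sub, which(core == kmax))
    kmax * graph_density(top)
  }, numeric(1))
}

#' Detect dense network modules with the MCODE algorithm
#'
#' Implements the three MCODE stages: (1) vertex weighting by the
#' density of the highest k-core of each node's closed neighborhood
#' times that core's k; (2) seeded greedy complex expansion from the
#' highest-weighted unassigned node, admitting neighbors whose weight is
#' at least `(1 - node_score_cutoff)` times the seed weight, each node
#' belonging to at most one complex; (3) post-processing that discards
#' complexes lacking a `k_core`-core and optionally shaves
#' singly-connected members (haircut). Complexes are scored by
#' `density * size` and returned in decreasing score order; ties in seed
#' selection and ranking break lexicographically on node name for
#' determinism.
#'
#' @param g An [interaction_graph()] (or plain undirected igraph).
#' @param params An [mcode_params()].
#' @return List of modules, each a list with `nodes` (character),
#'   `score`, `density`, `size`, `seed`.
#' @examples
#' g <- make_modular_graph(planted_graph_spec(2, 5, 1, 0, seed = 1))
#' lapply(mcode(g), `[[`, "nodes")
#' @export
mcode <- function(g, params = mcode_params()) {
  if (!inherits(params, "mcode_params")) stop_validation("`params` must be mcode_params")
  if (igraph::vcount(g) == 0L) stop_validation("mcode: empty graph")
  nm <- igraph::V(g)$name %||% as.character(seq_len(igraph::vcount(g)))

  w <- mcode_weights(g, params$degree_cutoff)
  assigned <- rep(FALSE, igraph::vcount(g))
  modules <- list()

  # deterministic seed order: weight desc, then node name
  order_idx <- order(-w, nm)
  adj <- igraph::as_adj_list(g)

  for (seed in order_idx) {
    if (assigned[seed] || w[seed] <= 0) next
    thresh <- (1 - params$node_score_cutoff) * w[seed]
    members <- seed
    assigned[seed] <- TRUE
    frontier <- seed
    while (length(frontier)) {
      nxt <- integer(0)
      for (v in frontier) {
        for (u in as.integer(adj[[v]])) {
          if (!assigned[u] && w[u] >= thresh) {
            assigned[u] <- TRUE
            members <- c(members, u)
            nxt <- c(nxt, u)
          }
        }
      }
      frontier <- nxt
    }

    sub <- igraph::induced_subgraph(g, members)
    core <- igraph::coreness(sub)
    if (max(core) < params$k_core) {
      next  # nodes stay consumed, as in the published greedy scheme
    }
    if (params$haircut) {
      keep <- igraph::degree(sub) >= 2
      sub <- igraph::induced_subgraph(sub, which(keep))
    }
    if (igraph::vcount(sub) < 2L) next
    modules[[length(modules) + 1L]] <- list(
      nodes = sort(igraph::V(sub)$name),
      score = graph_density(sub) * igraph::vcount(sub),
      density = graph_density(sub),
      size = igraph::vcount(sub),
      seed = nm[seed])
  }

  ord <- order(-vapply(modules, `[[`, numeric(1), "score"),
               vapply(modules, function(m) m$nodes[1], character(1)))
  modules[ord]
}

#' Brute-force densest-subgraph enumeration
#'
#' Independent oracle for module detection on small graphs: enumerates
#' every vertex subset of size >= `min_size` and returns the subset
#' maximizing `density * size` (ties broken by lexicographically
#' smallest member set). Exponential in the node count; refuses graphs
#' above `max_nodes`.
#'
#' @param g igraph.
#' @param min_size Smallest subset considered.
#' @param max_nodes Guard on graph size (default 15).
#' @return List with `nodes` and `score`.
#' @export
densest_subgraph_bruteforce <- function(g, min_size = 3L, max_nodes = 15L) {
  n <- igraph::vcount(g)
  if (n > max_nodes)
    stop_validation("brute-force enumeration limited to %d nodes", max_nodes)
  nm <- igraph::V(g)$name %||% as.character(seq_len(n))
  best <- NULL
  for (mask in seq_len(2^n - 1)) {
    idx <- which(bitwAnd(mask, 2^(seq_len(n) - 1)) != 0)
    if (length(idx) < min_size) next
    sub <- igraph::induced_subgraph(g, idx)
    sc <- graph_density(sub) * length(idx)
    key <- paste(sort(nm[idx]), collapse = ";")
    if (is.null(best) || sc > best$score ||
        (sc == best$score && key < best$key)) {
      best <- list(nodes = sort(nm[idx]), score = sc, key = key)
    }
  }
  best[c("nodes", "score")]
}
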