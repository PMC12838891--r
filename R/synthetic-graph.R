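#' Specification for a planted-module random graph
#'
#' A planted-partition graph: `n_modules` blocks of `module_size` nodes,
#' intra-module edge probability `p_in`, inter-module probability
#' `p_out`. Used as the test harness for module-detection algorithms.
#'
#' @param n_modules Number of planted modules.
#' @param module_size Nodes per module (>= 3).
#' @param p_in Intra-module edge probability.
#' @param p_out Inter-module edge probability, `p_out < p_in`.
#' @param seed Integer seed.
#' @return A `planted_graph_spec` list.
#' @export
planted_graph_spec <- function(n_modules, module_size, p_in, p_out, seed = 1L) {
  n_modules <- assert_count(n_modules, "n_modules", min = 1L)
  module_size <- assert_count(module_size, "module_size", min = 3L)
  p_in <- assert_prob(p_in, "p_in")
  p_out <- assert_prob(p_out, "p_out")
  if (!(p_out < p_in))
    stop_validation("need 0 <= p_out < p_in <= 1 (got p_in=%g, p_out=%g)", p_in, p_out)
  seed <- assert_count(seed, "seed")
  structure(list(n_modules = n_modules, module_size = module_size,
                 p_in = p_in, p_out = p_out, seed = seed),
            class = "planted_graph_spec")
}

#' Generate a graph with planted dense modules
#'
#' Samples a stochastic block model with constant within- and
#' between-block probabilities. Node names are role-coded
#' (`M<module>_N<node>`) and the planted assignment is stored in the
#' vertex attribute `module`.
#'
#' @param spec A [planted_graph_spec()].
#' @return An [interaction_graph()] (igraph) with `module` vertex
#'   attribute.
#' @examples
#' g <- make_modular_graph(planted_graph_spec(2, 5, 1, 0, seed = 3))
#' igraph::ecount(g)  # two disjoint 5-cliques: 20 edges
#' @export
make_modular_graph <- function(spec) {
  if (!inherits(spec, "planted_graph_spec"))
    stop_validation("`spec` must be a planted_graph_spec")
  withr::with_seed(spec$seed, {
    k <- spec$n_modules
    m <- spec$module_size
    pref <- matrix(spec$p_out, k, k)
    diag(pref) <- spec$p_in
    g <- igraph::sample_sbm(k * m, pref.matrix = pref, block.sizes = rep(m, k))
    modules <- rep(seq_len(k), each = m)
    igraph::V(g)$name <- sprintf("M%02d_N%02d", modules, sequence(rep(m, k)))
    igraph::V(g)$module <- modules
    as_interaction_graph(g)
  })
}

#' Specification for a block-correlated expression matrix
#'
#' Genes are partitioned into blocks; within a block, genes share a
#' single common factor so that the expected pairwise Pearson
#' correlation equals `block_correlation` when `noise_sd = 1`
#' (larger noise attenuates it).
#'
#' @param n_genes Number of genes.
#' @param n_samples Number of samples (>= 3).
#' @param block_assignments Integer/character vector of length `n_genes`
#'   mapping each gene to a block.
#' @param block_correlation Single value in `[0, 1)`, or one value per
#'   block.
#' @param noise_sd Standard deviation of the idiosyncratic noise.
#' @param seed Integer seed.
#' @return An `expr_block_spec` list.
#' @export
expr_block_spec <- function(n_genes, n_samples, block_assignments,
                            block_correlation, noise_sd = 1, seed = 1L) {
  n_genes <- assert_count(n_genes, "n_genes", min = 1L)
  n_samples <- assert_count(n_samples, "n_samples", min = 3L)
  if (length(block_assignments) != n_genes)
    stop_validation("`block_assignments` must assign every gene to exactly one block")
  blocks <- unique(block_assignments)
  if (length(block_correlation) == 1L)
    block_correlation <- stats::setNames(rep(block_correlation, length(blocks)),
                                         as.character(blocks))
  for (b in names(block_correlation)) {
    v <- block_correlation[[b]]
    if (!is.numeric(v) || v < 0 || v >= 1)
      stop_validation("block_correlation for block '%s' must lie in [0, 1)", b)
  }
  noise_sd <- assert_number(noise_sd, "noise_sd")
  if (noise_sd <= 0) stop_validation("`noise_sd` must be positive")
  seed <- assert_count(seed, "seed")
  structure(list(n_genes = n_genes, n_samples = n_samples,
                 block_assignments = as.character(block_assignments),
                 block_correlation = block_correlation,
                 noise_sd = noise_sd, seed = seed),
            class = "expr_block_spec")
}

#' Generate a block-correlated gene expression matrix
#'
#' Single-common-factor construction: for gene g in block b,
#' `x_g = sqrt(rho_b) * f_b + sqrt(1 - rho_b) * e_g`, with `f_b` a
#' block-shared standard normal factor and `e_g` independent noise of
#' standard deviation `noise_sd`. At `noise_sd = 1` the expected
#' within-block correlation is `rho_b`; across blocks it is zero.
#'
#' @param spec An [expr_block_spec()].
#' @return Numeric matrix, genes x samples, rownames `GENE###` and
#'   attribute `blocks` carrying the assignment.
#' @export
make_expression_matrix <- function(spec) {
  if (!inherits(spec, "expr_block_spec"))
    stop_validation("`spec` must be an expr_block_spec")
  withr::with_seed(spec$seed, {
    n <- spec$n_samples
    blocks <- spec$block_assignments
    factors <- lapply(stats::setNames(nm = unique(blocks)), function(b) stats::rnorm(n))
    x <- t(vapply(seq_len(spec$n_genes), function(i) {
      b <- blocks[i]
      rho <- spec$block_correlation[[b]]
      sqrt(rho) * factors[[b]] + sqrt(1 - rho) * stats::rnorm(n, sd = spec$noise_sd)
    }, numeric(n)))
    rownames(x) <- sprintf("GENE%03d", seq_len(spec$n_genes))
    colnames(x) <- sprintf("S%03d", seq_len(n))
    attr(x, "blocks") <- stats::setNames(blocks, rownames(x))
    x
  })
}

#' Write an expression matrix to TSV
#'
#' @param expr Genes x samples matrix.
#' @param path Output path.
#' @export
write_expression_tsv <- function(expr, path) {
  utils::write.table(data.frame(gene = rownames(expr), expr, check.names = FALSE),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
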