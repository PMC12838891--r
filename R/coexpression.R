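#' Co-expression partners of a gene
#'
#' Returns all genes whose expression across samples correlates with the
#' query gene at `|r| > r_thresh` with two-tailed `p < p_thresh`. The
#' p-value comes from the t transform of the Pearson coefficient,
#' `t = r * sqrt((n - 2) / (1 - r^2))` on `n - 2` degrees of freedom.
#'
#' @param expr Numeric matrix, genes x samples, with rownames.
#' @param gene Query gene symbol (must be a row of `expr`).
#' @param r_thresh Absolute-correlation threshold (default 0.5).
#' @param p_thresh Two-tailed p-value threshold (default 0.01).
#' @return Character vector of partner symbols (query excluded).
#' @examples
#' x <- make_expression_matrix(expr_block_spec(6, 50, rep(1:2, each = 3),
#'                                             0.95, seed = 2))
#' coexpression_partners(x, "GENE001")
#' @export
coexpression_partners <- function(expr, gene, r_thresh = 0.5, p_thresh = 0.01) {
  if (is.null(rownames(expr))) stop_validation("`expr` must have gene rownames")
  if (!gene %in% rownames(expr)) stop_validation("gene '%s' not in matrix", gene)
  n <- ncol(expr)
  if (n < 3L) stop_validation("need at least 3 samples")
  q <- expr[gene, ]
  if (stats::sd(q) == 0)
    stop_validation("query gene '%s' has zero variance", gene)

  sds <- apply(expr, 1L, stats::sd)
  r <- rep(NA_real_, nrow(expr))
  ok <- sds > 0
  r[ok] <- as.vector(stats::cor(q, t(expr[ok, , drop = FALSE])))
  tt <- r * sqrt((n - 2) / pmax(1 - r^2, .Machine$double.eps))
  p <- 2 * stats::pt(-abs(tt), df = n - 2)
  p[abs(r) >= 1] <- 0  # exact colinearity

  hit <- ok & abs(r) > r_thresh & p < p_thresh
  hit[rownames(expr) == gene] <- FALSE
  rownames(expr)[which(hit)]
}

#' Shared co-expression partners of two genes
#'
#' Intersection of the co-expression partner sets of two query genes;
#' symmetric in its gene arguments, and equal to a single partner set
#' when the two queries coincide.
#'
#' @inheritParams coexpression_partners
#' @param gene_a,gene_b Query gene symbols.
#' @return Character vector of symbols co-expressed with both queries
#'   (the queries themselves excluded).
#' @export
shared_partners <- function(expr, gene_a, gene_b, r_thresh = 0.5, p_thresh = 0.01) {
  pa <- coexpression_partners(expr, gene_a, r_thresh, p_thresh)
  if (identical(gene_a, gene_b)) return(pa)
  pb <- coexpression_partners(expr, gene_b, r_thresh, p_thresh)
  setdiff(intersect(pa, pb), c(gene_a, gene_b))
}

#' Coefficient of determination between two vectors
#'
#' The square of the Pearson correlation. Errors on constant input,
#' where the correlation is undefined.
#'
#' @param x,y Numeric vectors of equal length >= 3.
#' @return Single value in `[0, 1]`.
#' @examples
#' correlation_r2(1:10, 2 * (1:10) + 1)  # 1
#' @export
correlation_r2 <- function(x, y) {
  if (length(x) != length(y) || length(x) < 3L)
    stop_validation("x and y must have equal length >= 3")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop_validation("correlation undefined for constant input")
  stats::cor(x, y)^2
}
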