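#' Over-representation analysis with Benjamini-Hochberg correction
#'
#' For each annotation term, the p-value is the hypergeometric upper
#' tail `P(X >= overlap)` with population `|background|`, successes
#' `|term|`, and draws `|query|` (an overlap of 0 gives p = 1 under this
#' tail convention). False-discovery rates are Benjamini-Hochberg over
#' all terms tested.
#'
#' @param query [gene_set()] of interest; must be contained in
#'   `background`.
#' @param terms Named list of [gene_set()]s (or character vectors), each
#'   contained in `background`.
#' @param background [gene_set()] (or character vector) defining the
#'   population.
#' @return data.frame with one row per term: `term`, `overlap`,
#'   `term_size`, `query_size`, `background_size`, `p_value`, `fdr`,
#'   sorted by p-value.
#' @examples
#' bg <- gene_set("bg", sprintf("G%02d", 1:10))
#' q <- gene_set("q", sprintf("G%02d", 1:5), source = "derived")
#' enrichment(q, list(hit = sprintf("G%02d", 1:5)), bg)
#' @export
enrichment <- function(query, terms, background) {
  as_genes <- function(x) if (inherits(x, "gene_set")) x$genes else normalize_symbols(x)
  bg <- as_genes(background)
  q <- as_genes(query)
  if (length(setdiff(q, bg)))
    stop_validation("query contains genes outside the background: %s",
                    paste(utils::head(setdiff(q, bg), 5), collapse = ", "))
  if (length(terms) == 0L) stop_validation("no annotation terms supplied")
  if (is.null(names(terms))) stop_validation("`terms` must be a named list")

  rows <- lapply(names(terms), function(tm) {
    t_genes <- intersect(as_genes(terms[[tm]]), bg)
    k <- length(intersect(q, t_genes))
    # upper tail P(X >= k); phyper's lower.tail=FALSE gives P(X > k-1)
    p <- stats::phyper(k - 1, length(t_genes), length(bg) - length(t_genes),
                       length(q), lower.tail = FALSE)
    data.frame(term = tm, overlap = k, term_size = length(t_genes),
               query_size = length(q), background_size = length(bg),
               p_value = p, stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  res$fdr <- stats::p.adjust(res$p_value, method = "BH")
  res[order(res$p_value, res$term), , drop = FALSE]
}

#' Write enrichment results to TSV
#'
#' @param res data.frame from [enrichment()].
#' @param path Output path.
#' @export
write_enrichment_tsv <- function(res, path) {
  utils::write.table(res, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
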