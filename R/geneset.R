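#' Construct a named gene set
#'
#' A `gene_set` is a named collection of unique, case-normalized gene
#' symbols with a source tag recording whether the panel came from a
#' comorbidity, the index disease itself, or a derived operation.
#'
#' Symbols are upper-cased and whitespace-stripped on ingestion; mixed-case
#' duplicates collapse to a single symbol.
#'
#' @param name Character label for the set.
#' @param genes Character vector of gene symbols.
#' @param source One of `"comorbidity"`, `"osa"`, `"derived"`.
#' @return An object of class `gene_set` with elements `name`, `genes`,
#'   `source`.
#' @examples
#' gene_set("arrhythmia", c("KCNQ1", "scn5a ", "KCNQ1"))
#' @export
gene_set <- function(name, genes, source = c("comorbidity", "osa", "derived")) {
  source <- match.arg(source)
  genes <- normalize_symbols(genes)
  structure(list(name = as.character(name)[1], genes = genes, source = source),
            class = "gene_set")
}

#' @export
print.gene_set <- function(x, ...) {
  cat(sprintf("<gene_set> %s (%s): %d genes\n", x$name, x$source, length(x$genes)))
  invisible(x)
}

#' @export
length.gene_set <- function(x) length(x$genes)

#' Aggregate comorbidity panels into a deduplicated gene pool
#'
#' Forms the union of all panels and reports, per panel, its raw size and
#' how many of its genes appear in no other panel (its unique
#' contribution). Panels contributing zero unique genes are flagged,
#' mirroring the exclusion of non-contributing comorbidities from an
#' aggregated pool.
#'
#' @param panels List of [gene_set()] objects, all with source
#'   `"comorbidity"`.
#' @return A list with elements
#'   \describe{
#'     \item{pool}{`gene_set` holding the deduplicated union.}
#'     \item{report}{data.frame with columns `panel`, `size`,
#'       `unique_contribution`, `contributes` (FALSE when a panel adds no
#'       gene absent from every other panel).}
#'   }
#' @examples
#' a <- gene_set("A", c("g1", "g2")); b <- gene_set("B", c("g2", "g3"))
#' aggregate_pool(list(a, b))$report
#' @export
aggregate_pool <- function(panels) {
  if (!is.list(panels) || length(panels) == 0L)
    stop_validation("`panels` must be a non-empty list of gene_set objects")
  ok <- vapply(panels, function(p) inherits(p, "gene_set") && p$source == "comorbidity",
               logical(1))
  if (!all(ok))
    stop_validation("all panels must be gene_set objects with source 'comorbidity'")

  sets <- lapply(panels, `[[`, "genes")
  names(sets) <- vapply(panels, `[[`, character(1), "name")
  pool_genes <- sort(unique(unlist(sets, use.names = FALSE)))

  uniq <- vapply(seq_along(sets), function(i) {
    others <- unique(unlist(sets[-i], use.names = FALSE))
    sum(!(sets[[i]] %in% others))
  }, integer(1))

  report <- data.frame(
    panel = names(sets),
    size = vapply(sets, length, integer(1)),
    unique_contribution = uniq,
    contributes = uniq > 0L,
    row.names = NULL,
    stringsAsFactors = FALSE
  )
  list(pool = gene_set("pool", pool_genes, source = "comorbidity"), report = report)
}

#' Refine a disease gene set against a comorbidity pool
#'
#' The refined set is the overlap of the disease set with the pool,
#' augmented with an explicitly supplied subset of disease-unique genes.
#' The retained-unique subset is an argument (or the sentinel `"all"`)
#' rather than being derived, because the filter selecting which unique
#' genes survive is a curation decision upstream of this operation.
#'
#' @param pool `gene_set` from [aggregate_pool()].
#' @param osa `gene_set` of the index disease (source `"osa"`).
#' @param unique_retained Character vector of symbols in
#'   `setdiff(osa, pool)` to retain, or `"all"` to keep every
#'   disease-unique gene.
#' @return A `refined_set`: list with `genes` (character), `provenance`
#'   (named character, values `"comorbidity_overlap"` or `"osa_unique"`),
#'   `counts` (named integer of both classes), and an empty
#'   `phenotype_assignment` to be filled by [assign_phenotypes()].
#' @examples
#' pool <- gene_set("pool", c("A", "B", "C"))
#' osa <- gene_set("osa", c("B", "C", "D", "E"), source = "osa")
#' refine_set(pool, osa, unique_retained = "D")
#' @export
refine_set <- function(pool, osa, unique_retained = "all") {
  if (!inherits(pool, "gene_set") || !inherits(osa, "gene_set"))
    stop_validation("`pool` and `osa` must be gene_set objects")
  overlap <- intersect(osa$genes, pool$genes)
  osa_unique <- setdiff(osa$genes, pool$genes)

  if (identical(unique_retained, "all")) {
    retained <- osa_unique
  } else {
    retained <- normalize_symbols(unique_retained)
    bad <- setdiff(retained, osa_unique)
    if (length(bad))
      stop_validation("unique_retained contains genes not unique to the disease set: %s",
                      paste(bad, collapse = ", "))
  }

  genes <- c(sort(overlap), sort(retained))
  provenance <- stats::setNames(
    c(rep("comorbidity_overlap", length(overlap)), rep("osa_unique", length(retained))),
    genes)
  structure(list(
    genes = genes,
    provenance = provenance,
    counts = c(comorbidity_overlap = length(overlap), osa_unique = length(retained)),
    phenotype_assignment = NULL
  ), class = "refined_set")
}

#' @export
print.refined_set <- function(x, ...) {
  cat(sprintf("<refined_set> %d genes (%d comorbidity_overlap + %d osa_unique)\n",
              length(x$genes), x$counts[["comorbidity_overlap"]],
              x$counts[["osa_unique"]]))
  invisible(x)
}

#' Assign phenotype labels to a refined gene set
#'
#' Maps each covered gene to the phenotypes whose sets contain it.
#' A gene appearing in several phenotype sets is counted once per
#' phenotype in the tally; genes covered by no phenotype are reported as
#' uncovered.
#'
#' @param refined A `refined_set` from [refine_set()].
#' @param phenotype_map Named list: phenotype label -> character vector of
#'   symbols.
#' @return The `refined_set` with `phenotype_assignment` (named list gene
#'   -> character vector of phenotypes), `phenotype_counts` (named integer
#'   tally per phenotype) and `uncovered` (character vector).
#' @export
assign_phenotypes <- function(refined, phenotype_map) {
  if (!inherits(refined, "refined_set"))
    stop_validation("`refined` must be a refined_set")
  if (length(phenotype_map) && is.null(names(phenotype_map)))
    stop_validation("`phenotype_map` must be a named list")
  phenotype_map <- lapply(phenotype_map, normalize_symbols)

  assignment <- lapply(refined$genes, function(g) {
    names(phenotype_map)[vapply(phenotype_map, function(s) g %in% s, logical(1))]
  })
  names(assignment) <- refined$genes
  covered <- vapply(assignment, length, integer(1)) > 0L

  refined$phenotype_assignment <- assignment[covered]
  refined$phenotype_counts <- vapply(phenotype_map, function(s)
    sum(refined$genes %in% s), integer(1))
  refined$uncovered <- refined$genes[!covered]
  refined
}

# ---- readers / writers ------------------------------------------------------

#' Read gene sets from a GMT file
#'
#' One set per line: name, description, then member symbols,
#' tab-separated.
#'
#' @param path File path.
#' @param source Source tag applied to every set read.
#' @return List of [gene_set()] objects.
#' @export
read_gmt <- function(path, source = "comorbidity") {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  lapply(lines, function(ln) {
    parts <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    if (length(parts) < 3L)
      stop_validation("malformed GMT line (need name, description, >=1 symbol): %s",
                      substr(ln, 1, 60))
    gene_set(parts[1], parts[-(1:2)], source = source)
  })
}

#' Write gene sets to a GMT file
#'
#' @param sets List of `gene_set` objects.
#' @param path Output path.
#' @export
write_gmt <- function(sets, path) {
  lines <- vapply(sets, function(s)
    paste(c(s$name, s$source, s$genes), collapse = "\t"), character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read a one-symbol-per-line TSV gene panel
#'
#' The file may start with a `#name=<label>` header; other `#` lines are
#' comments.
#'
#' @param path File path.
#' @param source Source tag for the resulting set.
#' @return A [gene_set()].
#' @export
read_panel_tsv <- function(path, source = "comorbidity") {
  lines <- readLines(path, warn = FALSE)
  name <- sub("\\.[^.]*$", "", basename(path))
  hdr <- grep("^#name=", lines, value = TRUE)
  if (length(hdr)) name <- sub("^#name=", "", hdr[1])
  genes <- lines[!grepl("^#", lines)]
  gene_set(name, genes, source = source)
}

#' Write a refined set to TSV
#'
#' Columns: `symbol`, `provenance`, `phenotypes` (semicolon-joined; empty
#' when unassigned). [read_refined_tsv()] reproduces genes and provenance
#' exactly.
#'
#' @param refined A `refined_set`.
#' @param path Output path.
#' @export
write_refined_tsv <- function(refined, path) {
  phen <- vapply(refined$genes, function(g) {
    p <- refined$phenotype_assignment[[g]]
    if (is.null(p)) "" else paste(p, collapse = ";")
  }, character(1))
  df <- data.frame(symbol = refined$genes,
                   provenance = unname(refined$provenance[refined$genes]),
                   phenotypes = unname(phen),
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a refined set written by [write_refined_tsv()]
#'
#' @param path File path.
#' @return A `refined_set`.
#' @export
read_refined_tsv <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE, colClasses = "character")
  prov <- stats::setNames(df$provenance, df$symbol)
  res <- structure(list(
    genes = df$symbol,
    provenance = prov,
    counts = c(comorbidity_overlap = sum(prov == "comorbidity_overlap"),
               osa_unique = sum(prov == "osa_unique")),
    phenotype_assignment = NULL
  ), class = "refined_set")
  has_phen <- nzchar(df$phenotypes)
  if (any(has_phen)) {
    res$phenotype_assignment <- stats::setNames(
      strsplit(df$phenotypes[has_phen], ";", fixed = TRUE), df$symbol[has_phen])
  }
  res
}
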