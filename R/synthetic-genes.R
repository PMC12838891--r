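#' Specification for a synthetic comorbidity/disease gene universe
#'
#' Describes the count structure a synthetic gene universe must satisfy:
#' the sizes of the comorbidity panels, the size of the index-disease
#' (OSA) set, how many disease genes overlap the comorbidity pool, and how
#' many disease-unique genes are retained into the refined set.
#'
#' @param pool_panel_sizes Integer vector of genes per comorbidity panel.
#' @param osa_size Size of the disease gene set.
#' @param overlap_size Exact size of the disease/pool overlap.
#' @param unique_retained Number of disease-unique genes retained.
#' @param pool_distinct Optional number of distinct genes in the pool
#'   after deduplication across panels. Defaults to about 81% of the
#'   summed panel sizes (panels share genes), bounded by feasibility.
#' @param seed Integer seed; generators are pure functions of their spec.
#' @return An `overlap_spec` list.
#' @examples
#' overlap_spec(c(10, 12), osa_size = 20, overlap_size = 5,
#'              unique_retained = 3, seed = 1)
#' @export
overlap_spec <- function(pool_panel_sizes, osa_size, overlap_size,
                         unique_retained, pool_distinct = NULL, seed = 1L) {
  pool_panel_sizes <- vapply(seq_along(pool_panel_sizes), function(i)
    assert_count(pool_panel_sizes[i], sprintf("pool_panel_sizes[%d]", i), min = 1L),
    integer(1))
  osa_size <- assert_count(osa_size, "osa_size", min = 1L)
  overlap_size <- assert_count(overlap_size, "overlap_size")
  unique_retained <- assert_count(unique_retained, "unique_retained")
  seed <- assert_count(seed, "seed")

  total <- sum(pool_panel_sizes)
  if (is.null(pool_distinct)) {
    pool_distinct <- max(max(pool_panel_sizes), overlap_size,
                         as.integer(round(0.81 * total)))
    pool_distinct <- min(pool_distinct, total)
  }
  pool_distinct <- assert_count(pool_distinct, "pool_distinct", min = 1L)

  if (overlap_size > osa_size)
    stop_validation("infeasible spec: overlap_size (%d) > osa_size (%d)",
                    overlap_size, osa_size)
  if (overlap_size > pool_distinct)
    stop_validation("infeasible spec: overlap_size (%d) > distinct pool genes (%d)",
                    overlap_size, pool_distinct)
  if (pool_distinct > total)
    stop_validation("infeasible spec: pool_distinct (%d) > summed panel sizes (%d)",
                    pool_distinct, total)
  if (pool_distinct < max(pool_panel_sizes))
    stop_validation("infeasible spec: pool_distinct (%d) < largest panel (%d)",
                    pool_distinct, max(pool_panel_sizes))
  if (unique_retained > osa_size - overlap_size)
    stop_validation("infeasible spec: unique_retained (%d) > osa_size - overlap_size (%d)",
                    unique_retained, osa_size - overlap_size)

  structure(list(pool_panel_sizes = pool_panel_sizes, osa_size = osa_size,
                 overlap_size = overlap_size, unique_retained = unique_retained,
                 pool_distinct = pool_distinct, seed = seed),
            class = "overlap_spec")
}

#' The packaged study-condition overlap specification
#'
#' Thirteen comorbidity panels sized (76, 43, 164, 101, 232, 471, 593,
#' 607, 319, 113, 120, 100, 95), 2460 distinct pool genes after
#' deduplication, a 102-gene disease set overlapping the pool in exactly
#' 58 genes, and 8 disease-unique genes retained, yielding a 66-gene
#' refined ground truth.
#'
#' @param seed Integer seed.
#' @return An [overlap_spec()].
#' @export
study_overlap_spec <- function(seed = 1L) {
  overlap_spec(
    pool_panel_sizes = c(arrhythmia = 76, atrial_fibrillation = 43,
                         chronic_kidney_disease = 164, heart_failure = 101,
                         hypertension = 232, hypoxia = 471, inflammation = 593,
                         oxidative_stress = 607, reactive_oxygen_species = 319,
                         respiratory_control = 113, sleep_related = 120,
                         stroke = 100, type_2_diabetes = 95),
    osa_size = 102, overlap_size = 58, unique_retained = 8,
    pool_distinct = 2460, seed = seed)
}

#' Generate a synthetic gene universe with exact overlap structure
#'
#' Emits comorbidity panels, a disease gene set, and a provenance truth
#' table such that the disease set intersects the deduplicated panel
#' union in exactly `overlap_size` genes and exactly `unique_retained`
#' disease-unique genes are flagged as retained. Symbols are synthetic
#' and role-coded (`CMG` pool genes, `OSG` disease-unique genes) so
#' provenance is auditable; output is deterministic under the spec seed.
#'
#' @param spec An [overlap_spec()].
#' @return List with
#'   \describe{
#'     \item{panels}{list of [gene_set()] objects (one per panel).}
#'     \item{osa_set}{[gene_set()] of the disease genes.}
#'     \item{truth}{data.frame `gene`, `role` in
#'       `{comorbidity_only, comorbidity_overlap, osa_unique_retained,
#'       osa_unique_dropped}`.}
#'   }
#' @examples
#' u <- make_gene_universe(overlap_spec(c(8, 9), 20, 5, 15, seed = 7))
#' length(intersect(u$osa_set$genes,
#'                  unique(unlist(lapply(u$panels, `[[`, "genes")))))
#' @export
make_gene_universe <- function(spec) {
  if (!inherits(spec, "overlap_spec")) stop_validation("`spec` must be an overlap_spec")
  withr::with_seed(spec$seed, {
    sizes <- spec$pool_panel_sizes
    n_pool <- spec$pool_distinct
    panel_names <- names(sizes) %||% sprintf("panel%02d", seq_along(sizes))
    if (is.null(names(sizes))) names(sizes) <- panel_names

    pool_genes <- sprintf("CMG%05d", seq_len(n_pool))

    # fill panels to exact sizes while covering every pool gene at least
    # once: first deal one mandatory slot per gene round-robin over panels
    # with remaining capacity, then pad each panel with genes it lacks
    capacity <- sizes
    membership <- lapply(sizes, function(s) character(0))
    order_genes <- sample(pool_genes)
    for (g in order_genes) {
      open <- which(capacity > 0)
      pick <- if (length(open) == 1L) open else sample(open, 1L)
      membership[[pick]] <- c(membership[[pick]], g)
      capacity[pick] <- capacity[pick] - 1L
    }
    for (i in seq_along(membership)) {
      need <- sizes[i] - length(membership[[i]])
      if (need > 0) {
        avail <- setdiff(pool_genes, membership[[i]])
        membership[[i]] <- c(membership[[i]], sample(avail, need))
      }
    }

    shared <- sample(pool_genes, spec$overlap_size)
    n_unique <- spec$osa_size - spec$overlap_size
    uniq <- if (n_unique > 0) sprintf("OSG%04d", seq_len(n_unique)) else character(0)
    retained <- utils::head(uniq, spec$unique_retained)

    panels <- lapply(seq_along(membership), function(i)
      gene_set(panel_names[i], sort(membership[[i]]), source = "comorbidity"))
    osa_set <- gene_set("osa", c(shared, uniq), source = "osa")

    truth <- data.frame(
      gene = c(pool_genes, uniq),
      role = c(ifelse(pool_genes %in% shared, "comorbidity_overlap", "comorbidity_only"),
               ifelse(uniq %in% retained, "osa_unique_retained", "osa_unique_dropped")),
      stringsAsFactors = FALSE)

    list(panels = panels, osa_set = osa_set, truth = truth)
  })
}

#' Write synthetic gene panels to per-panel TSV files
#'
#' Each file is one-symbol-per-line with a `#name=` header, readable by
#' [read_panel_tsv()].
#'
#' @param panels List of `gene_set` objects.
#' @param dir Output directory (created if absent).
#' @return The directory, invisibly.
#' @export
write_panel_dir <- function(panels, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  for (p in panels) {
    writeLines(c(sprintf("#name=%s", p$name), p$genes),
               file.path(dir, paste0(p$name, ".tsv")))
  }
  invisible(dir)
}
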