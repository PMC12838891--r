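test_that("gene universe reproduces the requested overlap structure exactly", {
  # study conditions: 13 panels, 102-gene disease set, overlap 58, 8 retained
  u <- make_gene_universe(study_overlap_spec(seed = 11))
  union_genes <- unique(unlist(lapply(u$panels, `[[`, "genes")))
  expect_length(union_genes, 2460)
  expect_length(u$osa_set$genes, 102)
  expect_length(intersect(u$osa_set$genes, union_genes), 58)
  expect_equal(sum(u$truth$role == "osa_unique_retained"), 8)
  # refined ground truth = overlap + retained = 66
  expect_length(c(intersect(u$osa_set$genes, union_genes),
                  u$truth$gene[u$truth$role == "osa_unique_retained"]), 66)

  # small spec, verified by brute-force set arithmetic on the emitted lists
  u2 <- make_gene_universe(overlap_spec(c(8, 9, 7), osa_size = 20,
                                        overlap_size = 5, unique_retained = 15,
                                        seed = 4))
  un2 <- unique(unlist(lapply(u2$panels, `[[`, "genes")))
  expect_length(intersect(u2$osa_set$genes, un2), 5)
  expect_identical(sort(u2$truth$gene[u2$truth$role == "comorbidity_overlap"]),
                   sort(intersect(u2$osa_set$genes, un2)))
  expect_identical(vapply(u2$panels, function(p) length(p$genes), integer(1)),
                   c(8L, 9L, 7L))
})

test_that("zero overlap with nothing retained gives an empty refined truth", {
  u <- make_gene_universe(overlap_spec(c(6, 6), osa_size = 10, overlap_size = 0,
                                       unique_retained = 0, seed = 2))
  un <- unique(unlist(lapply(u$panels, `[[`, "genes")))
  expect_length(intersect(u$osa_set$genes, un), 0)
  expect_equal(sum(u$truth$role %in% c("comorbidity_overlap", "osa_unique_retained")), 0)
})

test_that("infeasible overlap specs fail validation naming the bound", {
  expect_error(overlap_spec(c(5, 5), osa_size = 4, overlap_size = 6,
                            unique_retained = 0),
               "overlap_size")
  expect_error(overlap_spec(c(5, 5), osa_size = 10, overlap_size = 2,
                            unique_retained = 9),
               "unique_retained")
})

test_that("generators are pure functions of their spec", {
  s <- overlap_spec(c(10, 12), 15, 4, 3, seed = 99)
  expect_identical(make_gene_universe(s), make_gene_universe(s))

  gs <- planted_graph_spec(3, 5, 0.7, 0.1, seed = 7)
  expect_true(igraph::identical_graphs(make_modular_graph(gs),
                                       make_modular_graph(gs)))

  es <- expr_block_spec(8, 30, rep(1:2, each = 4), 0.8, seed = 5)
  expect_identical(make_expression_matrix(es), make_expression_matrix(es))
})

test_that("planted graphs honor their density limits", {
  # deterministic limit: p_in = 1, p_out = 0 gives disjoint cliques
  g <- make_modular_graph(planted_graph_spec(2, 5, 1, 0, seed = 1))
  expect_equal(igraph::vcount(g), 10)
  expect_equal(igraph::ecount(g), 20)  # 2 * C(5,2)
  expect_equal(igraph::count_components(g), 2)

  g1 <- make_modular_graph(planted_graph_spec(1, 4, 1, 0, seed = 1))
  expect_equal(igraph::ecount(g1), 6)  # complete graph on 4 nodes

  # stochastic case: edge count within a conservative joint 99.9% band
  spec <- planted_graph_spec(3, 8, 0.8, 0.05, seed = 21)
  g2 <- make_modular_graph(spec)
  n_in <- 3 * choose(8, 2)
  n_out <- choose(3, 2) * 8 * 8
  lo <- qbinom(5e-4, n_in, 0.8) + qbinom(5e-4, n_out, 0.05)
  hi <- qbinom(1 - 5e-4, n_in, 0.8) + qbinom(1 - 5e-4, n_out, 0.05)
  expect_gte(igraph::ecount(g2), lo)
  expect_lte(igraph::ecount(g2), hi)
})

test_that("expression blocks attain their target correlation structure", {
  spec <- expr_block_spec(9, 200, rep(1:3, each = 3), 0.99, seed = 31)
  x <- make_expression_matrix(spec)
  cm <- cor(t(x))
  blocks <- attr(x, "blocks")
  same <- outer(blocks, blocks, "==")
  diag(same) <- NA
  expect_true(all(abs(cm[which(same)]) > 0.5))  # within-block pairs

  # independence limit: zero block correlation, large noise
  spec0 <- expr_block_spec(20, 500, seq_len(20), 0, noise_sd = 5, seed = 8)
  x0 <- make_expression_matrix(spec0)
  cm0 <- cor(t(x0))
  expect_lt(mean(abs(cm0[upper.tri(cm0)])), 0.1)
})

test_that("alert compound catalog carries its expected alerts", {
  cat <- make_alert_compounds()
  # every packaged alert has a positive example, plus alert-free controls
  expect_true(all(names(alert_catalog()) %in%
                    unlist(strsplit(cat$expected_alerts, ";"))))
  expect_true(any(cat$expected_alerts == ""))
  for (k in seq_len(nrow(cat))) {
    found <- structural_alerts(mol_from_smiles(cat$smiles[k], cat$name[k]))
    expected <- if (cat$expected_alerts[k] == "") character(0)
                else strsplit(cat$expected_alerts[k], ";")[[1]]
    expect_setequal(found, expected)
  }
})

test_that("the packaged docking fixture matches its source values", {
  t1 <- table1_fixture()
  expect_equal(nrow(t1), 20)
  lid <- t1[t1$compound == "LID" & t1$target == "CK1D", ]
  expect_equal(lid$vina_score, -8.0)
  expect_equal(lid$pocket_volume, 637)
  pfl <- t1[t1$compound == "PFL" & t1$target == "PINK1", ]
  expect_equal(pfl$vina_score, -11.2)
  expect_equal(pfl$pocket_volume, 3727)
})

test_that("synthetic writers round-trip through their readers", {
  u <- make_gene_universe(overlap_spec(c(5, 6), 8, 3, 2, seed = 3))
  dir <- withr::local_tempdir()
  write_panel_dir(u$panels, dir)
  back <- lapply(list.files(dir, full.names = TRUE), read_panel_tsv)
  expect_setequal(unlist(lapply(back, `[[`, "genes")),
                  unlist(lapply(u$panels, `[[`, "genes")))

  gmt <- file.path(dir, "sets.gmt")
  write_gmt(u$panels, gmt)
  back2 <- read_gmt(gmt)
  expect_identical(lapply(back2, `[[`, "genes"), lapply(u$panels, `[[`, "genes"))

  g <- make_modular_graph(planted_graph_spec(2, 4, 1, 0, seed = 2))
  ef <- file.path(dir, "edges.tsv")
  write_edge_list(g, ef)
  g2 <- read_edge_list(ef)
  expect_equal(igraph::ecount(g2), igraph::ecount(g))
  expect_setequal(igraph::V(g2)$name[igraph::degree(g2) > 0],
                  igraph::V(g)$name[igraph::degree(g) > 0])
})
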