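test_that("graph statistics follow their definitions", {
  tri <- interaction_graph(cbind(c("a", "b", "c"), c("b", "c", "a")))
  s <- graph_stats(tri)
  expect_equal(s$avg_degree, 2.0)
  expect_equal(s$avg_local_clustering, 1.0)

  path3 <- interaction_graph(cbind(c("a", "b"), c("b", "c")))
  expect_equal(graph_stats(path3)$avg_local_clustering, 0.0)

  expect_error(graph_stats(interaction_graph(matrix(character(0), 0, 2))),
               "empty")

  # invariant: avg_degree * n = 2E exactly, on random graphs
  for (seed in 1:5) {
    g <- make_modular_graph(planted_graph_spec(3, 6, 0.6, 0.1, seed = seed))
    s <- graph_stats(g)
    expect_equal(s$avg_degree * s$n_nodes, 2 * s$n_edges)
  }
})

test_that("a 66-node 171-edge graph reports average degree 5.18", {
  # any graph with those counts: build one deterministically
  set.seed(1)
  g <- igraph::sample_gnm(66, 171)
  igraph::V(g)$name <- sprintf("N%02d", 1:66)
  s <- graph_stats(g)
  expect_equal(round(s$avg_degree, 2), 5.18)
})

test_that("mcode recovers planted cliques and ignores sparse attachments", {
  g <- two_cliques_path_graph()
  mods <- mcode(g)
  expect_gte(length(mods), 2)
  expect_identical(mods[[1]]$nodes, sprintf("a%d", 1:5))
  expect_identical(mods[[2]]$nodes, sprintf("b%d", 1:5))
  # agreement with exhaustive densest-subgraph enumeration (13 nodes)
  brute <- densest_subgraph_bruteforce(g)
  expect_identical(mods[[1]]$nodes, brute$nodes)
  expect_equal(mods[[1]]$score, brute$score)
})

test_that("mcode handles degenerate graphs", {
  edgeless <- interaction_graph(matrix(character(0), 0, 2),
                                nodes = c("x", "y", "z"))
  expect_length(mcode(edgeless), 0)

  clique5 <- make_modular_graph(planted_graph_spec(1, 5, 1, 0, seed = 1))
  mods <- mcode(clique5)
  expect_length(mods, 1)
  expect_length(mods[[1]]$nodes, 5)
})

test_that("mcode exactly recovers planted modules across seeds", {
  for (seed in 1:20) {
    g <- make_modular_graph(planted_graph_spec(3, 6, 1, 0, seed = seed))
    mods <- mcode(g)
    expect_length(mods, 3)
    found <- rep(NA_integer_, igraph::vcount(g))
    names(found) <- igraph::V(g)$name
    for (k in seq_along(mods)) found[mods[[k]]$nodes] <- k
    truth <- igraph::V(g)$module
    expect_false(anyNA(found))
    expect_equal(mclust::adjustedRandIndex(found[igraph::V(g)$name], truth), 1)
  }
})

test_that("hypergeometric p-values equal brute-force enumeration", {
  bg <- sprintf("G%02d", 1:10)
  q <- bg[1:5]
  res <- enrichment(gene_set("q", q, source = "derived"),
                    list(full = q, half = bg[4:8], none = bg[6:10]),
                    gene_set("bg", bg))
  # complete overlap: p = 1 / C(10,5) = 1/252
  expect_equal(res$p_value[res$term == "full"], 1 / 252)
  # disjoint term: overlap 0 tail convention gives p = 1
  expect_equal(res$p_value[res$term == "none"], 1)
  # all terms against exhaustive enumeration on the 10-gene background
  for (tm in res$term) {
    term_genes <- list(full = q, half = bg[4:8], none = bg[6:10])[[tm]]
    expect_equal(res$p_value[res$term == tm], enum_hyper_p(bg, term_genes, q))
  }

  # a larger random case on a 12-gene background
  set.seed(9)
  bg2 <- sprintf("H%02d", 1:12)
  q2 <- sample(bg2, 6)
  t2 <- sample(bg2, 5)
  res2 <- enrichment(gene_set("q", q2, source = "derived"), list(t = t2),
                     gene_set("bg", bg2))
  expect_equal(res2$p_value, enum_hyper_p(bg2, t2, q2))
})

test_that("BH correction matches its closed form", {
  bg <- sprintf("G%02d", 1:10)
  q <- bg[1:4]
  # identical term sets give identical p; BH then equals that p for all
  terms <- stats::setNames(rep(list(bg[3:6]), 4), sprintf("t%d", 1:4))
  res <- enrichment(gene_set("q", q, source = "derived"), terms,
                    gene_set("bg", bg))
  expect_true(all(res$fdr == res$p_value[1]))
  # BH step formula on the sorted p-values
  m <- nrow(res)
  ps <- sort(res$p_value)
  manual <- rev(cummin(rev(pmin(1, m * ps / seq_len(m)))))
  expect_equal(sort(res$fdr), manual)
})

test_that("enrichment validates query containment", {
  bg <- gene_set("bg", c("A", "B"))
  expect_error(enrichment(gene_set("q", c("A", "Z"), source = "derived"),
                          list(t = "A"), bg),
               "outside the background")
})

test_that("edge-list reader applies the confidence threshold", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("a\tb\t0.9", "b\tc\t0.2", "c\td\t0.41"), path)
  g <- read_edge_list(path)
  expect_equal(igraph::ecount(g), 2)  # 0.2 edge dropped at the 0.4 default
})
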