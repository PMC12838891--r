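# shared fixture builders (all generated in code; nothing stored)

# two 5-cliques joined through a 3-node path: a1..a5, b1..b5, p1..p3
two_cliques_path_graph <- function() {
  clique_edges <- function(nodes) t(utils::combn(nodes, 2))
  a <- sprintf("a%d", 1:5)
  b <- sprintf("b%d", 1:5)
  p <- sprintf("p%d", 1:3)
  edges <- rbind(clique_edges(a), clique_edges(b),
                 cbind(c("a1", "p1", "p2", "p3"), c("p1", "p2", "p3", "b1")))
  interaction_graph(edges)
}

# brute-force hypergeometric upper tail by enumerating all draws of
# size q from a background of size n with term set `term`
enum_hyper_p <- function(background, term, query) {
  k_obs <- length(intersect(query, term))
  draws <- utils::combn(background, length(query), simplify = FALSE)
  mean(vapply(draws, function(s) length(intersect(s, term)) >= k_obs, logical(1)))
}

# parent molecules with usable ports, for randomized merge sweeps
merge_parent_pool <- function() {
  list(
    list(mol = mol_from_smiles("c1ccccc1", "benzene"), port = "aromatic_ch"),
    list(mol = mol_from_smiles("COc1ccccc1", "anisole"), port = "methoxy"),
    list(mol = mol_from_smiles("Oc1ccccc1", "phenol"), port = "phenol_oh"),
    list(mol = mol_from_smiles("OC(=O)c1ccccc1", "benzoic_acid"), port = "carboxyl"),
    list(mol = mol_from_smiles("COc1ccc(OC)cc1", "dimethoxybenzene"), port = "methoxy"),
    list(mol = mol_from_smiles("COc1ccc(cc1)[N+](C)(C)C", "methoxyphenyl_tma"),
         port = "methoxy")
  )
}
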