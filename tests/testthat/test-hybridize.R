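test_that("port detection finds the documented sites", {
  anis <- mol_from_smiles("COc1ccccc1", "anisole")
  p <- find_ports(anis, "methoxy")
  expect_length(p, 1)
  expect_true(anis$atoms$aromatic[p[[1]]$attach])
  expect_length(p[[1]]$detach, 2)  # O + CH3

  expect_length(find_ports(mol_from_smiles("c1ccccc1"), "methoxy"), 0)

  dim <- mol_from_smiles("COc1ccc(OC)cc1", "dimethoxybenzene")
  p2 <- find_ports(dim, "methoxy")
  expect_length(p2, 2)
  expect_true(p2[[1]]$attach < p2[[2]]$attach)  # ascending order

  expect_length(find_ports(mol_from_smiles("c1ccccc1"), "aromatic_ch"), 6)
  expect_length(find_ports(mol_from_smiles("OC(=O)c1ccccc1"), "carboxyl"), 1)
  expect_length(find_ports(mol_from_smiles("Oc1ccccc1"), "phenol_oh"), 1)
  expect_error(find_ports(anis, "no_such_port"), "unknown port")
})

test_that("direct merges do the atom bookkeeping", {
  benz <- mol_from_smiles("c1ccccc1", "benzene")
  pb <- find_ports(benz, "aromatic_ch")
  bip <- merge_scaffolds(benz, pb[[1]], mol_from_smiles("c1ccccc1"), pb[[2]])
  expect_equal(heavy_atom_count(bip), 12)
  expect_identical(bip$smiles, canonical_smiles("c1ccc(cc1)-c1ccccc1"))

  # methoxy port detaches OCH3 (2 heavy atoms): anisole + benzene -> biphenyl
  anis <- mol_from_smiles("COc1ccccc1", "anisole")
  pm <- find_ports(anis, "methoxy")
  bip2 <- merge_scaffolds(anis, pm[[1]], benz, pb[[1]])
  expect_equal(heavy_atom_count(bip2), 12)
  expect_identical(bip2$smiles, bip$smiles)
})

test_that("linker merges add the linker atoms", {
  benz <- mol_from_smiles("c1ccccc1", "benzene")
  pb <- find_ports(benz, "aromatic_ch")
  h <- merge_scaffolds(benz, pb[[1]], mol_from_smiles("c1ccccc1"), pb[[2]],
                       link = "ethylene")
  # 6 + 6 + 2 - 0 - 0
  expect_equal(heavy_atom_count(h), 14)
  expect_identical(h$smiles, canonical_smiles("c1ccccc1CCc1ccccc1"))

  h2 <- merge_scaffolds(benz, pb[[1]], mol_from_smiles("c1ccccc1"), pb[[2]],
                        link = "oxy")
  expect_identical(h2$smiles, canonical_smiles("c1ccccc1Oc1ccccc1"))
})

test_that("merges conserve heavy atoms and formal charge over random sweeps", {
  pool <- merge_parent_pool()
  linkers <- c("direct", names(linker_library()))
  linker_sizes <- c(direct = 0L,
                    vapply(linker_library(), function(l)
                      nrow(l$fragment$atoms), integer(1)))
  set.seed(2024)
  for (rep in 1:25) {
    pa <- pool[[sample(length(pool), 1)]]
    pb <- pool[[sample(length(pool), 1)]]
    sa <- find_ports(pa$mol, pa$port)
    sb <- find_ports(pb$mol, pb$port)
    if (!length(sa) || !length(sb)) next
    site_a <- sa[[sample(length(sa), 1)]]
    site_b <- sb[[sample(length(sb), 1)]]
    if (identical(pa$mol$smiles, pb$mol$smiles) &&
        identical(site_a$attach, site_b$attach)) next
    lk <- sample(linkers, 1)
    h <- merge_scaffolds(pa$mol, site_a, pb$mol, site_b, link = lk)
    expected_heavy <- heavy_atom_count(pa$mol) + heavy_atom_count(pb$mol) +
      linker_sizes[[lk]] - length(site_a$detach) - length(site_b$detach)
    expect_equal(heavy_atom_count(h), expected_heavy)
    detached_charge <- sum(pa$mol$atoms$charge[site_a$detach]) +
      sum(pb$mol$atoms$charge[site_b$detach])
    expect_equal(total_charge(h),
                 total_charge(pa$mol) + total_charge(pb$mol) - detached_charge)
    # output always round-trips unchanged
    expect_identical(mol_sanitize(h)$smiles, h$smiles)
  }
})

test_that("self-merging at the same position is rejected", {
  benz <- mol_from_smiles("c1ccccc1", "benzene")
  p <- find_ports(benz, "aromatic_ch")
  expect_error(merge_scaffolds(benz, p[[1]], benz, p[[1]]), "self-merge")
  # different positions on two copies are fine
  expect_s3_class(merge_scaffolds(benz, p[[1]], benz, p[[2]]), "molecule")
})

test_that("3D embedding produces sane, deterministic conformers", {
  methane <- mol_from_smiles("C", "methane")
  conf <- embed_3d(methane, seed = 7)
  expect_true(conf$success)
  expect_equal(nrow(conf$coords), 5)  # C + 4 explicit H
  # C-H bond lengths in the force-field equilibrium range
  for (k in seq_len(nrow(conf$bonds))) {
    d <- sqrt(sum((conf$coords[conf$bonds$i[k], ] - conf$coords[conf$bonds$j[k], ])^2))
    expect_gt(d, 1.0); expect_lt(d, 1.2)
  }
  expect_gt(min_nonbonded_distance(conf), 0.9)

  conf2 <- embed_3d(methane, seed = 7)
  expect_identical(conf$coords, conf2$coords)

  bip <- merge_scaffolds(mol_from_smiles("c1ccccc1", "b1"),
                         find_ports(mol_from_smiles("c1ccccc1"), "aromatic_ch")[[1]],
                         mol_from_smiles("c1ccccc1", "b2"),
                         find_ports(mol_from_smiles("c1ccccc1"), "aromatic_ch")[[2]])
  cb <- embed_3d(bip, seed = 1)
  expect_true(cb$success)
  expect_gt(min_nonbonded_distance(cb), 0.9)

  # invalid valence fails before embedding
  atoms <- data.frame(element = c("C", "F", "F", "F", "F", "F"),
                      charge = 0, aromatic = FALSE)
  bad <- molecule(atoms, data.frame(i = 1, j = 2:6, order = 1L))
  expect_error(embed_3d(bad), class = "comolead_chemistry")
})

test_that("conformers export to SDF", {
  conf <- embed_3d(mol_from_smiles("CCO", "ethanol"), seed = 3)
  path <- withr::local_tempfile(fileext = ".sdf")
  write_conformer_sdf(list(conf), path)
  txt <- readLines(path)
  expect_true(any(grepl("V2000", txt)))
  expect_true(any(grepl("\\$\\$\\$\\$", txt)))
})
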