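test_that("rule filters reproduce hand-evaluated violation counts", {
  # heavy, lipophilic compound: MW and logP both out of bounds
  d <- descriptor_set(mw = 629.73, logp_consensus = 5.23, hbd = 1, hba = 7)
  expect_equal(rule_filters(d)$Lipinski$n_violations, 2)

  eth <- compute_descriptors(mol_from_smiles("CCO", "ethanol"))
  rf <- rule_filters(eth)
  expect_equal(rf$Lipinski$n_violations, 0)
  expect_true(rf$Veber$pass)

  d3 <- descriptor_set(mw = 510, hbd = 6, hba = 11, logp_consensus = 4)
  expect_equal(rule_filters(d3)$Lipinski$n_violations, 3)
  expect_false(rule_filters(d3)$Lipinski$pass)  # pass needs <= 1
})

test_that("rule filters are monotone in each parameter", {
  base <- list(mw = 400, logp_consensus = 3, hbd = 2, hba = 5,
               logp_wlogp = 3, molar_refractivity = 90, heavy_atoms = 30,
               rotatable_bonds = 5, tpsa = 80, rings = 3, carbons = 20,
               heteroatoms = 5)
  worsen <- list(mw = 700, logp_consensus = 7, hbd = 8, hba = 12,
                 logp_wlogp = 7, molar_refractivity = 150, heavy_atoms = 80,
                 rotatable_bonds = 20, tpsa = 200, rings = 9)
  base_counts <- vapply(rule_filters(do.call(descriptor_set, base)),
                        `[[`, integer(1), "n_violations")
  for (param in names(worsen)) {
    mod <- base
    mod[[param]] <- worsen[[param]]
    counts <- vapply(rule_filters(do.call(descriptor_set, mod)),
                     `[[`, integer(1), "n_violations")
    expect_true(all(counts >= base_counts),
                info = sprintf("worsening %s decreased a violation count", param))
  }
})

test_that("ESOL reproduces its linear form", {
  expect_equal(esol_logs(descriptor_set(mw = 0, logp_consensus = 0,
                                        rotatable_bonds = 0,
                                        aromatic_proportion = 0)), 0.16)
  expect_equal(esol_logs(descriptor_set(mw = 200, logp_consensus = 2,
                                        rotatable_bonds = 2,
                                        aromatic_proportion = 0.5)), -2.578)
  # heavy lipophilic profile lands clearly in the poorly-soluble regime
  heavy <- descriptor_set(mw = 629.73, logp_consensus = 5.23,
                          rotatable_bonds = 8, aromatic_proportion = 0.6)
  expect_lt(esol_logs(heavy), -6)
})

test_that("solubility bands partition the real line with stated boundaries", {
  expect_equal(solubility_class(-1), "highly_soluble")
  expect_equal(solubility_class(-5), "moderately_soluble")
  expect_equal(solubility_class(-8.5), "insoluble")
  # boundaries go to the less-soluble band
  expect_equal(solubility_class(-2), "soluble")
  expect_equal(solubility_class(-4), "moderately_soluble")
  expect_equal(solubility_class(-6), "poorly_soluble")
  expect_equal(solubility_class(-8), "insoluble")
  # no gaps or overlaps: every value on a fine grid classifies uniquely
  grid <- seq(-12, 2, by = 0.01)
  cls <- solubility_class(grid)
  expect_false(anyNA(cls))
  expect_true(all(diff(match(cls, c("insoluble", "poorly_soluble",
                                    "moderately_soluble", "soluble",
                                    "highly_soluble"))) >= 0))
})

test_that("bioavailability score follows the published decision tree", {
  neutral_pass <- descriptor_set(mw = 300, logp_consensus = 2, hbd = 1, hba = 3)
  expect_equal(bioavailability_score(neutral_pass), 0.55)

  zwit_fail <- descriptor_set(mw = 629.73, logp_consensus = 5.23, hbd = 1,
                              hba = 7, ionization_class = "zwitterion")
  expect_equal(bioavailability_score(zwit_fail), 0.17)

  expect_equal(bioavailability_score(descriptor_set(tpsa = 60,
                                                    ionization_class = "anion")),
               0.85)
  expect_equal(bioavailability_score(descriptor_set(tpsa = 100,
                                                    ionization_class = "anion")),
               0.56)
  expect_equal(bioavailability_score(descriptor_set(tpsa = 160,
                                                    ionization_class = "anion")),
               0.11)
  # determinism
  expect_identical(bioavailability_score(neutral_pass),
                   bioavailability_score(neutral_pass))
})

test_that("structural alerts match their catalog", {
  expect_identical(structural_alerts(mol_from_smiles("C[N+](C)(C)C")),
                   "quaternary_nitrogen")
  expect_length(structural_alerts(mol_from_smiles("CCO")), 0)
  expect_identical(structural_alerts(mol_from_smiles("c1ccc(/C=C/c2ccccc2)cc1")),
                   "stilbene")
  # catalog file loading validates patterns
  path <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("# comment", "nitro\t[N+](=O)[O-]"), path)
  cat2 <- read_alert_catalog(path)
  expect_identical(structural_alerts(mol_from_smiles("O=[N+]([O-])c1ccccc1"),
                                     cat2), "nitro")
  writeLines("broken\t[[[", path)
  expect_error(read_alert_catalog(path), "failed to compile")
})

test_that("liability engine fires the documented categories on the fixtures", {
  profs <- read_adme_fixture()

  li_pflid <- identify_liabilities(profs$PFLID)
  expect_setequal(li_pflid$category,
                  c("lipophilicity", "solubility", "molecular_weight",
                    "bioavailability", "structural_alert", "druglikeness_failure"))
  expect_equal(li_pflid$category[1], "bioavailability")  # most severe first
  expect_equal(as.numeric(li_pflid$value[li_pflid$category == "lipophilicity"]), 5.23)
  expect_match(li_pflid$bound[li_pflid$category == "molecular_weight"], "600")

  li_iclid <- identify_liabilities(profs$ICLID)
  expect_true(all(c("lipophilicity", "solubility", "molecular_weight",
                    "structural_alert") %in% li_iclid$category))
  expect_equal(as.numeric(li_iclid$value[li_iclid$category == "solubility"]), -7.8)

  # fully compliant profile -> empty report
  clean <- adme_profile("clean",
                        descriptor_set(mw = 350, logp_consensus = 2.5, hbd = 2,
                                       hba = 5, logp_wlogp = 2.5, tpsa = 80,
                                       molar_refractivity = 90, heavy_atoms = 25,
                                       rotatable_bonds = 4, rings = 3,
                                       carbons = 18, heteroatoms = 6,
                                       aromatic_proportion = 0.4),
                        gi_absorption = "high")
  expect_equal(nrow(identify_liabilities(clean)), 0)
})

test_that("profile_molecule assembles a coherent profile from structure", {
  p <- profile_molecule(mol_from_smiles("CC(=O)NCCc1c[nH]c2ccc(OC)cc12",
                                        "melatonin"))
  expect_s3_class(p, "adme_profile")
  expect_true(p$rules$Lipinski$pass)
  expect_equal(p$ba_score, 0.55)
  expect_length(p$alerts, 0)
  expect_identical(p$solubility_class, solubility_class(p$log_s))
})
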