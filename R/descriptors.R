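#' Build a descriptor record directly from values
#'
#' Used both by [compute_descriptors()] and to assemble records from
#' literature-reported values (fixtures) when a structure is not
#' available. Any field may be `NA`; rule filters skip bounds whose
#' inputs are missing.
#'
#' @param mw Molecular weight, g/mol.
#' @param heavy_atoms Heavy-atom count.
#' @param fsp3 Fraction of sp3 carbons.
#' @param rotatable_bonds Rotatable-bond count.
#' @param hbd,hba Hydrogen-bond donor/acceptor counts.
#' @param molar_refractivity Molar refractivity.
#' @param tpsa Topological polar surface area, A^2.
#' @param logp_wlogp Atom-contribution (Wildman-Crippen) log P.
#' @param logp_consensus Consensus log P (mean of available estimators).
#' @param logp_all Numeric vector of all individual log P estimates
#'   available (used for the "any method above bound" liability check).
#' @param aromatic_proportion Fraction of heavy atoms that are aromatic.
#' @param rings Ring count (cyclomatic number).
#' @param carbons,heteroatoms Carbon / non-carbon-non-hydrogen counts.
#' @param formal_charge Net formal charge.
#' @param ionization_class One of `"neutral"`, `"anion"`, `"cation"`,
#'   `"zwitterion"`.
#' @return A `descriptor_set` list.
#' @export
descriptor_set <- function(mw = NA, heavy_atoms = NA, fsp3 = NA,
                           rotatable_bonds = NA, hbd = NA, hba = NA,
                           molar_refractivity = NA, tpsa = NA,
                           logp_wlogp = NA, logp_consensus = NA,
                           logp_all = NULL, aromatic_proportion = NA,
                           rings = NA, carbons = NA, heteroatoms = NA,
                           formal_charge = NA,
                           ionization_class = c("neutral", "anion", "cation",
                                                "zwitterion")) {
  ionization_class <- match.arg(ionization_class)
  if (is.null(logp_all))
    logp_all <- stats::na.omit(c(logp_wlogp, logp_consensus))
  structure(list(
    mw = mw, heavy_atoms = heavy_atoms, fsp3 = fsp3,
    rotatable_bonds = rotatable_bonds, hbd = hbd, hba = hba,
    molar_refractivity = molar_refractivity, tpsa = tpsa,
    logp_wlogp = logp_wlogp, logp_consensus = logp_consensus,
    logp_all = as.numeric(logp_all),
    aromatic_proportion = aromatic_proportion, rings = rings,
    carbons = carbons, heteroatoms = heteroatoms,
    formal_charge = formal_charge, ionization_class = ionization_class),
    class = "descriptor_set")
}

#' @export
print.descriptor_set <- function(x, ...) {
  cat(sprintf(paste0("<descriptor_set> MW %.2f, heavy %s, logP %.2f, TPSA %.1f, ",
                     "HBD %s, HBA %s, RB %s, %s\n"),
              x$mw, x$heavy_atoms, x$logp_consensus, x$tpsa, x$hbd, x$hba,
              x$rotatable_bonds, x$ionization_class))
  invisible(x)
}

mol_sdfset <- function(mol) {
  smi <- canonical_smiles(mol)
  nm <- if (nzchar(mol$name)) mol$name else "mol"
  ChemmineR::smiles2sdf(stats::setNames(smi, nm))
}

# count unique SMARTS matches on a molecule via the chemistry backend
smarts_count <- function(mol, smarts) {
  sdf <- mol_sdfset(mol)
  as.integer(ChemmineR::smartsSearchOB(sdf, smarts, uniqueMatches = TRUE))[1]
}

# rotatable bond: acyclic single bond between two non-terminal heavy
# atoms, excluding amide C-N
rotatable_bond_count <- function(mol) {
  if (!nrow(mol$bonds)) return(0L)
  deg <- atom_degree(mol)
  in_ring <- ring_bonds(mol)
  amide_cn <- function(i, j) {
    for (pair in list(c(i, j), c(j, i))) {
      c_at <- pair[1]; n_at <- pair[2]
      if (mol$atoms$element[c_at] == "C" && mol$atoms$element[n_at] == "N") {
        nb <- neighbors_of(mol, c_at)
        b <- mol$bonds
        has_dbl_o <- any(vapply(nb, function(x)
          mol$atoms$element[x] == "O" &&
            any(b$order[(b$i == c_at & b$j == x) | (b$j == c_at & b$i == x)] == 2L),
          logical(1)))
        if (has_dbl_o) return(TRUE)
      }
    }
    FALSE
  }
  n <- 0L
  for (k in seq_len(nrow(mol$bonds))) {
    i <- mol$bonds$i[k]; j <- mol$bonds$j[k]
    if (mol$bonds$order[k] != 1L || in_ring[k]) next
    if (deg[i] < 2L || deg[j] < 2L) next
    if (mol$atoms$element[i] == "H" || mol$atoms$element[j] == "H") next
    if (amide_cn(i, j)) next
    n <- n + 1L
  }
  n
}

classify_ionization <- function(charges) {
  pos <- sum(charges > 0) > 0
  neg <- sum(charges < 0) > 0
  if (pos && neg) "zwitterion"
  else if (pos) "cation"
  else if (neg) "anion"
  else "neutral"
}

#' Compute physicochemical descriptors of a molecule
#'
#' Molecular weight (implicit hydrogens included), topological polar
#' surface area (fragment contributions), atom-contribution
#' (Wildman-Crippen) log P, molar refractivity and H-bond donor count
#' come from the chemistry backend; acceptor count is the classic N+O
#' tally; graph-derived quantities (heavy atoms, rings, sp3 fraction,
#' aromatic proportion, rotatable bonds with the amide exclusion,
#' formal charge and ionization class) are computed on the package's
#' molecular graph. With a single packaged log P estimator the consensus
#' equals that estimator.
#'
#' @param mol A [molecule()].
#' @return A [descriptor_set()].
#' @examples
#' compute_descriptors(mol_from_smiles("CCO", "ethanol"))
#' @export
compute_descriptors <- function(mol) {
  if (!inherits(mol, "molecule")) stop_validation("`mol` must be a molecule")
  props <- tryCatch(ChemmineR::propOB(mol_sdfset(mol)),
                    error = function(e)
                      stop_chemistry("descriptor backend failed for %s: %s",
                                     mol$name, conditionMessage(e)))
  el <- mol$atoms$element
  heavy <- el != "H"
  carbons <- sum(el == "C")
  sp3_carbons <- sum(vapply(seq_along(el), function(i) {
    if (el[i] != "C" || mol$atoms$aromatic[i]) return(FALSE)
    b <- mol$bonds
    all(b$order[b$i == i | b$j == i] == 1L)
  }, logical(1)))
  n_rings <- nrow(mol$bonds) - nrow(mol$atoms) +
    igraph::count_components(mol_graph(mol))

  descriptor_set(
    mw = props$MW[1],
    heavy_atoms = sum(heavy),
    fsp3 = if (carbons > 0) sp3_carbons / carbons else NA_real_,
    rotatable_bonds = rotatable_bond_count(mol),
    hbd = props$HBD[1],
    hba = sum(el %in% c("N", "O")),
    molar_refractivity = props$MR[1],
    tpsa = props$TPSA[1],
    logp_wlogp = props$logP[1],
    logp_consensus = props$logP[1],
    logp_all = props$logP[1],
    aromatic_proportion = if (sum(heavy) > 0) sum(mol$atoms$aromatic & heavy) / sum(heavy)
                          else NA_real_,
    rings = n_rings,
    carbons = carbons,
    heteroatoms = sum(heavy & el != "C"),
    formal_charge = total_charge(mol),
    ionization_class = classify_ionization(mol$atoms$charge))
}
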