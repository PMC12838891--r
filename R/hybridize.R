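# Scaffold hybridization: linker-based merging of two parent molecular
# graphs at detected connection ports, with valence checking and
# re-perception, plus 3D embedding of the result.

#' Define a linker fragment
#'
#' A linker is a small molecule with two open attachment points given as
#' atom indices; at merge time a single bond is formed from each parent
#' attach atom to the corresponding linker end.
#'
#' @param name Linker name.
#' @param smiles Fragment SMILES.
#' @param attach1,attach2 Atom indices of the two open valences (may
#'   coincide for one-atom linkers).
#' @return A `linker` object.
#' @export
linker <- function(name, smiles, attach1 = 1L, attach2 = NULL) {
  frag <- mol_from_smiles(smiles, name = name)
  if (is.null(attach2)) attach2 <- nrow(frag$atoms)
  n <- nrow(frag$atoms)
  if (attach1 < 1 || attach1 > n || attach2 < 1 || attach2 > n)
    stop_validation("linker attach index outside fragment")
  # both ends must tolerate one more single bond
  used <- bond_order_sum(frag)
  cap <- max_valence(frag$atoms$element, frag$atoms$charge)
  extra <- as.integer(attach1 == attach2) + 1L
  if (used[attach1] + (if (attach1 == attach2) 2L else 1L) > cap[attach1] ||
      used[attach2] + 1L > cap[attach2])
    stop_chemistry("linker '%s' has no free valence at its attachment points", name)
  structure(list(name = name, fragment = frag,
                 attach1 = as.integer(attach1), attach2 = as.integer(attach2)),
            class = "linker")
}

#' The packaged linker library
#'
#' @return Named list of [linker()]s: `methylene` (-CH2-), `ethylene`
#'   (-CH2CH2-), `oxy` (-O-), `amine` (-NH-).
#' @export
linker_library <- function() {
  list(
    methylene = linker("methylene", "C"),
    ethylene = linker("ethylene", "CC"),
    oxy = linker("oxy", "O"),
    amine = linker("amine", "N")
  )
}

# drop detach atoms from a molecule, returning the reduced molecule and
# the new index of the attach atom
excise_port <- function(mol, site) {
  keep <- setdiff(seq_len(nrow(mol$atoms)), site$detach)
  if (!(site$attach %in% keep))
    stop_validation("port attach atom would be detached")
  remap <- stats::setNames(seq_along(keep), keep)
  b <- mol$bonds
  b <- b[b$i %in% keep & b$j %in% keep, , drop = FALSE]
  b$i <- remap[as.character(b$i)]
  b$j <- remap[as.character(b$j)]
  list(mol = molecule(mol$atoms[keep, , drop = FALSE], b, name = mol$name),
       attach = unname(remap[as.character(site$attach)]))
}

#' Merge two parent scaffolds at connection ports
#'
#' Removes each port's detachable atoms, then forms single bonds
#' `attachA - linker - attachB` (or a direct `attachA - attachB` bond).
#' The merged graph is valence-checked, must be a single connected
#' component, and is re-perceived and canonicalized through the
#' chemistry backend. Self-merging (both ports on the same structure at
#' the same position) is rejected.
#'
#' @param mol_a,mol_b Parent [molecule()]s.
#' @param port_a,port_b Port sites from [find_ports()] on the respective
#'   parents.
#' @param link A [linker()], the name of a packaged linker, or
#'   `"direct"`.
#' @param name Name for the hybrid.
#' @return The sanitized hybrid `molecule`.
#' @examples
#' benz <- mol_from_smiles("c1ccccc1", "benzene")
#' p <- find_ports(benz, "aromatic_ch")
#' merge_scaffolds(benz, p[[1]], mol_from_smiles("c1ccccc1"), p[[2]])
#' @export
merge_scaffolds <- function(mol_a, port_a, mol_b, port_b, link = "direct",
                            name = "hybrid") {
  for (p in list(port_a, port_b))
    if (!is.list(p) || is.null(p$attach))
      stop_validation("ports must be sites returned by find_ports()")
  if (identical(canonical_smiles(mol_a), canonical_smiles(mol_b)) &&
      identical(port_a$attach, port_b$attach) &&
      identical(port_a$detach, port_b$detach))
    stop_validation("self-merge rejected: both ports address the same position of the same structure")

  if (is.character(link) && !identical(link, "direct")) {
    lib <- linker_library()
    if (!link %in% names(lib))
      stop_validation("unknown linker '%s'; packaged linkers: %s", link,
                      paste(names(lib), collapse = ", "))
    link <- lib[[link]]
  }

  ea <- excise_port(mol_a, port_a)
  eb <- excise_port(mol_b, port_b)
  na <- nrow(ea$mol$atoms)

  atoms <- rbind(ea$mol$atoms, eb$mol$atoms)
  bonds <- rbind(ea$mol$bonds,
                 transform(eb$mol$bonds, i = i + na, j = j + na))
  attach_b <- eb$attach + na

  if (identical(link, "direct")) {
    bonds <- rbind(bonds, data.frame(i = ea$attach, j = attach_b, order = 1L))
  } else {
    if (!inherits(link, "linker")) stop_validation("`link` must be a linker or 'direct'")
    nl <- nrow(link$fragment$atoms)
    off <- nrow(atoms)
    atoms <- rbind(atoms, link$fragment$atoms)
    if (nrow(link$fragment$bonds))
      bonds <- rbind(bonds, transform(link$fragment$bonds, i = i + off, j = j + off))
    bonds <- rbind(bonds,
                   data.frame(i = ea$attach, j = off + link$attach1, order = 1L),
                   data.frame(i = attach_b, j = off + link$attach2, order = 1L))
  }

  hybrid <- molecule(atoms, bonds, name = name)
  check_valences(hybrid)
  if (!is_connected_mol(hybrid))
    stop("internal error: merged scaffold is disconnected")
  mol_sanitize(hybrid)
}

# conformers computed this session, keyed by canonical SMILES + seed;
# the backend's conformer generator draws from a global time-seeded
# random state, so reproducibility is provided by caching the first
# result for each key rather than by reseeding the generator
.embed_cache <- new.env(parent = emptyenv())

#' Embed a molecule in 3D
#'
#' Generates all-atom coordinates (hydrogens made explicit) by the
#' chemistry backend's structure builder followed by force-field
#' cleanup. The backend's conformer search uses a global random state
#' that cannot be seeded from R, so `embed_3d` guarantees its
#' determinism contract by caching: within a session, the same molecule
#' and seed always return identical coordinates. Coordinates may differ
#' between sessions; bonded topology, stoichiometry and geometric
#' sanity (bond lengths, non-bonded clearance) do not. Embedding
#' failure is reported as a flagged result rather than an error so that
#' batch pipelines continue.
#'
#' @param mol A [molecule()].
#' @param seed Integer seed (cache key component; recorded on the
#'   conformer).
#' @return A `conformer`: list with `atoms` (element/charge data.frame,
#'   hydrogens explicit), `bonds`, `coords` (n x 3, Angstrom), `name`,
#'   `seed`, `success`. On failure `success` is `FALSE` and `coords` is
#'   `NULL`.
#' @export
embed_3d <- function(mol, seed = 1L) {
  check_valences(mol)
  seed <- assert_count(seed, "seed")
  smi <- canonical_smiles(mol)
  key <- paste0(smi, "#", seed)
  if (!is.null(.embed_cache[[key]])) {
    cached <- .embed_cache[[key]]
    cached$name <- mol$name
    return(cached)
  }
  res <- tryCatch({
    mb <- ob_convert("SMI", "SDF", paste0(smi, "\tmol\n"), gen3d = TRUE)
    parse_molblock(mb)
  }, error = function(e) NULL)
  if (is.null(res)) {
    warning(sprintf("3D embedding failed for %s", mol$name))
    return(structure(list(atoms = NULL, bonds = NULL, coords = NULL,
                          name = mol$name, seed = seed, success = FALSE),
                     class = "conformer"))
  }
  conf <- structure(list(atoms = res$atoms, bonds = res$bonds,
                         coords = res$coords, name = mol$name,
                         seed = seed, success = TRUE),
                    class = "conformer")
  .embed_cache[[key]] <- conf
  conf
}

#' Minimum non-bonded interatomic distance of a conformer
#'
#' @param conf A `conformer` from [embed_3d()].
#' @return Smallest distance (Angstrom) between atom pairs that do not
#'   share a bond; `Inf` when fewer than two non-bonded pairs exist.
#' @export
min_nonbonded_distance <- function(conf) {
  if (!isTRUE(conf$success)) stop_validation("conformer has no coordinates")
  d <- as.matrix(stats::dist(conf$coords))
  bonded <- matrix(FALSE, nrow(d), ncol(d))
  if (nrow(conf$bonds))
    bonded[cbind(conf$bonds$i, conf$bonds$j)] <- TRUE
  bonded <- bonded | t(bonded)
  diag(bonded) <- TRUE
  vals <- d[!bonded]
  if (!length(vals)) Inf else min(vals)
}

#' @export
print.conformer <- function(x, ...) {
  if (isTRUE(x$success))
    cat(sprintf("<conformer> %s: %d atoms embedded\n", x$name, nrow(x$coords)))
  else cat(sprintf("<conformer> %s: embedding FAILED\n", x$name))
  invisible(x)
}

#' @rdname write_sdf
#' @export
write_conformer_sdf <- function(mols, path) {
  blocks <- vapply(mols, function(m) {
    if (inherits(m, "conformer")) {
      if (!isTRUE(m$success)) stop_validation("cannot write failed conformer '%s'", m$name)
      mm <- molecule(m$atoms, m$bonds, name = m$name)
      mol_to_molblock(mm, coords = m$coords)
    } else mol_to_molblock(m)
  }, character(1))
  writeLines(blocks, path)
  invisible(path)
}
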