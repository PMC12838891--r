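# Molecular graphs.
#
# Parsing, canonicalization and 3D embedding are delegated to Open Babel
# (ChemmineOB); the editable graph representation, valence accounting and
# substructure machinery used for scaffold hybridization live here.

ob_convert <- function(from, to, source, gen3d = FALSE) {
  opts <- if (gen3d) data.frame(names = "gen3D", args = "med")
          else data.frame(names = "gen2D", args = "")
  out <- tryCatch(
    suppressWarnings(ChemmineOB::convertFormat(from, to, source, options = opts)),
    error = function(e) "")
  if (!nzchar(trimws(out)))
    stop_chemistry("Open Babel could not convert input (%s -> %s)", from, to)
  out
}

# decode the V2000 atom-line charge field (superseded by M CHG when present)
mdl_charge <- function(code) c(0, 3, 2, 1, 0, -1, -2, -3)[code + 1L]

parse_molblock <- function(text) {
  lines <- strsplit(text, "\n", fixed = TRUE)[[1]]
  counts <- strsplit(trimws(lines[4]), "\\s+")[[1]]
  n_atoms <- as.integer(substr(lines[4], 1, 3))
  n_bonds <- as.integer(substr(lines[4], 4, 6))
  if (is.na(n_atoms)) {  # loosely formatted counts line
    n_atoms <- as.integer(counts[1]); n_bonds <- as.integer(counts[2])
  }
  atom_lines <- lines[4 + seq_len(n_atoms)]
  afields <- strsplit(trimws(atom_lines), "\\s+")
  coords <- t(vapply(afields, function(f) as.numeric(f[1:3]), numeric(3)))
  element <- vapply(afields, `[[`, character(1), 4L)
  charge <- vapply(afields, function(f) mdl_charge(as.integer(f[5])), numeric(1))

  bonds <- if (n_bonds > 0) {
    bl <- lines[4 + n_atoms + seq_len(n_bonds)]
    data.frame(
      i = as.integer(substr(bl, 1, 3)),
      j = as.integer(substr(bl, 4, 6)),
      order = as.integer(substr(bl, 7, 9)))
  } else data.frame(i = integer(0), j = integer(0), order = integer(0))

  chg_lines <- grep("^M  CHG", lines, value = TRUE)
  if (length(chg_lines)) {
    charge <- rep(0, n_atoms)
    for (ln in chg_lines) {
      f <- as.integer(strsplit(trimws(sub("^M  CHG", "", ln)), "\\s+")[[1]])
      n <- f[1]
      for (k in seq_len(n)) charge[f[2 * k]] <- f[2 * k + 1]
    }
  }
  list(atoms = data.frame(element = element, charge = charge,
                          stringsAsFactors = FALSE),
       bonds = bonds, coords = coords)
}

# aromatic atom flags from a MOL2 conversion of the same SMILES: Open
# Babel writes SYBYL types like C.ar/N.ar and atom order follows the
# input SMILES parse, matching the SDF conversion
mol2_aromatic <- function(smiles_line) {
  txt <- ob_convert("SMI", "MOL2", smiles_line)
  lines <- strsplit(txt, "\n", fixed = TRUE)[[1]]
  a0 <- which(lines == "@<TRIPOS>ATOM")
  if (!length(a0)) return(logical(0))
  sections <- grep("^@<TRIPOS>", lines)
  a1 <- min(sections[sections > a0[1]], length(lines) + 1L)
  at <- lines[(a0[1] + 1):(a1 - 1)]
  at <- at[nzchar(trimws(at))]
  types <- vapply(strsplit(trimws(at), "\\s+"), `[[`, character(1), 6L)
  grepl("\\.ar$", types)
}

#' Construct a molecule from components
#'
#' A `molecule` is an editable molecular graph: heavy atoms with element
#' symbol, formal charge and an aromatic flag, and bonds with integer
#' kekule order. Hydrogens are implicit. Most users will build molecules
#' with [mol_from_smiles()] instead.
#'
#' @param atoms data.frame with columns `element`, `charge`, `aromatic`.
#' @param bonds data.frame with columns `i`, `j`, `order` (1, 2, 3).
#' @param name Molecule name.
#' @param smiles Canonical SMILES, if known.
#' @return A `molecule` object.
#' @export
molecule <- function(atoms, bonds, name = "", smiles = NA_character_) {
  if (!all(c("element", "charge") %in% names(atoms)))
    stop_validation("`atoms` needs element and charge columns")
  if (is.null(atoms$aromatic)) atoms$aromatic <- FALSE
  n <- nrow(atoms)
  if (nrow(bonds)) {
    if (any(bonds$i < 1 | bonds$i > n | bonds$j < 1 | bonds$j > n))
      stop_validation("bond endpoint outside atom range")
    if (any(bonds$i == bonds$j)) stop_validation("self-bond not allowed")
    key <- paste(pmin(bonds$i, bonds$j), pmax(bonds$i, bonds$j))
    if (anyDuplicated(key)) stop_validation("duplicate bond")
  }
  structure(list(atoms = atoms, bonds = bonds, name = as.character(name),
                 smiles = smiles),
            class = "molecule")
}

#' Parse a SMILES string into a molecule
#'
#' Open Babel performs the parse, valence completion and aromaticity
#' perception; the result is the heavy-atom kekule graph plus per-atom
#' aromatic flags and the canonical SMILES form.
#'
#' @param smiles A SMILES string.
#' @param name Optional molecule name.
#' @return A [molecule()].
#' @examples
#' mol_from_smiles("COc1ccccc1", "anisole")
#' @export
mol_from_smiles <- function(smiles, name = "") {
  line <- paste0(smiles, "\t", if (nzchar(name)) name else "mol", "\n")
  mb <- ob_convert("SMI", "SDF", line)
  parsed <- parse_molblock(mb)
  arom <- mol2_aromatic(line)
  if (length(arom) == nrow(parsed$atoms)) parsed$atoms$aromatic <- arom
  else parsed$atoms$aromatic <- FALSE
  can <- canonical_smiles(smiles)
  molecule(parsed$atoms, parsed$bonds, name = name, smiles = can)
}

#' Canonical SMILES of a SMILES string or molecule
#'
#' @param x SMILES string or `molecule`.
#' @return Canonical SMILES (Open Babel canonicalization).
#' @export
canonical_smiles <- function(x) {
  if (inherits(x, "molecule")) {
    if (!is.na(x$smiles)) return(x$smiles)
    out <- ob_convert("SDF", "CAN", mol_to_molblock(x))
  } else {
    out <- ob_convert("SMI", "CAN", paste0(x, "\n"))
  }
  strsplit(trimws(out), "\\s+")[[1]][1]
}

#' @export
print.molecule <- function(x, ...) {
  cat(sprintf("<molecule> %s: %d heavy atoms, %d bonds, charge %+d\n  %s\n",
              if (nzchar(x$name)) x$name else "(unnamed)",
              nrow(x$atoms), nrow(x$bonds), total_charge(x),
              if (is.na(x$smiles)) "(no SMILES)" else x$smiles))
  invisible(x)
}

#' Heavy-atom count of a molecule
#' @param mol A `molecule`.
#' @return Integer count of non-hydrogen atoms.
#' @export
heavy_atom_count <- function(mol) sum(mol$atoms$element != "H")

#' Total formal charge of a molecule
#' @param mol A `molecule`.
#' @return Integer net formal charge.
#' @export
total_charge <- function(mol) as.integer(sum(mol$atoms$charge))

# igraph view of the bond graph (atoms as vertices 1..n)
mol_graph <- function(mol) {
  igraph::graph_from_data_frame(
    if (nrow(mol$bonds)) mol$bonds[, c("i", "j")] else data.frame(i = integer(0), j = integer(0)),
    directed = FALSE,
    vertices = data.frame(name = as.character(seq_len(nrow(mol$atoms)))))
}

# ring-bond flags: an edge lies on a cycle iff it is not a bridge
ring_bonds <- function(mol) {
  if (!nrow(mol$bonds)) return(logical(0))
  g <- mol_graph(mol)
  br <- igraph::bridges(g)
  in_ring <- rep(TRUE, nrow(mol$bonds))
  in_ring[as.integer(br)] <- FALSE
  in_ring
}

# per-atom sum of kekule bond orders
bond_order_sum <- function(mol) {
  v <- rep(0L, nrow(mol$atoms))
  if (nrow(mol$bonds)) {
    for (k in seq_len(nrow(mol$bonds))) {
      v[mol$bonds$i[k]] <- v[mol$bonds$i[k]] + mol$bonds$order[k]
      v[mol$bonds$j[k]] <- v[mol$bonds$j[k]] + mol$bonds$order[k]
    }
  }
  v
}

# heavy-atom degree (neighbor count)
atom_degree <- function(mol) {
  v <- rep(0L, nrow(mol$atoms))
  if (nrow(mol$bonds)) {
    tab <- table(factor(c(mol$bonds$i, mol$bonds$j), levels = seq_len(nrow(mol$atoms))))
    v <- as.integer(tab)
  }
  v
}

neighbors_of <- function(mol, idx) {
  b <- mol$bonds
  sort(unique(c(b$j[b$i == idx], b$i[b$j == idx])))
}

# maximum permitted valence for the organic subset, adjusted by formal
# charge (N+ -> 4, O- -> 1, ...)
max_valence <- function(element, charge) {
  base <- c(H = 1, B = 3, C = 4, N = 3, O = 2, F = 1, Si = 4, P = 5,
            S = 6, Cl = 1, Br = 1, I = 1)
  b <- base[element]
  b[is.na(b)] <- 8  # exotic elements: effectively unchecked
  adj <- element %in% c("B", "C", "N", "O", "P", "S")
  b[adj] <- b[adj] + charge[adj]
  unname(b)
}

#' Check valences of a molecule
#'
#' Verifies that every atom's summed kekule bond order does not exceed
#' its charge-adjusted maximum valence; the remainder is filled by
#' implicit hydrogens.
#'
#' @param mol A `molecule`.
#' @return Invisibly `TRUE`; errors (class `comolead_chemistry`) naming
#'   the first offending atom otherwise.
#' @export
check_valences <- function(mol) {
  used <- bond_order_sum(mol)
  cap <- max_valence(mol$atoms$element, mol$atoms$charge)
  bad <- which(used > cap)
  if (length(bad))
    stop_chemistry("valence violation at atom %d (%s: %d bonds > max %d)",
                   bad[1], mol$atoms$element[bad[1]], used[bad[1]], cap[bad[1]])
  invisible(TRUE)
}

is_connected_mol <- function(mol) {
  if (nrow(mol$atoms) <= 1L) return(TRUE)
  igraph::is_connected(mol_graph(mol))
}

#' Serialize a molecule to a V2000 molblock
#'
#' @param mol A `molecule`.
#' @param coords Optional n x 3 coordinate matrix (default zeros).
#' @return Molblock text.
#' @export
mol_to_molblock <- function(mol, coords = NULL) {
  n <- nrow(mol$atoms)
  if (is.null(coords)) coords <- matrix(0, n, 3)
  header <- c(if (nzchar(mol$name)) mol$name else "mol", "  comolead", "")
  counts <- sprintf("%3d%3d  0  0  0  0  0  0  0  0999 V2000", n, nrow(mol$bonds))
  atoms <- vapply(seq_len(n), function(i)
    sprintf("%10.4f%10.4f%10.4f %-3s 0  0  0  0  0  0  0  0  0  0  0  0",
            coords[i, 1], coords[i, 2], coords[i, 3], mol$atoms$element[i]),
    character(1))
  bonds <- if (nrow(mol$bonds))
    sprintf("%3d%3d%3d  0  0  0  0", mol$bonds$i, mol$bonds$j, mol$bonds$order)
  else character(0)
  chg_idx <- which(mol$atoms$charge != 0)
  chg <- character(0)
  if (length(chg_idx)) {
    groups <- split(chg_idx, ceiling(seq_along(chg_idx) / 8))
    chg <- vapply(groups, function(ix)
      paste0(sprintf("M  CHG%3d", length(ix)),
             paste0(sprintf("%4d%4d", ix, mol$atoms$charge[ix]), collapse = "")),
      character(1))
  }
  paste(c(header, counts, atoms, bonds, chg, "M  END", "$$$$"), collapse = "\n")
}

#' Re-perceive and canonicalize an edited molecule
#'
#' Round-trips the molecule through Open Babel (molblock to canonical
#' SMILES and back), re-perceiving aromaticity and validating that the
#' structure is chemically parseable.
#'
#' @param mol A `molecule`.
#' @return A sanitized `molecule` with canonical SMILES set.
#' @export
mol_sanitize <- function(mol) {
  check_valences(mol)
  can <- ob_convert("SDF", "CAN", mol_to_molblock(mol))
  can <- strsplit(trimws(can), "\\s+")[[1]][1]
  out <- mol_from_smiles(can, name = mol$name)
  out
}

#' Read molecules from a SMILES file
#'
#' One molecule per line: SMILES, optionally followed by whitespace and
#' a name. Lines starting with `#` are comments.
#'
#' @param path File path.
#' @return List of [molecule()] objects.
#' @export
read_smiles_file <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines)) & !grepl("^#", lines)]
  lapply(lines, function(ln) {
    parts <- strsplit(trimws(ln), "\\s+")[[1]]
    mol_from_smiles(parts[1], name = if (length(parts) > 1) parts[2] else "")
  })
}

#' Write molecules to an SDF file
#'
#' `write_sdf()` writes flat (2D, zero-coordinate) molblocks;
#' `write_conformer_sdf()` additionally accepts conformers from
#' [embed_3d()] and writes their 3D coordinates.
#'
#' @param mols List of `molecule` objects (for `write_conformer_sdf`,
#'   conformers are allowed too).
#' @param path Output path.
#' @export
write_sdf <- function(mols, path) {
  blocks <- vapply(mols, mol_to_molblock, character(1))
  writeLines(blocks, path)
  invisible(path)
}
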