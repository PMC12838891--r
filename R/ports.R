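# Connection-port detection for scaffold hybridization.
#
# A port is a position on a parent scaffold where a substituent can be
# replaced by a bond to a partner scaffold: an attach atom that remains,
# plus a (possibly empty) set of detachable atoms that are removed at
# merge time. The packaged library covers the substituent classes used
# in linker-based conjugation: methoxy groups, terminal aromatic C-H
# positions, carboxyl O-H and phenol O-H. Each port records a SMARTS
# string documenting the pattern; matching itself runs on the package's
# molecular graph so that atom indices are available (needed for graph
# editing).

#' Define a connection-port specification
#'
#' @param name Port name.
#' @param pattern SMARTS-class pattern string documenting the matched
#'   substructure.
#' @param matcher Function `(mol) -> list of sites`, each site a list
#'   with `attach` (atom index kept) and `detach` (integer vector of
#'   atom indices removed).
#' @return A `port_spec`.
#' @export
port_spec <- function(name, pattern, matcher) {
  stopifnot(is.function(matcher))
  structure(list(name = name, pattern = pattern, matcher = matcher),
            class = "port_spec")
}

# methyl carbon: degree-1 carbon with a single bond
is_methyl <- function(mol, idx) {
  mol$atoms$element[idx] == "C" && atom_degree(mol)[idx] == 1L &&
    all(mol$bonds$order[mol$bonds$i == idx | mol$bonds$j == idx] == 1L)
}

match_methoxy <- function(mol) {
  deg <- atom_degree(mol)
  sites <- list()
  for (o in which(mol$atoms$element == "O" & mol$atoms$charge == 0 & deg == 2)) {
    nb <- neighbors_of(mol, o)
    ords <- vapply(nb, function(x) {
      b <- mol$bonds
      b$order[(b$i == o & b$j == x) | (b$j == o & b$i == x)]
    }, integer(1))
    if (any(ords != 1L)) next
    me <- nb[vapply(nb, function(x) is_methyl(mol, x), logical(1))]
    ar <- nb[mol$atoms$aromatic[nb] & mol$atoms$element[nb] == "C"]
    ar <- setdiff(ar, me)
    if (length(me) >= 1L && length(ar) >= 1L)
      sites[[length(sites) + 1L]] <- list(attach = ar[1], detach = c(o, me[1]))
  }
  sites
}

match_aromatic_ch <- function(mol) {
  deg <- atom_degree(mol)
  idx <- which(mol$atoms$element == "C" & mol$atoms$aromatic &
                 mol$atoms$charge == 0 & deg == 2)
  lapply(idx, function(i) list(attach = i, detach = integer(0)))
}

match_carboxyl <- function(mol) {
  deg <- atom_degree(mol)
  sites <- list()
  for (c_at in which(mol$atoms$element == "C")) {
    nb <- neighbors_of(mol, c_at)
    b <- mol$bonds
    get_ord <- function(x)
      b$order[(b$i == c_at & b$j == x) | (b$j == c_at & b$i == x)]
    os <- nb[mol$atoms$element[nb] == "O"]
    dbl_o <- os[vapply(os, function(x) get_ord(x) == 2L, logical(1))]
    oh <- os[vapply(os, function(x)
      get_ord(x) == 1L && deg[x] == 1L && mol$atoms$charge[x] == 0, logical(1))]
    if (length(dbl_o) == 1L && length(oh) == 1L)
      # acyl port: the hydroxyl leaves, the carbonyl carbon bonds on
      sites[[length(sites) + 1L]] <- list(attach = c_at, detach = oh)
  }
  sites
}

match_phenol_oh <- function(mol) {
  deg <- atom_degree(mol)
  sites <- list()
  for (o in which(mol$atoms$element == "O" & mol$atoms$charge == 0 & deg == 1)) {
    nb <- neighbors_of(mol, o)
    b <- mol$bonds
    ord <- b$order[(b$i == o & b$j == nb[1]) | (b$j == o & b$i == nb[1])]
    if (ord == 1L && mol$atoms$aromatic[nb[1]] && mol$atoms$element[nb[1]] == "C")
      # ether port: the phenolic oxygen keeps its place and bonds on
      sites[[length(sites) + 1L]] <- list(attach = o, detach = integer(0))
  }
  sites
}

#' The packaged connection-port library
#'
#' @return Named list of [port_spec()]s: `methoxy` (aryl-OCH3 replaced
#'   at the ring carbon), `aromatic_ch` (unsubstituted aromatic carbon),
#'   `carboxyl` (acyl position, hydroxyl leaves), `phenol_oh` (phenolic
#'   oxygen becomes an ether link).
#' @export
port_library <- function() {
  list(
    methoxy = port_spec("methoxy", "[cX3][OX2][CH3]", match_methoxy),
    aromatic_ch = port_spec("aromatic_ch", "[cH]", match_aromatic_ch),
    carboxyl = port_spec("carboxyl", "[CX3](=O)[OX2H1]", match_carboxyl),
    phenol_oh = port_spec("phenol_oh", "[c][OX2H1]", match_phenol_oh)
  )
}

#' Find connection ports on a molecule
#'
#' Returns one site per non-overlapping pattern match, ordered by
#' ascending attach-atom index. Overlapping matches are resolved
#' greedily by lowest atom index.
#'
#' @param mol A [molecule()].
#' @param spec A [port_spec()], or the name of a packaged port from
#'   [port_library()].
#' @return List of sites, each with `attach` (index), `detach` (integer
#'   vector) and `port` (name).
#' @examples
#' find_ports(mol_from_smiles("COc1ccccc1"), "methoxy")
#' @export
find_ports <- function(mol, spec) {
  if (is.character(spec)) {
    lib <- port_library()
    if (!spec %in% names(lib))
      stop_validation("unknown port '%s'; packaged ports: %s", spec,
                      paste(names(lib), collapse = ", "))
    spec <- lib[[spec]]
  }
  if (!inherits(spec, "port_spec")) stop_validation("`spec` must be a port_spec")
  sites <- spec$matcher(mol)
  if (!length(sites)) return(list())
  ord <- order(vapply(sites, `[[`, numeric(1), "attach"))
  sites <- sites[ord]
  # greedy non-overlap on (attach + detach) atom sets
  used <- integer(0)
  keep <- list()
  for (s in sites) {
    atoms <- c(s$attach, s$detach)
    if (!length(intersect(atoms, used))) {
      used <- c(used, atoms)
      s$port <- spec$name
      keep[[length(keep) + 1L]] <- s
    }
  }
  keep
}
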