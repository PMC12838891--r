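# Structural-alert screening: a small named SMARTS catalog matched by
# the chemistry backend's substructure search. The packaged catalog
# covers the alert classes the liability rules cite (Michael acceptors,
# quaternary nitrogens, stilbene linkages); further patterns load from a
# plain-text file.

#' The packaged structural-alert catalog
#'
#' @return Named character vector of SMARTS patterns:
#'   `michael_acceptor` (enone/enal conjugate acceptor),
#'   `quaternary_nitrogen`, `stilbene` (aryl-CH=CH-aryl linkage).
#' @export
alert_catalog <- function() {
  c(michael_acceptor = "[CX3]=[CX3][CX3]=[OX1]",
    quaternary_nitrogen = "[NX4+]",
    stilbene = "[c][CX3]=[CX3][c]")
}

#' Load an alert catalog from a pattern file
#'
#' Tab- or whitespace-separated lines `name pattern`; `#` comments
#' allowed. Each pattern is validated against a probe molecule at load
#' time so malformed SMARTS fail early.
#'
#' @param path Pattern file.
#' @return Named character vector of SMARTS patterns.
#' @export
read_alert_catalog <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines)) & !grepl("^#", lines)]
  parts <- strsplit(trimws(lines), "\\s+")
  bad <- vapply(parts, function(p) length(p) < 2L, logical(1))
  if (any(bad))
    stop_validation("malformed alert catalog line: %s", lines[which(bad)[1]])
  pats <- stats::setNames(vapply(parts, `[[`, character(1), 2L),
                          vapply(parts, `[[`, character(1), 1L))
  probe <- mol_from_smiles("CCO", "probe")
  for (nm in names(pats)) {
    ok <- tryCatch({ smarts_count(probe, pats[[nm]]); TRUE },
                   error = function(e) FALSE)
    if (!ok) stop_validation("alert pattern '%s' failed to compile: %s", nm, pats[[nm]])
  }
  pats
}

#' Match structural alerts on a molecule
#'
#' @param mol A [molecule()].
#' @param catalog Named character vector of SMARTS patterns (default the
#'   packaged catalog).
#' @return Character vector of alert names with at least one match.
#' @examples
#' structural_alerts(mol_from_smiles("C[N+](C)(C)C"))
#' @export
structural_alerts <- function(mol, catalog = alert_catalog()) {
  if (!length(catalog)) return(character(0))
  if (is.null(names(catalog))) stop_validation("alert catalog must be named")
  hits <- vapply(catalog, function(p) smarts_count(mol, p) > 0, logical(1))
  names(catalog)[hits]
}
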