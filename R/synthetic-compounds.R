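# Toy compound catalog with known structural alerts, and SMILES
# export, for exercising the alert and descriptor machinery without any
# external structure source.

#' Catalog of toy compounds with known structural alerts
#'
#' Small molecules chosen so that every packaged alert pattern has at
#' least one positive example, together with alert-free controls.
#'
#' @return data.frame: `name`, `smiles`, `expected_alerts`
#'   (semicolon-joined, empty for controls).
#' @examples
#' make_alert_compounds()
#' @export
make_alert_compounds <- function() {
  data.frame(
    name = c("tetramethylammonium", "trans_stilbene", "methyl_vinyl_ketone",
             "chalcone", "ethanol", "benzene", "anisole"),
    smiles = c("C[N+](C)(C)C",
               "c1ccc(/C=C/c2ccccc2)cc1",
               "CC(=O)C=C",
               "O=C(/C=C/c1ccccc1)c1ccccc1",
               "CCO",
               "c1ccccc1",
               "COc1ccccc1"),
    expected_alerts = c("quaternary_nitrogen",
                        "stilbene",
                        "michael_acceptor",
                        "michael_acceptor",
                        "", "", ""),
    stringsAsFactors = FALSE)
}

#' Write a compound table to a SMILES file
#'
#' One `SMILES<tab>name` pair per line, readable by
#' [read_smiles_file()].
#'
#' @param compounds data.frame with `smiles` and `name` columns.
#' @param path Output path.
#' @export
write_smiles_file <- function(compounds, path) {
  writeLines(paste(compounds$smiles, compounds$name, sep = "\t"), path)
  invisible(path)
}

#' Write the packaged docking fixture to CSV
#'
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_table1_csv <- function(path) {
  file.copy(system.file("extdata", "table1_docking.csv", package = "comolead"),
            path, overwrite = TRUE)
  invisible(path)
}
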