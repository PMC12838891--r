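# Docking-score table analytics: ingestion of (compound, target, Vina
# score, pocket volume) tables and the comparative arithmetic built on
# them. Docking itself is never run here.

# RT in kcal/mol at 298.15 K (R = 1.98720425e-3 kcal/(mol K))
RT_KCAL <- 0.5925

#' The packaged compound-generation map
#'
#' Maps compound codes to their development generation: natural
#' alkaloids and the circadian reference (natural), established kinase
#' inhibitors (reference), initial hybrids (second_gen), ADME-optimized
#' leads (third_gen).
#'
#' @return Named character vector code -> generation.
#' @export
generation_map <- function() {
  c(GLA = "natural", LIC = "natural", LID = "natural", MLT = "natural",
    IC261 = "reference", PF670462 = "reference",
    ICLID = "second_gen", PFLID = "second_gen",
    ICL = "third_gen", PFL = "third_gen")
}

normalize_target <- function(x) {
  up <- toupper(trimws(x))
  out <- ifelse(up %in% c("CK1D", "CK1DELTA", "3UYS", "CSNK1D"), "CK1D",
         ifelse(up %in% c("PINK1", "5OAT"), "PINK1", NA_character_))
  out
}

#' Load a docking-score table
#'
#' CSV with header `compound,target,vina_kcal_mol,volume_A3`. Target
#' codes may be kinase names (`CK1D`, `PINK1`) or the PDB ids `3UYS` /
#' `5OAT`. The compound generation is inferred from
#' [generation_map()], overridable per compound. Rows with unknown
#' targets or non-numeric scores raise errors naming the line; rows
#' with non-negative scores are kept but flagged (`favorable = FALSE`).
#'
#' @param path CSV path.
#' @param generations Optional named character vector overriding the
#'   packaged generation map.
#' @return data.frame of docking records: `compound`, `generation`,
#'   `target`, `vina_score`, `pocket_volume`, `favorable`.
#' @export
load_table <- function(path, generations = NULL) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("compound", "target", "vina_kcal_mol", "volume_A3")
  if (!all(need %in% names(df)))
    stop_validation("docking table needs columns %s", paste(need, collapse = ", "))
  if (nrow(df) == 0L) stop_validation("docking table is empty")

  tgt <- normalize_target(df$target)
  if (anyNA(tgt))
    stop_validation("unknown target code '%s' at line %d",
                    df$target[which(is.na(tgt))[1]], which(is.na(tgt))[1] + 1L)
  score <- suppressWarnings(as.numeric(df$vina_kcal_mol))
  if (anyNA(score))
    stop_validation("non-numeric Vina score at line %d", which(is.na(score))[1] + 1L)
  vol <- suppressWarnings(as.numeric(df$volume_A3))
  if (any(is.na(vol) | vol <= 0))
    stop_validation("pocket volume must be a positive number (line %d)",
                    which(is.na(vol) | vol <= 0)[1] + 1L)

  gmap <- generation_map()
  if (!is.null(generations)) gmap[names(generations)] <- generations
  gen <- unname(gmap[df$compound])
  gen[is.na(gen)] <- "natural"  # unknown codes default conservatively

  if (any(score >= 0))
    warning(sprintf("%d record(s) have non-favorable (>= 0) Vina scores",
                    sum(score >= 0)))
  data.frame(compound = df$compound, generation = gen, target = tgt,
             vina_score = score, pocket_volume = vol,
             favorable = score < 0, stringsAsFactors = FALSE)
}

#' The packaged docking-score fixture
#'
#' The 20-row docking table of natural alkaloids, reference inhibitors
#' and designed hybrids against CK1D (3UYS) and PINK1 (5OAT).
#'
#' @return data.frame of docking records (see [load_table()]).
#' @export
table1_fixture <- function() {
  load_table(system.file("extdata", "table1_docking.csv", package = "comolead"))
}

#' Best binder for a target
#'
#' The record with the most negative Vina score among records for the
#' target, optionally restricted to a generation subset. Ties break
#' lexicographically on compound code; the result does not depend on
#' row order.
#'
#' @param records Docking records from [load_table()].
#' @param target `"CK1D"` or `"PINK1"` (PDB ids accepted).
#' @param subset Generation filter (character vector of generations) or
#'   `"all"`.
#' @return Single-row data.frame.
#' @examples
#' best_binder(table1_fixture(), "CK1D", subset = "natural")
#' @export
best_binder <- function(records, target, subset = "all") {
  target <- normalize_target(target)
  sel <- records[records$target == target, , drop = FALSE]
  if (!identical(subset, "all"))
    sel <- sel[sel$generation %in% subset, , drop = FALSE]
  if (nrow(sel) == 0L)
    stop_validation("no records for target %s under the requested subset", target)
  sel <- sel[order(sel$vina_score, sel$compound), , drop = FALSE]
  sel[1, , drop = FALSE]
}

#' Binding-energy improvement of a compound over a reference
#'
#' `delta = vina(reference) - vina(compound)` in kcal/mol; positive
#' values mean the compound binds more strongly. The implied
#' fold-change in inhibition constant is `exp(|delta| / RT)` with
#' RT = 0.5925 kcal/mol (298.15 K). `delta_reported` rounds to one
#' decimal for presentation; arithmetic stays unrounded.
#'
#' @param records Docking records.
#' @param compound,reference Compound codes.
#' @param target Target code.
#' @return List: `compound`, `reference`, `target`, `delta`,
#'   `delta_reported`, `fold_ki_estimate`.
#' @examples
#' improvement(table1_fixture(), "ICLID", "IC261", "PINK1")$delta  # 3.0
#' @export
improvement <- function(records, compound, reference, target) {
  target <- normalize_target(target)
  get_score <- function(code) {
    r <- records[records$compound == code & records$target == target, , drop = FALSE]
    if (nrow(r) == 0L)
      stop_validation("no record for %s on %s", code, target)
    r$vina_score[1]
  }
  delta <- get_score(reference) - get_score(compound)
  list(compound = compound, reference = reference, target = target,
       delta = delta,
       delta_reported = round(delta, 1),
       fold_ki_estimate = exp(abs(delta) / RT_KCAL))
}

#' Dual-target binding summary
#'
#' One row per compound with both target scores and the worse (less
#' negative) of the two; ranking by that worse-of-two score ascending
#' identifies the best balanced dual binder. Compounds lacking a record
#' for either target are flagged and excluded from the ranking.
#'
#' @param records Docking records.
#' @return data.frame: `compound`, `generation`, `ck1d`, `pink1`,
#'   `worse_of_two`, `dual` (logical), sorted with ranked dual binders
#'   first. Ties break lexicographically on compound code.
#' @examples
#' head(dual_summary(table1_fixture()), 3)
#' @export
dual_summary <- function(records) {
  comps <- sort(unique(records$compound))
  rows <- lapply(comps, function(cc) {
    sub <- records[records$compound == cc, , drop = FALSE]
    ck <- sub$vina_score[sub$target == "CK1D"][1]
    pk <- sub$vina_score[sub$target == "PINK1"][1]
    data.frame(compound = cc, generation = sub$generation[1],
               ck1d = ck, pink1 = pk,
               worse_of_two = if (is.na(ck) || is.na(pk)) NA_real_ else max(ck, pk),
               dual = !is.na(ck) && !is.na(pk),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(!out$dual, out$worse_of_two, out$compound), , drop = FALSE]
  rownames(out) <- NULL
  out
}
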