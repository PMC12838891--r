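# ADME profile assembly and the liability classifier.

#' Assemble an ADME profile
#'
#' An `adme_profile` bundles everything the liability classifier and
#' the lead-selection scores consume: a descriptor record, rule-filter
#' outcomes (computed, or literature-reported violation counts),
#' solubility, bioavailability score, structural alerts, and
#' fixture-supplied pharmacokinetic flags (CYP inhibition, GI
#' absorption) which come from trained external predictors and are not
#' recomputed here.
#'
#' @param compound Compound identifier.
#' @param descriptors A [descriptor_set()].
#' @param rules Optional list from [rule_filters()]; computed from
#'   `descriptors` when omitted and computable.
#' @param rule_violation_counts Optional named integer vector (e.g.
#'   `c(Lipinski = 2, Ghose = 4, Muegge = 3)`) for literature records;
#'   used for the drug-likeness-failure liability when full rule
#'   evaluation is not possible.
#' @param log_s Log S (ESOL scale); computed via [esol_logs()] when
#'   omitted and computable.
#' @param ba_score Bioavailability score; computed via
#'   [bioavailability_score()] when omitted.
#' @param alerts Character vector of structural-alert names.
#' @param cyp_flags Named logical vector of CYP-inhibition flags.
#' @param gi_absorption `"high"`, `"low"`, or `NA`.
#' @param sa_score Synthetic-accessibility score (fixture input to lead
#'   selection).
#' @return An `adme_profile`.
#' @export
adme_profile <- function(compound, descriptors,
                         rules = NULL, rule_violation_counts = NULL,
                         log_s = NULL, ba_score = NULL,
                         alerts = character(0), cyp_flags = NULL,
                         gi_absorption = NA_character_, sa_score = NA_real_) {
  if (!inherits(descriptors, "descriptor_set"))
    stop_validation("`descriptors` must be a descriptor_set")
  if (is.null(rules) && is.null(rule_violation_counts)) {
    # literature records carry reported counts instead; evaluating the
    # full battery on partial descriptors would understate violations
    rules <- tryCatch(rule_filters(descriptors), error = function(e) NULL)
  }
  if (is.null(log_s)) {
    log_s <- tryCatch(esol_logs(descriptors), error = function(e) NA_real_)
  }
  if (is.null(ba_score)) {
    lp <- if (!is.null(rule_violation_counts) && "Lipinski" %in% names(rule_violation_counts))
      rule_violation_counts[["Lipinski"]] <= 1 else NULL
    ba_score <- bioavailability_score(descriptors, lipinski_pass = lp)
  }
  if (!is.na(gi_absorption) && !gi_absorption %in% c("high", "low"))
    stop_validation("gi_absorption must be 'high', 'low' or NA")
  structure(list(
    compound = as.character(compound),
    descriptors = descriptors,
    rules = rules,
    rule_violation_counts = rule_violation_counts,
    log_s = log_s,
    solubility_class = solubility_class(log_s),
    ba_score = ba_score,
    alerts = alerts,
    cyp_flags = cyp_flags,
    gi_absorption = gi_absorption,
    sa_score = sa_score),
    class = "adme_profile")
}

#' Profile a molecule end to end
#'
#' Computes descriptors, rule filters, ESOL solubility, the
#' bioavailability score and structural alerts from a structure.
#'
#' @param mol A [molecule()].
#' @param catalog Alert catalog (default packaged).
#' @return An [adme_profile()].
#' @export
profile_molecule <- function(mol, catalog = alert_catalog()) {
  d <- compute_descriptors(mol)
  adme_profile(compound = if (nzchar(mol$name)) mol$name else canonical_smiles(mol),
               descriptors = d,
               alerts = structural_alerts(mol, catalog))
}

#' @export
print.adme_profile <- function(x, ...) {
  cat(sprintf("<adme_profile> %s: MW %.2f, cLogP %.2f, LogS %.2f (%s), BA %.2f\n",
              x$compound, x$descriptors$mw, x$descriptors$logp_consensus,
              x$log_s, x$solubility_class, x$ba_score))
  if (length(x$alerts)) cat("  alerts:", paste(x$alerts, collapse = ", "), "\n")
  invisible(x)
}

# number of failed drug-likeness rules, from full results when present,
# falling back to reported violation counts
count_failed_rules <- function(p) {
  if (!is.null(p$rules)) {
    return(sum(!vapply(p$rules, `[[`, logical(1), "pass")))
  }
  if (!is.null(p$rule_violation_counts)) {
    cnt <- p$rule_violation_counts
    failed <- 0L
    for (rn in names(cnt)) {
      lim <- if (rn == "Lipinski") 1L else 0L
      if (!is.na(cnt[[rn]]) && cnt[[rn]] > lim) failed <- failed + 1L
    }
    return(failed)
  }
  NA_integer_
}

#' The liability rule set
#'
#' Declarative bounds for [identify_liabilities()]: consensus log P
#' above 4.5 or any single estimator above 6.0 (lipophilicity); Log S
#' below -7 (solubility deficit); molecular weight above 500 (or 600)
#' Da; bioavailability score below 0.3 or low GI absorption; any
#' structural alert; and failure of two or more drug-likeness rules.
#'
#' @return Named list of bound values.
#' @export
liability_bounds <- function() {
  list(logp_consensus_max = 4.5, logp_single_max = 6.0,
       log_s_min = -7, mw_soft = 500, mw_hard = 600,
       ba_min = 0.3, max_failed_rules = 1L)
}

#' Classify ADME liabilities of a profile
#'
#' Checks every liability rule and returns the fired categories ranked
#' by severity. The default severity order (most severe first) is
#' bioavailability, solubility, lipophilicity, structural alerts,
#' molecular weight, drug-likeness failures; pass `severity_order` to
#' reconfigure.
#'
#' @param p An [adme_profile()].
#' @param bounds Bound set from [liability_bounds()].
#' @param severity_order Character vector ordering the six categories.
#' @return A `liability_report`: data.frame with columns `category`,
#'   `value`, `bound`, `severity` (1 = most severe), ordered by
#'   severity. Zero rows when the profile is fully compliant.
#' @export
identify_liabilities <- function(p, bounds = liability_bounds(),
                                 severity_order = c("bioavailability",
                                                    "solubility",
                                                    "lipophilicity",
                                                    "structural_alert",
                                                    "molecular_weight",
                                                    "druglikeness_failure")) {
  if (!inherits(p, "adme_profile")) stop_validation("`p` must be an adme_profile")
  d <- p$descriptors
  rows <- list()
  add <- function(category, value, bound)
    rows[[length(rows) + 1L]] <<- data.frame(category = category,
                                             value = as.character(value),
                                             bound = as.character(bound),
                                             stringsAsFactors = FALSE)

  if (!is.na(d$logp_consensus) && d$logp_consensus > bounds$logp_consensus_max)
    add("lipophilicity", d$logp_consensus,
        sprintf("consensus logP > %.1f", bounds$logp_consensus_max))
  else if (length(d$logp_all) && any(d$logp_all > bounds$logp_single_max, na.rm = TRUE))
    add("lipophilicity", max(d$logp_all, na.rm = TRUE),
        sprintf("single-method logP > %.1f", bounds$logp_single_max))

  if (!is.na(p$log_s) && p$log_s < bounds$log_s_min)
    add("solubility", p$log_s, sprintf("Log S < %.0f", bounds$log_s_min))

  if (!is.na(d$mw)) {
    if (d$mw > bounds$mw_hard)
      add("molecular_weight", d$mw, sprintf("MW > %.0f Da", bounds$mw_hard))
    else if (d$mw > bounds$mw_soft)
      add("molecular_weight", d$mw, sprintf("MW > %.0f Da", bounds$mw_soft))
  }

  if ((!is.na(p$ba_score) && p$ba_score < bounds$ba_min))
    add("bioavailability", p$ba_score, sprintf("score < %.1f", bounds$ba_min))
  else if (identical(p$gi_absorption, "low"))
    add("bioavailability", "low GI absorption", "predicted GI absorption low")

  if (length(p$alerts))
    add("structural_alert", paste(p$alerts, collapse = ";"), "no structural alerts")

  nf <- count_failed_rules(p)
  if (!is.na(nf) && nf > bounds$max_failed_rules)
    add("druglikeness_failure", nf,
        sprintf("> %d failed drug-likeness rules", bounds$max_failed_rules))

  if (!length(rows)) {
    out <- data.frame(category = character(0), value = character(0),
                      bound = character(0), severity = integer(0))
  } else {
    out <- do.call(rbind, rows)
    out$severity <- match(out$category, severity_order)
    out <- out[order(out$severity), , drop = FALSE]
    rownames(out) <- NULL
  }
  class(out) <- c("liability_report", class(out))
  out
}

#' Read literature ADME profiles from the packaged fixture format
#'
#' CSV columns: `compound`, `mw`, `logp_consensus`, `logp_max_method`,
#' `log_s`, `ba_score`, `hbd`, `hba`, `tpsa`, `ionization`,
#' `lipinski_violations`, `ghose_violations`, `muegge_violations`,
#' `alerts` (semicolon-joined), `gi_absorption`, `sa_score`,
#' `provenance`. Missing numbers may be empty.
#'
#' @param path CSV path; defaults to the packaged profile fixture.
#' @return Named list of [adme_profile()]s.
#' @export
read_adme_fixture <- function(path = system.file("extdata", "adme_profiles.csv",
                                                 package = "comolead")) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  out <- lapply(seq_len(nrow(df)), function(k) {
    r <- df[k, ]
    num <- function(x) if (is.na(x) || x == "") NA_real_ else as.numeric(x)
    d <- descriptor_set(
      mw = num(r$mw),
      hbd = num(r$hbd), hba = num(r$hba), tpsa = num(r$tpsa),
      logp_consensus = num(r$logp_consensus),
      logp_all = stats::na.omit(c(num(r$logp_consensus), num(r$logp_max_method))),
      ionization_class = if (is.na(r$ionization) || r$ionization == "") "neutral"
                         else r$ionization)
    counts <- c(Lipinski = num(r$lipinski_violations),
                Ghose = num(r$ghose_violations),
                Muegge = num(r$muegge_violations))
    counts <- counts[!is.na(counts)]
    alerts <- if (is.na(r$alerts) || r$alerts == "") character(0)
              else strsplit(r$alerts, ";", fixed = TRUE)[[1]]
    adme_profile(
      compound = r$compound, descriptors = d,
      rules = NULL, rule_violation_counts = if (length(counts)) counts else NULL,
      log_s = num(r$log_s), ba_score = num(r$ba_score),
      alerts = alerts,
      gi_absorption = if (is.na(r$gi_absorption) || r$gi_absorption == "")
        NA_character_ else r$gi_absorption,
      sa_score = num(r$sa_score))
  })
  stats::setNames(out, df$compound)
}
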