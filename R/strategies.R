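# Optimization-strategy target checks: each named strategy carries a
# declarative set of target outcomes checkable on an ADME profile.

#' The packaged variant-strategy definitions
#'
#' Three parallel optimization strategies with their declared target
#' outcomes: `aggressive` (Lipinski compliant, bioavailability above
#' 0.50, zero structural alerts), `moderate` (at most one Lipinski
#' violation, bioavailability between 0.40 and 0.55), and `polarity`
#' (Log S above -6, three to five H-bond donors, TPSA 110-130).
#'
#' @return Named list of `variant_strategy` objects, each with `name`
#'   and a named list of predicate `targets`.
#' @export
variant_strategies <- function() {
  lip_viol <- function(p) {
    if (!is.null(p$rules)) p$rules$Lipinski$n_violations
    else if (!is.null(p$rule_violation_counts) &&
             "Lipinski" %in% names(p$rule_violation_counts))
      p$rule_violation_counts[["Lipinski"]]
    else NA_integer_
  }
  strat <- function(name, targets)
    structure(list(name = name, targets = targets), class = "variant_strategy")
  list(
    aggressive = strat("aggressive", list(
      lipinski_compliant = function(p) isTRUE(lip_viol(p) == 0L),
      ba_above_0.50 = function(p) !is.na(p$ba_score) && p$ba_score > 0.50,
      zero_alerts = function(p) length(p$alerts) == 0L)),
    moderate = strat("moderate", list(
      lipinski_at_most_1 = function(p) isTRUE(lip_viol(p) <= 1L),
      ba_0.40_to_0.55 = function(p)
        !is.na(p$ba_score) && p$ba_score >= 0.40 && p$ba_score <= 0.55)),
    polarity = strat("polarity", list(
      logs_above_minus6 = function(p) !is.na(p$log_s) && p$log_s > -6,
      hbd_3_to_5 = function(p) {
        h <- p$descriptors$hbd
        !is.na(h) && h >= 3 && h <= 5
      },
      tpsa_110_to_130 = function(p) {
        t <- p$descriptors$tpsa
        !is.na(t) && t >= 110 && t <= 130
      }))
  )
}

#' Check a profile against a strategy's target outcomes
#'
#' @param p An [adme_profile()].
#' @param strategy A `variant_strategy` or the name of a packaged one.
#' @return List: `strategy`, `met` (named logical per target),
#'   `all_met`.
#' @export
check_strategy_targets <- function(p, strategy) {
  if (is.character(strategy)) {
    lib <- variant_strategies()
    if (!strategy %in% names(lib))
      stop_validation("unknown strategy '%s'", strategy)
    strategy <- lib[[strategy]]
  }
  met <- vapply(strategy$targets, function(f) isTRUE(f(p)), logical(1))
  list(strategy = strategy$name, met = met, all_met = all(met))
}
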