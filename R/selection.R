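# Variant assessment and lead selection: retention banding of binding
# changes, ADME improvement deltas, strategy target checks, and the
# weighted composite score that designates the lead.

#' Binding-retention policy
#'
#' Thresholds for banding a binding-energy change between a variant and
#' its parent: retained at <= 1.0 kcal/mol, moderately reduced between
#' 1.0 and 2.0, substantially reduced above 2.0. `rt` converts energy
#' changes into implied Ki fold-changes.
#'
#' @param retained_max,moderate_max Band edges in kcal/mol.
#' @param rt RT in kcal/mol (default 0.5925, 298.15 K).
#' @return A `retention_policy`.
#' @export
retention_policy <- function(retained_max = 1.0, moderate_max = 2.0,
                             rt = RT_KCAL) {
  if (!(retained_max > 0 && moderate_max > retained_max))
    stop_validation("need 0 < retained_max < moderate_max")
  structure(list(retained_max = retained_max, moderate_max = moderate_max,
                 rt = rt), class = "retention_policy")
}

#' Classify binding retention of a variant
#'
#' `delta_dg` is variant score minus parent score (positive = weaker
#' binding). The implied Ki fold-change is `exp(max(delta, 0) / RT)`;
#' improvements (negative delta) class as retained with
#' `ki_fold = exp(delta / RT) < 1`.
#'
#' @param delta_dg Binding-energy change, kcal/mol.
#' @param policy A [retention_policy()].
#' @return List: `band` in `{retained, moderately_reduced,
#'   substantially_reduced}`, `ki_fold`, `delta_dg`.
#' @examples
#' classify_retention(1.3)$band  # moderately_reduced
#' @export
classify_retention <- function(delta_dg, policy = retention_policy()) {
  delta_dg <- assert_number(delta_dg, "delta_dg")
  band <- if (delta_dg <= policy$retained_max) "retained"
          else if (delta_dg <= policy$moderate_max) "moderately_reduced"
          else "substantially_reduced"
  list(band = band,
       ki_fold = exp(delta_dg / policy$rt),
       delta_dg = delta_dg)
}

#' ADME improvement deltas between parent and variant profiles
#'
#' Signed so that positive values are improvements: lipophilicity drop
#' `parent logP - variant logP`, solubility gain `variant LogS -
#' parent LogS`, weight loss `parent MW - variant MW`, bioavailability
#' ratio `variant BA / parent BA`, and the reduction in total
#' drug-likeness rule violations.
#'
#' @param parent,variant [adme_profile()]s.
#' @return An `adme_deltas` list: `d_logp`, `d_logs`, `d_mw`,
#'   `ba_ratio`, `violation_reduction`, plus `parent_logp` and
#'   `variant_lipinski_pass` carried along for the success criteria.
#' @export
adme_deltas <- function(parent, variant) {
  for (p in list(parent, variant))
    if (!inherits(p, "adme_profile")) stop_validation("profiles must be adme_profile")
  if (is.na(parent$ba_score) || parent$ba_score == 0)
    stop_validation("parent bioavailability score is zero or missing")

  total_viol <- function(p) {
    if (!is.null(p$rules))
      sum(vapply(p$rules, `[[`, integer(1), "n_violations"))
    else if (!is.null(p$rule_violation_counts))
      sum(p$rule_violation_counts, na.rm = TRUE)
    else NA_integer_
  }
  lip_pass <- function(p) {
    if (!is.null(p$rules)) p$rules$Lipinski$pass
    else if (!is.null(p$rule_violation_counts) &&
             "Lipinski" %in% names(p$rule_violation_counts))
      p$rule_violation_counts[["Lipinski"]] <= 1
    else NA
  }

  structure(list(
    d_logp = parent$descriptors$logp_consensus - variant$descriptors$logp_consensus,
    d_logs = variant$log_s - parent$log_s,
    d_mw = parent$descriptors$mw - variant$descriptors$mw,
    ba_ratio = variant$ba_score / parent$ba_score,
    violation_reduction = total_viol(parent) - total_viol(variant),
    parent_logp = parent$descriptors$logp_consensus,
    variant_lipinski_pass = lip_pass(variant)),
    class = "adme_deltas")
}

#' Check whether a variant meets a prioritization criterion
#'
#' A variant succeeds when any of the following fires: a relative
#' consensus log P improvement of 30% or more, a solubility gain of at
#' least one log unit (inclusive), achievement of Lipinski compliance,
#' or a two-fold or greater bioavailability improvement.
#'
#' @param deltas [adme_deltas()] versus the stated parent.
#' @param variant The variant [adme_profile()] (used for the Lipinski
#'   clause when the deltas carry no verdict).
#' @return List: `success` (logical), `fired` (character vector of
#'   criteria among `logp_relative`, `logs_gain`, `lipinski`,
#'   `ba_fold`).
#' @export
variant_success <- function(deltas, variant = NULL) {
  if (!inherits(deltas, "adme_deltas")) stop_validation("`deltas` must be adme_deltas")
  fired <- character(0)
  if (!is.na(deltas$d_logp) && !is.na(deltas$parent_logp) &&
      deltas$parent_logp != 0 &&
      deltas$d_logp / deltas$parent_logp >= 0.30)
    fired <- c(fired, "logp_relative")
  if (!is.na(deltas$d_logs) && deltas$d_logs >= 1.0)
    fired <- c(fired, "logs_gain")
  lp <- deltas$variant_lipinski_pass
  if (is.na(lp) && !is.null(variant) && !is.null(variant$rules))
    lp <- variant$rules$Lipinski$pass
  if (isTRUE(lp)) fired <- c(fired, "lipinski")
  if (!is.na(deltas$ba_ratio) && deltas$ba_ratio >= 2.0)
    fired <- c(fired, "ba_fold")
  list(success = length(fired) > 0L, fired = fired)
}

#' Lead designation of a variant
#'
#' A variant is designated a successful lead when binding is retained
#' on both targets and the 30%-or-greater ADME improvement condition
#' holds (by default the relative consensus log P criterion, the one
#' stated as a percentage; an alternative metric function may be
#' configured).
#'
#' @param retention_ck1d,retention_pink1 Results of
#'   [classify_retention()] for the two targets.
#' @param deltas [adme_deltas()] versus the parent.
#' @param improvement_metric Function `(deltas) -> logical` implementing
#'   the 30% condition.
#' @return Logical.
#' @export
lead_designation <- function(retention_ck1d, retention_pink1, deltas,
                             improvement_metric = NULL) {
  if (is.null(improvement_metric)) {
    improvement_metric <- function(d) {
      !is.na(d$d_logp) && !is.na(d$parent_logp) && d$parent_logp != 0 &&
        d$d_logp / d$parent_logp >= 0.30
    }
  }
  identical(retention_ck1d$band, "retained") &&
    identical(retention_pink1$band, "retained") &&
    isTRUE(improvement_metric(deltas))
}

#' Composite lead-score weights
#'
#' ADME quality 40%, binding retention 40%, synthetic accessibility
#' 10%, strategic balance 10%; weights must sum to one.
#'
#' @param w_adme,w_binding,w_synth,w_balance Weights.
#' @return A `lead_score_weights`.
#' @export
lead_score_weights <- function(w_adme = 0.40, w_binding = 0.40,
                               w_synth = 0.10, w_balance = 0.10) {
  w <- c(adme = w_adme, binding = w_binding, synth = w_synth,
         balance = w_balance)
  if (abs(sum(w) - 1) > 1e-9)
    stop_validation("lead-score weights must sum to 1 (got %.4f)", sum(w))
  structure(as.list(w), class = "lead_score_weights")
}

#' Weighted composite lead score
#'
#' Linear combination of four sub-scores in `[0, 1]`.
#'
#' @param adme_sub,binding_sub,synth_sub,balance_sub Sub-scores in
#'   `[0, 1]`.
#' @param w A [lead_score_weights()].
#' @return Score in `[0, 1]`.
#' @export
composite_lead_score <- function(adme_sub, binding_sub, synth_sub, balance_sub,
                                 w = lead_score_weights()) {
  if (!inherits(w, "lead_score_weights"))
    stop_validation("`w` must be lead_score_weights")
  for (s in c(adme_sub, binding_sub, synth_sub, balance_sub))
    if (is.na(s) || s < 0 || s > 1) stop_validation("sub-scores must lie in [0, 1]")
  w$adme * adme_sub + w$binding * binding_sub + w$synth * synth_sub +
    w$balance * balance_sub
}

# ---- packaged sub-score constructions --------------------------------------

solubility_band_index <- function(band) {
  idx <- c(insoluble = 0, poorly_soluble = 0.25, moderately_soluble = 0.5,
           soluble = 0.75, highly_soluble = 1)
  unname(idx[band])
}

#' ADME sub-score of a profile
#'
#' Mean of four `[0, 1]` components: Lipinski pass indicator,
#' bioavailability relative to the 0.55 compliant class (capped at 1),
#' the solubility band rescaled (insoluble 0 ... highly soluble 1), and
#' an alert-free indicator.
#'
#' @param p An [adme_profile()].
#' @return Value in `[0, 1]`.
#' @export
adme_subscore <- function(p) {
  lp <- if (!is.null(p$rules)) p$rules$Lipinski$pass
        else if (!is.null(p$rule_violation_counts) &&
                 "Lipinski" %in% names(p$rule_violation_counts))
          p$rule_violation_counts[["Lipinski"]] <= 1
        else NA
  mean(c(as.numeric(isTRUE(lp)),
         min(p$ba_score / 0.55, 1),
         solubility_band_index(p$solubility_class),
         as.numeric(length(p$alerts) == 0L)))
}

#' Binding sub-score across both targets
#'
#' Mean over targets of `clamp(1 - max(delta, 0) / 2, 0, 1)`, so full
#' credit for retained or improved binding and zero credit at a
#' 2 kcal/mol loss.
#'
#' @param delta_ck1d,delta_pink1 Binding-energy changes (variant minus
#'   parent), kcal/mol.
#' @return Value in `[0, 1]`.
#' @export
binding_subscore <- function(delta_ck1d, delta_pink1) {
  clamp <- function(x) pmin(pmax(x, 0), 1)
  mean(clamp(1 - pmax(c(delta_ck1d, delta_pink1), 0) / 2.0))
}

#' Synthetic-accessibility sub-score
#'
#' 1 at scores of 4.5 or lower, decaying linearly to 0 at 10.
#'
#' @param sa_score Synthetic-accessibility score (1 easy ... 10 hard).
#' @return Value in `[0, 1]`.
#' @export
synth_subscore <- function(sa_score) {
  if (is.na(sa_score)) return(NA_real_)
  if (sa_score <= 4.5) 1 else max(0, 1 - (sa_score - 4.5) / (10 - 4.5))
}

#' Strategic-balance sub-score
#'
#' `1 - |adme_sub - binding_sub|`: rewards candidates whose ADME and
#' binding achievements are balanced rather than one-sided.
#'
#' @param adme_sub,binding_sub Sub-scores.
#' @return Value in `[0, 1]`.
#' @export
balance_subscore <- function(adme_sub, binding_sub) {
  1 - abs(adme_sub - binding_sub)
}

#' Score and rank lead candidates
#'
#' Convenience wrapper evaluating the packaged sub-score constructions
#' for each candidate and ranking by the weighted composite; ties break
#' lexicographically on compound code, and the winner is invariant to
#' candidate order.
#'
#' @param candidates Named list; each element a list with `profile`
#'   (an [adme_profile()]), `delta_ck1d`, `delta_pink1` (kcal/mol vs
#'   parent).
#' @param w A [lead_score_weights()].
#' @return data.frame ranked by score descending: `compound`,
#'   `adme_sub`, `binding_sub`, `synth_sub`, `balance_sub`, `score`.
#' @export
rank_leads <- function(candidates, w = lead_score_weights()) {
  if (is.null(names(candidates)) || !length(candidates))
    stop_validation("`candidates` must be a non-empty named list")
  rows <- lapply(names(candidates), function(nm) {
    cd <- candidates[[nm]]
    a <- adme_subscore(cd$profile)
    b <- binding_subscore(cd$delta_ck1d, cd$delta_pink1)
    s <- synth_subscore(cd$profile$sa_score)
    bal <- balance_subscore(a, b)
    data.frame(compound = nm, adme_sub = a, binding_sub = b,
               synth_sub = s, balance_sub = bal,
               score = composite_lead_score(a, b, s, bal, w),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(-out$score, out$compound), , drop = FALSE]
  rownames(out) <- NULL
  out
}
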