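# Drug-likeness rule battery, ESOL solubility and the Abbott
# bioavailability score. All bounds live in a declarative table so the
# filters are auditable and extensible.

# Each rule is a list of checks: descriptor field, direction, bound.
# Lipinski passes with <= 1 violation; the other four require 0.
druglikeness_rules <- function() {
  chk <- function(param, field, op, bound)
    list(param = param, field = field, op = op, bound = bound)
  list(
    Lipinski = list(
      max_violations = 1L,
      checks = list(
        chk("MW <= 500", "mw", "<=", 500),
        chk("logP <= 5", "logp_consensus", "<=", 5),
        chk("HBD <= 5", "hbd", "<=", 5),
        chk("HBA <= 10", "hba", "<=", 10))),
    Ghose = list(
      max_violations = 0L,
      checks = list(
        chk("MW >= 160", "mw", ">=", 160),
        chk("MW <= 480", "mw", "<=", 480),
        chk("WLOGP >= -0.4", "logp_wlogp", ">=", -0.4),
        chk("WLOGP <= 5.6", "logp_wlogp", "<=", 5.6),
        chk("MR >= 40", "molar_refractivity", ">=", 40),
        chk("MR <= 130", "molar_refractivity", "<=", 130),
        chk("atoms >= 20", "heavy_atoms", ">=", 20),
        chk("atoms <= 70", "heavy_atoms", "<=", 70))),
    Veber = list(
      max_violations = 0L,
      checks = list(
        chk("RB <= 10", "rotatable_bonds", "<=", 10),
        chk("TPSA <= 140", "tpsa", "<=", 140))),
    Egan = list(
      max_violations = 0L,
      checks = list(
        chk("WLOGP <= 5.88", "logp_wlogp", "<=", 5.88),
        chk("TPSA <= 131.6", "tpsa", "<=", 131.6))),
    Muegge = list(
      max_violations = 0L,
      checks = list(
        chk("MW >= 200", "mw", ">=", 200),
        chk("MW <= 600", "mw", "<=", 600),
        chk("logP >= -2", "logp_consensus", ">=", -2),
        chk("logP <= 5", "logp_consensus", "<=", 5),
        chk("TPSA <= 150", "tpsa", "<=", 150),
        chk("rings <= 7", "rings", "<=", 7),
        chk("carbons > 4", "carbons", ">", 4),
        chk("heteroatoms > 1", "heteroatoms", ">", 1),
        chk("RB <= 15", "rotatable_bonds", "<=", 15),
        chk("HBA <= 10", "hba", "<=", 10),
        chk("HBD <= 5", "hbd", "<=", 5)))
  )
}

apply_check <- function(d, check) {
  v <- d[[check$field]]
  if (is.null(v) || is.na(v)) return(NA)  # missing input: bound not assessable
  switch(check$op,
         "<=" = v <= check$bound,
         ">=" = v >= check$bound,
         "<" = v < check$bound,
         ">" = v > check$bound)
}

#' Evaluate the five drug-likeness filters
#'
#' Applies the Lipinski, Ghose, Veber, Egan and Muegge bound sets to a
#' descriptor record. Lipinski passes with at most one violation; the
#' other filters require none. Bounds whose input descriptor is missing
#' (`NA`) are skipped, so literature records with partial coverage can
#' still be screened on the parameters they report.
#'
#' @param d A [descriptor_set()].
#' @return List of `rule_result` objects, one per rule, each with
#'   `rule_name`, `violations` (data.frame `parameter`, `value`,
#'   `bound`), `n_violations`, `pass`.
#' @examples
#' d <- descriptor_set(mw = 629.73, logp_consensus = 5.23, hbd = 1, hba = 7)
#' rule_filters(d)$Lipinski$n_violations  # 2
#' @export
rule_filters <- function(d) {
  if (!inherits(d, "descriptor_set")) stop_validation("`d` must be a descriptor_set")
  rules <- druglikeness_rules()
  out <- lapply(names(rules), function(rn) {
    rule <- rules[[rn]]
    res <- lapply(rule$checks, function(ck) {
      ok <- apply_check(d, ck)
      if (isFALSE(ok))
        data.frame(parameter = ck$param, value = d[[ck$field]],
                   bound = ck$bound, stringsAsFactors = FALSE)
      else NULL
    })
    viol <- do.call(rbind, res)
    nv <- if (is.null(viol)) 0L else nrow(viol)
    structure(list(rule_name = rn,
                   violations = viol %||% data.frame(parameter = character(0),
                                                     value = numeric(0),
                                                     bound = numeric(0)),
                   n_violations = nv,
                   pass = nv <= rule$max_violations),
              class = "rule_result")
  })
  stats::setNames(out, names(rules))
}

#' @export
print.rule_result <- function(x, ...) {
  cat(sprintf("%s: %d violation(s) -> %s\n", x$rule_name, x$n_violations,
              if (x$pass) "pass" else "FAIL"))
  if (x$n_violations > 0)
    for (k in seq_len(nrow(x$violations)))
      cat(sprintf("  %s (value %.4g)\n", x$violations$parameter[k],
                  x$violations$value[k]))
  invisible(x)
}

#' ESOL aqueous solubility estimate
#'
#' The linear ESOL model:
#' `Log S = 0.16 - 0.63 logP - 0.0062 MW + 0.066 RB - 0.74 AP`,
#' with `AP` the aromatic proportion of heavy atoms. Coefficients are
#' arguments so variants can be dropped in.
#'
#' @param d A [descriptor_set()] with `logp_consensus`, `mw`,
#'   `rotatable_bonds` and `aromatic_proportion` available.
#' @param coef Named numeric vector `intercept`, `logp`, `mw`, `rb`,
#'   `ap`.
#' @return Estimated Log S (log mol/L).
#' @examples
#' esol_logs(descriptor_set(mw = 200, logp_consensus = 2,
#'                          rotatable_bonds = 2, aromatic_proportion = 0.5))
#' @export
esol_logs <- function(d, coef = c(intercept = 0.16, logp = -0.63,
                                  mw = -0.0062, rb = 0.066, ap = -0.74)) {
  needed <- c(d$logp_consensus, d$mw, d$rotatable_bonds, d$aromatic_proportion)
  if (any(is.na(needed)))
    stop_validation("esol_logs needs logP, MW, rotatable bonds and aromatic proportion")
  unname(coef["intercept"] + coef["logp"] * d$logp_consensus +
           coef["mw"] * d$mw + coef["rb"] * d$rotatable_bonds +
           coef["ap"] * d$aromatic_proportion)
}

#' Solubility class of a Log S value
#'
#' Bands: highly soluble (`> -2`), soluble (`(-4, -2]`), moderately
#' soluble (`(-6, -4]`), poorly soluble (`(-8, -6]`), insoluble
#' (`<= -8`). Boundaries belong to the less-soluble band; the only
#' strict inequalities in the published banding are the top (`> -2`)
#' and bottom (`< -8`) bands, and `-8` itself is classed insoluble.
#'
#' @param log_s Numeric Log S value(s).
#' @return Character vector of band labels.
#' @examples
#' solubility_class(c(-1, -5, -8.5))
#' @export
solubility_class <- function(log_s) {
  vapply(log_s, function(s) {
    if (is.na(s)) return(NA_character_)
    if (s > -2) "highly_soluble"
    else if (s > -4) "soluble"
    else if (s > -6) "moderately_soluble"
    else if (s > -8) "poorly_soluble"
    else "insoluble"
  }, character(1))
}

#' Abbott bioavailability score
#'
#' Rule-based probability class for >10% oral bioavailability.
#' Anions are scored by polar surface area bands (TPSA <= 75: 0.85;
#' 75-150: 0.56; > 150: 0.11); all other ionization classes score 0.55
#' when Rule-of-Five compliant (at most one Lipinski violation) and
#' 0.17 otherwise.
#'
#' @param d A [descriptor_set()] with `ionization_class` and, for
#'   anions, `tpsa`; for the non-anion branch the Lipinski inputs.
#' @param lipinski_pass Optional logical overriding the internally
#'   evaluated Lipinski outcome (used with literature records that
#'   report the violation count directly).
#' @return One of 0.11, 0.17, 0.55, 0.56, 0.85.
#' @examples
#' bioavailability_score(descriptor_set(mw = 300, logp_consensus = 2,
#'                                      hbd = 1, hba = 3))  # 0.55
#' @export
bioavailability_score <- function(d, lipinski_pass = NULL) {
  if (!inherits(d, "descriptor_set")) stop_validation("`d` must be a descriptor_set")
  if (d$ionization_class == "anion") {
    if (is.na(d$tpsa)) stop_validation("anion scoring needs TPSA")
    if (d$tpsa > 150) return(0.11)
    if (d$tpsa > 75) return(0.56)
    return(0.85)
  }
  if (is.null(lipinski_pass))
    lipinski_pass <- rule_filters(d)$Lipinski$pass
  if (isTRUE(lipinski_pass)) 0.55 else 0.17
}
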