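test_that("retention banding follows the energy thresholds", {
  expect_equal(classify_retention(0.0)$band, "retained")
  expect_equal(classify_retention(0.0)$ki_fold, 1.0)
  expect_equal(classify_retention(1.3)$band, "moderately_reduced")
  expect_equal(classify_retention(2.5)$band, "substantially_reduced")
  # improvement (negative delta) stays retained with ki_fold < 1
  neg <- classify_retention(-1.0)
  expect_equal(neg$band, "retained")
  expect_lt(neg$ki_fold, 1)
})

test_that("retention is monotone and ki_fold strictly increasing", {
  deltas <- seq(-2, 4, length.out = 1e4)
  bands <- vapply(deltas, function(d) classify_retention(d)$band, character(1))
  ranks <- match(bands, c("retained", "moderately_reduced",
                          "substantially_reduced"))
  expect_true(all(diff(ranks) >= 0))
  folds <- vapply(deltas, function(d) classify_retention(d)$ki_fold, numeric(1))
  expect_true(all(diff(folds) > 0))
})

test_that("ADME deltas are signed toward improvement", {
  profs <- read_adme_fixture()
  dd <- adme_deltas(profs$PFLID, profs$PFL)
  expect_equal(dd$d_logp, 5.23 - 4.0, tolerance = 1e-9)
  expect_equal(dd$d_mw, 629.73 - 520, tolerance = 1e-9)
  expect_gte(dd$ba_ratio, 3.0)
  expect_gt(dd$d_logs, 0)

  # identical profiles: all zeros, ratio one
  same <- adme_deltas(profs$ICLID, profs$ICLID)
  expect_equal(same$d_logp, 0)
  expect_equal(same$d_logs, 0)
  expect_equal(same$d_mw, 0)
  expect_equal(same$ba_ratio, 1)
  expect_equal(same$violation_reduction, 0)

  zero_ba <- adme_profile("z", descriptor_set(mw = 300, logp_consensus = 1,
                                              hbd = 1, hba = 2),
                          ba_score = 0)
  expect_error(adme_deltas(zero_ba, profs$PFL), "zero or missing")
})

test_that("variant success fires the documented criteria", {
  profs <- read_adme_fixture()
  vs <- variant_success(adme_deltas(profs$PFLID, profs$PFL))
  expect_true(vs$success)
  expect_true("ba_fold" %in% vs$fired)  # the bioavailability criterion

  # no change at all, Lipinski-failing variant: no criterion fires
  fail_d <- descriptor_set(mw = 700, logp_consensus = 6, hbd = 6, hba = 11)
  fail_p <- adme_profile("f", fail_d, log_s = -9)
  none <- variant_success(adme_deltas(fail_p, fail_p))
  expect_false(none$success)

  # a solubility gain of exactly one log unit is inclusive
  better <- adme_profile("b", fail_d, log_s = -8)
  one_log <- variant_success(adme_deltas(fail_p, better))
  expect_true("logs_gain" %in% one_log$fired)

  # 30% relative logP improvement fires on its own
  lean_d <- descriptor_set(mw = 700, logp_consensus = 4, hbd = 6, hba = 11)
  lean_p <- adme_profile("l", lean_d, log_s = -9)
  rel <- variant_success(adme_deltas(fail_p, lean_p))
  expect_true("logp_relative" %in% rel$fired)  # (6-4)/6 = 0.33
})

test_that("lead designation requires dual retention plus the 30% metric", {
  profs <- read_adme_fixture()
  good <- adme_deltas(
    adme_profile("p", descriptor_set(mw = 600, logp_consensus = 6, hbd = 1,
                                     hba = 6), log_s = -8, ba_score = 0.17),
    adme_profile("v", descriptor_set(mw = 450, logp_consensus = 4, hbd = 2,
                                     hba = 5), log_s = -5, ba_score = 0.55))
  r_ok <- classify_retention(0.5)
  r_mid <- classify_retention(1.5)
  expect_true(lead_designation(r_ok, r_ok, good))    # (6-4)/6 >= 0.30
  expect_false(lead_designation(r_mid, r_ok, good))
  no_gain <- adme_deltas(profs$ICLID, profs$ICLID)
  expect_false(lead_designation(r_ok, r_ok, no_gain))
})

test_that("designation implies both bands retained over random inputs", {
  profs <- read_adme_fixture()
  strong <- adme_deltas(
    adme_profile("p6", descriptor_set(mw = 600, logp_consensus = 6, hbd = 1,
                                      hba = 6), log_s = -8, ba_score = 0.17),
    adme_profile("v4", descriptor_set(mw = 450, logp_consensus = 4, hbd = 2,
                                      hba = 5), log_s = -5, ba_score = 0.55))
  deltas_pool <- list(adme_deltas(profs$PFLID, profs$PFL),
                      adme_deltas(profs$ICLID, profs$ICL),
                      adme_deltas(profs$ICLID, profs$ICLID),
                      strong)
  set.seed(31)
  n_designated <- 0
  for (k in 1:400) {
    r1 <- classify_retention(runif(1, -1, 3))
    r2 <- classify_retention(runif(1, -1, 3))
    dd <- deltas_pool[[sample(4, 1)]]
    designated <- lead_designation(r1, r2, dd)
    if (designated) {
      n_designated <- n_designated + 1
      expect_equal(r1$band, "retained")
      expect_equal(r2$band, "retained")
    } else {
      expect_true(r1$band != "retained" || r2$band != "retained" ||
                    !isTRUE(dd$d_logp / dd$parent_logp >= 0.30))
    }
  }
  expect_gt(n_designated, 0)  # the implication was actually exercised
})

test_that("the composite score is the stated weighted sum", {
  expect_equal(composite_lead_score(1, 1, 1, 1), 1.0)
  expect_equal(composite_lead_score(1, 0, 1, 0), 0.5)  # 0.4 + 0.1
  expect_equal(composite_lead_score(0, 0, 0, 0), 0)
  # linearity in each sub-score
  base <- composite_lead_score(0.2, 0.4, 0.6, 0.8)
  up <- composite_lead_score(0.7, 0.4, 0.6, 0.8)
  expect_equal(up - base, 0.4 * 0.5)
  expect_error(lead_score_weights(0.5, 0.5, 0.5, 0.5), "sum to 1")
})

test_that("lead ranking selects the balanced dual binder and ignores order", {
  profs <- read_adme_fixture()
  t1 <- table1_fixture()
  cand <- list(
    ICL = list(profile = profs$ICL,
               delta_ck1d = improvement(t1, "ICL", "ICLID", "CK1D")$delta * -1,
               delta_pink1 = improvement(t1, "ICL", "ICLID", "PINK1")$delta * -1),
    PFL = list(profile = profs$PFL,
               delta_ck1d = improvement(t1, "PFL", "PFLID", "CK1D")$delta * -1,
               delta_pink1 = improvement(t1, "PFL", "PFLID", "PINK1")$delta * -1))
  ranked <- rank_leads(cand)
  expect_equal(ranked$compound[1], "PFL")
  ranked_rev <- rank_leads(rev(cand))
  expect_identical(ranked$compound, ranked_rev$compound)
  expect_equal(ranked$score, ranked_rev$score)
})

test_that("strategy target checks evaluate their declared predicates", {
  profs <- read_adme_fixture()
  agg_icl <- check_strategy_targets(profs$ICL, "aggressive")
  expect_true(agg_icl$met[["lipinski_compliant"]])
  expect_true(agg_icl$met[["ba_above_0.50"]])
  expect_true(agg_icl$met[["zero_alerts"]])
  expect_true(agg_icl$all_met)

  agg_pflid <- check_strategy_targets(profs$PFLID, "aggressive")
  expect_false(agg_pflid$all_met)

  mod_pfl <- check_strategy_targets(profs$PFL, "moderate")
  expect_true(mod_pfl$all_met)
  expect_error(check_strategy_targets(profs$PFL, "bogus"), "unknown strategy")
})
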