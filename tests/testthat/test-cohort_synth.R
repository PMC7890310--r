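test_that("molecular group mapping follows the five-group taxonomy exactly", {
  expect_equal(as.character(derive_molecular_group(1, 1, 1)),
               "Triple-positive")
  expect_equal(as.character(derive_molecular_group(0, 0, 0)),
               "Triple-negative")
  expect_equal(as.character(derive_molecular_group(1, 1, 0)), "TERT+IDH")
  expect_equal(as.character(derive_molecular_group(1, 0, 0)), "IDH-only")
  expect_equal(as.character(derive_molecular_group(0, 1, 0)), "TERT-only")
  # every remaining combination carries codeletion outside the taxonomy
  expect_equal(as.character(derive_molecular_group(1, 0, 1)), "Others")
  expect_equal(as.character(derive_molecular_group(0, 1, 1)), "Others")
  expect_equal(as.character(derive_molecular_group(0, 0, 1)), "Others")
  # total on {0,1}^3, vectorized
  g <- expand.grid(i = 0:1, t = 0:1, c = 0:1)
  expect_false(anyNA(derive_molecular_group(g$i, g$t, g$c)))
})

test_that("generated cohorts satisfy every structural invariant", {
  co <- small_cohort(n = 500, seed = 3)
  expect_s3_class(co, "cohort_table")
  expect_silent(validate_cohort(co))
  # marker consistency row by row
  yn <- function(col) co[[col]] == "Yes"
  expect_equal(as.character(derive_molecular_group(
    yn("idh"), yn("tert"), yn("codel_1p19q"))),
    as.character(co$mol_group))
  expect_true(all(co$os_months >= co$pfs_months))
  expect_true(all(co$pfs_months[co$pfs_event == 0] >= 36))
  expect_true(all((co$histology == "Glioblastoma") == (co$who_grade == "IV")))
})

test_that("seeded generation is deterministic and small cohorts are rejected", {
  a <- small_cohort(n = 120, seed = 9)
  b <- small_cohort(n = 120, seed = 9)
  expect_identical(a, b)
  expect_error(cohort_config(n_patients = 20), "n_patients")
  expect_error(cohort_config(censor_horizon_months = 24), "36")
  expect_error(cohort_config(baseline_hazard = -1), "negative")
})

test_that("marginal fidelity: frequencies match configuration at n = 10000", {
  co <- small_cohort(n = 10000, seed = 5)
  m <- default_marginals()
  for (feat in c("age_group", "sex", "kps", "location", "who_grade",
                 "resection", "radiotherapy", "chemotherapy", "mol_group")) {
    p <- m[[feat]]
    cnt <- table(co[[feat]])[names(p)]
    obs <- cnt / nrow(co)
    se <- sqrt(p * (1 - p) / nrow(co))
    # ~34 simultaneous level checks: 4 SE keeps the familywise false-alarm
    # probability ~0.2%, where a per-level 3 SE bound would trip by chance
    expect_true(all(abs(obs - p) <= 4 * se + 1e-12),
                info = paste("marginal drift in", feat))
    # and a per-feature goodness-of-fit check
    gof <- suppressWarnings(stats::chisq.test(as.numeric(cnt), p = p))
    expect_gt(gof$p.value, 1e-3)
  }
})

test_that("zero baseline hazard yields a fully censored cohort", {
  co <- generate_cohort(cohort_config(n_patients = 100, seed = 2,
                                      baseline_hazard = 0))
  expect_true(all(co$pfs_event == 0))
  expect_true(all(co$os_event == 0))
})

test_that("exponential survival median matches the closed form", {
  # rate ln2 / 24 per month, no covariate effects: median event time ~ 24
  r <- log(2) / 24
  cfg <- cohort_config(n_patients = 6000, seed = 8, baseline_hazard = r,
                       effect_logits = lapply(default_effect_logits(),
                                              function(e) e * 0),
                       admin_censor_max = 2000)
  co <- generate_cohort(cfg)
  # compare against an independent inverse-CDF exponential oracle
  set.seed(8)
  oracle <- stats::qexp(stats::runif(6000), rate = r)
  events <- co$pfs_months[co$pfs_event == 1]
  expect_lt(abs(median(events) - 24), 1.5)
  expect_lt(abs(median(events) - median(oracle)), 2)
})

test_that("planted grade effect shortens grade-IV progression per the oracle", {
  eff <- lapply(default_effect_logits(), function(e) e * 0)
  eff$who_grade <- c(II = 0, III = 0, IV = 1)
  cfg <- cohort_config(n_patients = 4000, seed = 13,
                       baseline_hazard = 0.02, effect_logits = eff,
                       admin_censor_max = 3000)
  co <- generate_cohort(cfg)
  iv <- co$who_grade == "IV"
  med_iv <- median(co$pfs_months[iv & co$pfs_event == 1])
  med_lo <- median(co$pfs_months[!iv & co$pfs_event == 1])
  expect_lt(med_iv, med_lo)
  # oracle: direct inverse-CDF exponential simulation at the same rates
  set.seed(99)
  o_iv <- median(stats::qexp(stats::runif(2e5), rate = 0.02 * exp(1)))
  o_lo <- median(stats::qexp(stats::runif(2e5), rate = 0.02))
  expect_lt(abs(med_iv - o_iv), 1.5)
  expect_lt(abs(med_lo - o_lo), 2.5)
})

test_that("null effects leave the label independent of every feature", {
  cfg <- cohort_config(n_patients = 2000, seed = 21,
                       effect_logits = lapply(default_effect_logits(),
                                              function(e) e * 0))
  co <- generate_cohort(cfg)
  lab <- cohort_label(co, "pfs")$label
  ps <- vapply(glioma_features(),
               function(f) chi2_independence(co[[f]], lab), 0)
  # under the null, p-values should not pile up near 0
  expect_gt(min(ps), 1e-4)
  expect_gt(mean(ps > 0.1), 0.5)
})

test_that("piecewise baseline sampler matches a closed-form check", {
  bh <- data.frame(start = c(0, 12), rate = c(0.05, 0.2))
  set.seed(4)
  t <- mcdsl:::sample_piecewise_exponential(2e5, bh, rep(1, 2e5))
  # S(12) = exp(-0.6); S(24) = exp(-0.6 - 2.4)
  expect_lt(abs(mean(t > 12) - exp(-0.6)), 0.01)
  expect_lt(abs(mean(t > 24) - exp(-3.0)), 0.01)
})
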