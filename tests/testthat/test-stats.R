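test_that("endpoint adjudication reproduces component counts and flags", {
  coh <- fixture_endpoint_cohort()
  adj <- adjudicate(coh)
  expect_equal(sum(adj$ae_flag), 69)
  expect_equal(sum(adj$icd_therapy_flag), 22)
  expect_equal(sum(adj$scd_flag), 14)
  # secondary endpoint is a subset of the composite
  expect_true(all(adj$ae_flag[adj$icd_therapy_flag]))
  # SCD record: composite yes, secondary no
  one <- adjudicate(data.frame(event_type = "SCD", event_month = 12,
                               followup_months = 12))
  expect_true(one$ae_flag)
  expect_false(one$icd_therapy_flag)
  expect_equal(one$ae_time, 12)
  # all-censored cohort
  none <- adjudicate(data.frame(event_type = rep("none", 5),
                                event_month = NA_real_,
                                followup_months = 10:14))
  expect_equal(sum(none$ae_flag), 0)
  expect_equal(none$ae_time, 10:14)
  # event without a month is an error
  expect_error(adjudicate(data.frame(event_type = "SCD", event_month = NA,
                                     followup_months = 10)),
               "without an event month")
})

test_that("group comparisons pick the appropriate test", {
  # identical numeric groups -> p = 1
  d <- data.frame(x = rep(c(1, 2, 3, 4, 5, 6, 7, 8), 2),
                  g = rep(c(TRUE, FALSE), each = 8))
  res <- compare_groups(d, "x", "g")
  expect_equal(res$p, 1, tolerance = 1e-9)

  # fully separated 2x2 table -> tiny p (oracle: exact hypergeometric)
  d2 <- data.frame(x = rep(c(1, 0), each = 10), g = rep(c(TRUE, FALSE), each = 10))
  res2 <- compare_groups(d2, "x", "g")
  expect_lt(res2$p, 0.001)
  oracle_p <- fisher.test(table(d2$x, d2$g))$p.value
  expect_lt(oracle_p, 0.001)

  # a clearly non-normal variable falls back to Mann-Whitney, and a large
  # shift is detected (oracle: large-sample z approximation agrees)
  set.seed(8)
  n <- 300
  d3 <- data.frame(x = exp(rnorm(2 * n)) + rep(c(0, 1.5), each = n),
                   g = rep(c(FALSE, TRUE), each = n))
  res3 <- compare_groups(d3, "x", "g")
  expect_equal(res3$test, "mann-whitney")
  expect_lt(res3$p, 1e-6)
  z_oracle <- wilcox.test(x ~ g, data = d3, exact = FALSE)$p.value
  expect_equal(res3$p, z_oracle)

  expect_error(compare_groups(data.frame(x = rep(1, 10),
                                         g = rep(c(TRUE, FALSE), 5)), "x", "g"),
               "constant")
})

test_that("Kaplan-Meier estimates match hand-computed product limits", {
  # no events: flat at 1
  k0 <- km_curve(c(3, 5, 8), c(0, 0, 0))
  expect_true(all(k0$surv == 1))
  expect_true(is.na(k0$median))
  # events at t = 1, 2 in n = 2 -> S = 0.5 then 0
  k1 <- km_curve(c(1, 2), c(1, 1))
  expect_equal(k1$surv, c(0.5, 0))
  # hand product-limit on a 5-subject fixture with censoring interleaved:
  # t=1 event (4/5), t=2 censored, t=3 event (4/5 * 2/3), t=4,5 censored
  k2 <- km_curve(c(1, 2, 3, 4, 5), c(1, 0, 1, 0, 0))
  expect_equal(k2$surv[k2$time == 1], 4 / 5)
  expect_equal(k2$surv[k2$time == 3], 4 / 5 * 2 / 3)
  # extending a censoring time beyond the last event leaves the curve unchanged
  k3 <- km_curve(c(1, 2, 3, 9, 5), c(1, 0, 1, 0, 0))
  expect_equal(k3$surv[k3$time %in% c(1, 3)], k2$surv[k2$time %in% c(1, 3)])
  expect_error(km_curve(c(-1, 2), c(1, 1)), "positive")
})

test_that("Cox fits recover null covariates and decompose chi-square", {
  set.seed(31)
  n <- 4000
  noisecov <- rnorm(n)
  tev <- rexp(n, 0.05)
  tc <- runif(n, 1, 40)
  coh <- data.frame(
    x = noisecov, ess = rnorm(n, 30, 10),
    event_type = factor(ifelse(tev <= tc, "SCD", "none"),
                        levels = event_type_levels()),
    event_month = ifelse(tev <= tc, tev, NA),
    followup_months = pmin(tev, tc))
  fit <- cox_fit(coh, endpoint = "ae", covariates = "x")
  expect_equal(fit$terms$hr, 1, tolerance = 0.06)
  expect_true(fit$terms$ci_lower < 1 && fit$terms$ci_upper > 1)

  # sequential change-chi-square equals the definitional log-likelihood gap
  fit2 <- cox_fit(coh, endpoint = "ae", covariates = c("ess", "x"),
                  sequential = TRUE)
  adj <- adjudicate(coh)
  s <- survival::Surv(adj$ae_time, adj$ae_flag)
  ll_null <- survival::coxph(s ~ 1)$loglik
  ll_1 <- survival::coxph(s ~ adj$ess)$loglik[2]
  ll_2 <- survival::coxph(s ~ adj$ess + adj$x)$loglik[2]
  expect_equal(fit2$terms$change_chisq[fit2$terms$term == "ess"],
               2 * (ll_1 - ll_null[1]))
  expect_equal(fit2$terms$change_chisq[fit2$terms$term == "x"],
               2 * (ll_2 - ll_1))
  expect_equal(fit2$model_chisq, 2 * (ll_2 - ll_null[1]))
  expect_equal(sum(unique(fit2$terms$change_chisq)), fit2$model_chisq)

  expect_error(cox_fit(coh[1:30, ], "ae", "x", min_events = 25), "events")
  expect_error(cox_fit(coh, "ae", "nonexistent"), "unknown covariate")
})

test_that("time-dependent ROC reduces to the plain ROC without censoring", {
  coh <- fixture_uncensored()
  adj <- adjudicate(coh)
  r <- td_roc(adj, "marker", horizon_months = 24)
  case <- adj$ae_flag
  expect_equal(r$auc, oracle_auc(adj$marker, case), tolerance = 1e-12)
  if (requireNamespace("pROC", quietly = TRUE)) {
    proc_auc <- as.numeric(pROC::auc(pROC::roc(case, adj$marker, quiet = TRUE,
                                               direction = "<")))
    expect_equal(r$auc, proc_auc, tolerance = 1e-12)
  }

  # perfect marker: the event indicator itself
  adj$perfect <- as.numeric(adj$ae_flag)
  expect_equal(td_roc(adj, "perfect", 24)$auc, 1)

  # independent marker: AUC near 0.5 (larger fixture tames Monte-Carlo noise)
  big <- adjudicate(fixture_uncensored(n = 400, seed = 23))
  set.seed(99)
  big$junk <- rnorm(nrow(big))
  expect_lt(abs(td_roc(big, "junk", 24)$auc - 0.5), 0.1)

  expect_error(td_roc(adj, "marker", horizon_months = 0.5), "no events")
})

test_that("late H/M categorization partitions the positive axis", {
  expect_equal(as.character(categorize_late_hm(c(1.19, 1.2, 1.4, 1.6, 1.61))),
               c("low", "intermediate", "intermediate", "intermediate", "high"))
  expect_error(categorize_late_hm(0), "positive")
  expect_error(categorize_late_hm(-1), "positive")
  # every positive value maps to exactly one bin
  set.seed(12)
  v <- exp(rnorm(500))
  cats <- categorize_late_hm(v)
  expect_false(anyNA(cats))
  expect_equal(sum(table(cats)), 500)
})

test_that("bell-shape test contrasts combined extremes with intermediates", {
  # equal event rates in all bins -> not significant
  n <- 120
  flat <- data.frame(
    late_hm = rep(c(1.0, 1.4, 1.8), each = n / 3),
    event_type = factor(rep(rep(c("SCD", "none"), each = n / 6), 3),
                        levels = event_type_levels()))
  flat$event_month <- ifelse(flat$event_type == "SCD", 6, NA)
  flat$followup_months <- ifelse(flat$event_type == "SCD", 6, 24)
  expect_gt(bellshape_test(flat)$p, 0.5)

  # strong intermediate excess -> significant, higher intermediate rate
  bell <- flat
  bell$event_type[bell$late_hm == 1.4] <-
    factor("SCD", levels = event_type_levels())
  bell$event_month[bell$late_hm == 1.4] <- 6
  bell$followup_months[bell$late_hm == 1.4] <- 6
  res <- bellshape_test(bell)
  expect_lt(res$p, 0.001)
  expect_gt(res$event_rates["intermediate"], res$event_rates["extreme"])
})

test_that("ICC matches the variance-component ratio and bands correctly", {
  # identical reader columns -> ICC 1, excellent
  x <- matrix(rep(1:20, 3), 20, 3)
  r <- icc(x)
  expect_equal(r$estimate, 1)
  expect_equal(r$band, "excellent")

  # independent noise columns -> ICC near 0, poor
  set.seed(5)
  r0 <- icc(matrix(rnorm(300 * 3), 300, 3))
  expect_lt(abs(r0$estimate), 0.15)
  expect_equal(r0$band, "poor")

  # known variance components: sigma2_subject = 4, sigma2_error = 1 -> 0.8
  set.seed(6)
  n <- 500
  subj <- rnorm(n, 0, 2)
  tab <- matrix(subj, n, 3) + matrix(rnorm(n * 3), n, 3)
  r1 <- icc(tab)
  expect_equal(r1$estimate, 0.8, tolerance = 0.03)
  expect_true(r1$ci_lower < 0.8 && r1$ci_upper > r1$estimate)
  expect_equal(r1$band, "excellent")

  # agreement form penalises a systematic reader shift; consistency does not
  shifted <- tab
  shifted[, 3] <- shifted[, 3] + 3
  expect_lt(icc(shifted)$estimate, icc(shifted, type = "consistency")$estimate)

  expect_error(icc(tab[1:3, ]), "at least 5")
  expect_error(icc(matrix(rep(1, 20), 10, 2)), "between-subject")
  # band cut-offs
  expect_equal(icc_band(c(0.39, 0.40, 0.59, 0.60, 0.74, 0.75)),
               c("poor", "fair", "fair", "good", "good", "excellent"))
})
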