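test_that("planar truth validates its invariants and closes the washout equation", {
  tr <- planar_truth(He = 100, Me = 50, Hl = 80, Ml = 45)
  expect_equal(tr$WO, washout(100, 50, 80, 45))
  expect_error(planar_truth(He = 50, Me = 50, Hl = 10, Ml = 5), "He > Me")
  expect_error(planar_truth(He = 50, Me = -1, Hl = 10, Ml = 5), "He > Me")
  expect_error(planar_truth(He = 50, Me = 10, Hl = -1, Ml = 5), "non-negative")
  expect_error(make_planar_pair(tr, image_shape = c(20, 20)), "32")
})

test_that("zero-washout truth yields zero washout through the pipeline", {
  He <- 180; Me <- 60
  Ml <- 50; Hl <- (He - Me) / 1.21 + Ml
  tr <- planar_truth(He, Me, Hl, Ml)
  ph <- make_planar_pair(tr, noise = "off")
  pm <- planar_metrics(ph$early, ph$late, ph$roi)
  expect_equal(pm$wo_percent, 0, tolerance = 1e-12)
})

test_that("Poisson planar phantoms give H/M estimates within counting error", {
  tr <- planar_truth(He = 120, Me = 60, Hl = 90, Ml = 55)
  # delta-method SE of the ratio of two Poisson-mean estimates
  se_ratio <- function(H, M, nH, nM) (H / M) * sqrt(1 / (nH * H) + 1 / (nM * M))
  ph0 <- make_planar_pair(tr, image_shape = c(64, 64), noise = "off")
  nH <- nrow(roi_pixels(ph0$roi$heart, c(64, 64)))
  nM <- 49
  se <- se_ratio(120, 60, nH, nM)

  # fixed seed: estimate within 3 SE of truth
  ph <- make_planar_pair(tr, image_shape = c(64, 64), noise = "on", seed = 5)
  est <- hm_ratio(ph$early, ph$roi$heart, ph$roi$mediastinum)
  expect_lt(abs(est - 2), 3 * se)

  # empirical coverage of the 3-SE band over many seeds
  reps <- 200
  est <- vapply(seq_len(reps), function(s) {
    p <- make_planar_pair(tr, image_shape = c(64, 64), noise = "on", seed = s)
    hm_ratio(p$early, p$roi$heart, p$roi$mediastinum)
  }, numeric(1))
  expect_gte(mean(abs(est - 2) <= 3 * se), 0.97)
})

test_that("H/M estimator bias vanishes as counts grow", {
  reps <- 150
  bias <- sd_est <- numeric(3)
  scales <- c(1, 10, 100)
  for (k in seq_along(scales)) {
    tr <- planar_truth(He = 12 * scales[k], Me = 6 * scales[k],
                       Hl = 9 * scales[k], Ml = 5 * scales[k])
    est <- vapply(seq_len(reps), function(s) {
      p <- make_planar_pair(tr, image_shape = c(48, 48), noise = "on",
                            seed = 1000 * k + s)
      hm_ratio(p$early, p$roi$heart, p$roi$mediastinum)
    }, numeric(1))
    bias[k] <- mean(est) - 2
    sd_est[k] <- sd(est)
  }
  # dispersion shrinks with counts and bias is within Monte-Carlo error of 0
  expect_true(all(diff(sd_est) < 0))
  expect_true(all(abs(bias) <= 4 * sd_est / sqrt(reps) + 1e-3))
  expect_lt(abs(bias[3]), abs(bias[1]) + 4 * sd_est[1] / sqrt(reps))
})

test_that("SPECT phantom geometry validates and reproduces uniform truth", {
  expect_error(volume_truth(rep(100, 16)), "17")
  expect_error(volume_truth(c(rep(100, 16), 120)), "\\[0, 100\\]")
  expect_error(volume_truth(rep(50, 17)), "maximum")
  expect_error(volume_truth(rep(100, 17), dim = c(20, 32, 32),
                            center = c(16, 16), r_outer = 18), "bounds")
  v <- make_spect_volume(volume_truth(rep(100, 17)), noise = "off")
  expect_equal(segment_uptake(v), rep(100, 17))
})

test_that("phantom segment means match generator-mask averaging", {
  up <- c(rep(100, 16), 35)
  v <- make_spect_volume(volume_truth(up), noise = "off")
  # oracle: average counts over the generator's own voxel labels
  lab <- attr(v, "segment_map")
  oracle <- vapply(1:17, function(s) mean(v$counts[which(lab == s)]), numeric(1))
  oracle <- 100 * oracle / max(oracle)
  expect_equal(segment_uptake(v), oracle, tolerance = 1e-12)
  expect_equal(segment_uptake(v)[17], 35, tolerance = 0.5)
  expect_equal(segment_uptake(v)[1:16], rep(100, 16))
})

test_that("Poisson SPECT phantoms recover scores away from bin edges", {
  # all uptakes at least 5 points from the 70/60/50/40 bin edges
  up <- c(100, 90, 80, 76, 64, 55, 45, 34, 25, 85, 95, 100, 76, 64, 45, 90, 80)
  tru <- volume_truth(up)
  noiseless <- score_segment(segment_uptake(make_spect_volume(tru, noise = "off")))
  noisy <- score_segment(segment_uptake(make_spect_volume(tru, noise = "on",
                                                          seed = 9)))
  expect_identical(noisy, noiseless)
})

test_that("cohort calibration validates and the generator is reproducible", {
  expect_error(cohort_calibration(proportions = c(male = 1.2)), "\\[0, 1\\]")
  expect_error(cohort_calibration(event_type_probs = c(a = 0.5, b = 0.4)),
               "sum to 1")
  expect_error(make_cohort(n = 5), "at least 10")
  c1 <- make_cohort(seed = 123)
  c2 <- make_cohort(seed = 123)
  expect_identical(c1, c2)
  expect_equal(nrow(c1), 170)
  # integer summed scores in range, dss exact
  expect_true(all(c1$ess == round(c1$ess) & c1$ess >= 0 & c1$ess <= 68))
  expect_identical(c1$dss, c1$ess - c1$lss)
})

test_that("cohort covariates converge to their calibration values", {
  cal <- cohort_calibration()
  coh <- make_cohort(cal, n = 10000, seed = 77)
  spec <- cal$continuous
  for (i in seq_len(nrow(spec))) {
    v <- coh[[spec$var[i]]]
    se <- spec$sd[i] / sqrt(10000)
    # 3 SE plus the small truncation/rounding shift of bounded marginals
    expect_lt(abs(mean(v) - spec$mean[i]), 3 * se + 0.02 * spec$sd[i])
  }
  for (nm in names(cal$proportions)) {
    p <- cal$proportions[[nm]]
    expect_lt(abs(mean(coh[[nm]]) - p), 3 * sqrt(p * (1 - p) / 10000))
  }
  # copula correlations survive the marginal transforms
  expect_equal(cor(coh$ess, coh$lss), 0.8, tolerance = 0.05)
  expect_equal(cor(coh$late_hm, coh$ess), -0.4, tolerance = 0.05)
})

test_that("zero hazard multipliers censor the whole cohort", {
  cal <- cohort_calibration(hm_multipliers = c(low = 0, intermediate = 0, high = 0))
  coh <- make_cohort(cal, n = 200, seed = 4)
  expect_true(all(coh$event_type == "none"))
  expect_true(all(is.na(coh$event_month)))
  expect_true(all(coh$followup_months >= cal$censor_window_months[1] &
                    coh$followup_months <= cal$censor_window_months[2]))
})
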