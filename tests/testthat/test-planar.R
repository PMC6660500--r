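test_that("mean counts over ROIs match explicit pixel averages", {
  # uniform image: any ROI returns the constant
  img <- planar_image(matrix(7, 40, 40))
  expect_equal(mean_counts(img, roi_square(5, 5)), 7)
  poly <- roi_polygon(cbind(x = c(10, 30, 20), y = c(10, 10, 30)))
  expect_equal(mean_counts(img, poly), 7)

  # 7x7 square on a ramp: oracle is the explicit sum over the 49 pixels
  ramp <- outer(0:39, 0:39, function(r, c) r + 2 * c)
  img2 <- planar_image(ramp)
  r0 <- 12; c0 <- 20
  oracle <- sum(ramp[r0 + (1:7), c0 + (1:7)]) / 49
  expect_equal(mean_counts(img2, roi_square(r0, c0)), oracle)

  # polygon covering exactly the left half of a two-valued image -> midpoint
  two <- matrix(10, 40, 40)
  two[1:20, ] <- 30  # top half 30, bottom half 10
  img3 <- planar_image(two)
  half <- roi_polygon(cbind(x = c(-0.5, 9.5, 9.5, -0.5),
                            y = c(-0.5, -0.5, 39.5, 39.5)))
  expect_equal(mean_counts(img3, half), (10 + 30) / 2)

  # pixel-center rasterization: a square polygon covers the expected grid
  sq <- roi_polygon(cbind(x = c(4.5, 9.5, 9.5, 4.5), y = c(4.5, 4.5, 9.5, 9.5)))
  px <- roi_pixels(sq, c(40, 40))
  expect_equal(nrow(px), 25)  # centers 5..9 in each direction

  expect_error(mean_counts(img, roi_square(38, 38)), "bounds")
})

test_that("H/M ratio is a scale-invariant ratio of ROI means", {
  m <- matrix(50, 64, 64)
  m[40:50, 25:35] <- 100
  heart <- roi_polygon(cbind(x = c(24.5, 34.5, 34.5, 24.5),
                             y = c(39.5, 39.5, 49.5, 49.5)))
  med <- roi_square(5, 28)
  img <- planar_image(m)
  expect_equal(hm_ratio(img, heart, med), 2.0)
  # global count scaling leaves the ratio unchanged
  for (c in c(0.5, 3, 117)) {
    expect_equal(hm_ratio(planar_image(m * c), heart, med), 2.0)
  }
  expect_error(hm_ratio(planar_image(m * 0), heart, med), "zero")
})

test_that("washout follows the background/decay-corrected formula", {
  # hand evaluation: 100 * (150 - 60 * 1.21) / 150 = 100 * 77.4 / 150
  expect_equal(washout(200, 50, 100, 40), 51.6)
  # zero-washout fixed point: late background-corrected = early / decay
  expect_equal(washout(200, 50, 150 / 1.21 + 40, 40), 0)
  # complete washout
  expect_equal(washout(200, 50, 40, 40), 100)
  # undefined when early heart does not exceed mediastinum
  expect_error(washout(50, 50, 40, 30), "undefined")
  expect_error(washout(40, 50, 40, 30), "undefined")
})

test_that("washout is monotone in its count arguments", {
  base <- washout(200, 50, 100, 40)
  # strictly decreasing in Hl
  expect_true(washout(200, 50, 110, 40) < base)
  expect_true(washout(200, 50, 90, 40) > base)
  # strictly increasing in He
  expect_true(washout(210, 50, 100, 40) > base)
  expect_true(washout(190, 50, 100, 40) < base)
  # algebraic identity at decay factor 1:
  # WO(f=1) + 100 * (Hl-Ml)/(He-Me) = 100
  for (i in 1:20) {
    set.seed(i)
    He <- runif(1, 100, 300); Me <- runif(1, 10, He - 1)
    Hl <- runif(1, 0, 200); Ml <- runif(1, 0, Hl + 10)
    expect_equal(washout(He, Me, Hl, Ml, decay_factor = 1) +
                   100 * (Hl - Ml) / (He - Me), 100)
  }
})

test_that("decay factor is exponential in the interval", {
  expect_equal(decay_factor(0), 1.0)
  expect_equal(decay_factor(13.22), 2.0)
  expect_equal(decay_factor(2 * 13.22), 4.0)
  expect_equal(decay_factor(3.75), 2^(3.75 / 13.22))
  expect_error(decay_factor(-1), "non-negative")
  expect_error(decay_factor(3.75, 0), "positive")
})

test_that("automatic mediastinal ROI lands in the low-count band", {
  tr <- planar_truth(He = 160, Me = 80, Hl = 120, Ml = 70)
  ph <- make_planar_pair(tr, noise = "off")
  auto <- auto_mediastinal_roi(ph$early)
  # every pixel of the returned square sits at the mediastinal level
  px <- roi_pixels(auto, dim(ph$early$counts))
  expect_true(all(ph$early$counts[px] == 80))
  # matches the generator ROI's mean
  expect_equal(mean_counts(ph$early, auto),
               mean_counts(ph$early, ph$roi$mediastinum))
  # margin constraint: never touches the 1-pixel border
  expect_gte(auto$row0, 1)
  expect_gte(auto$col0, 1)
  expect_lte(auto$row0 + auto$size, nrow(ph$early$counts) - 1)
  expect_lte(auto$col0 + auto$size, ncol(ph$early$counts) - 1)

  # uniform image: deterministic topmost-then-leftmost tie-break
  uni <- planar_image(matrix(5, 64, 64))
  tie <- auto_mediastinal_roi(uni)
  expect_equal(tie$row0, 1)
  expect_equal(tie$col0, floor(64 / 3))
})

test_that("planar pipeline reproduces noiseless truth to machine precision", {
  tr <- planar_truth(He = 162, Me = 100, Hl = 145.2, Ml = 95)
  ph <- make_planar_pair(tr, noise = "off")
  pm <- planar_metrics(ph$early, ph$late, ph$roi)
  expect_identical(pm$He, 162)
  expect_identical(pm$early_hm, 1.62)
  expect_equal(pm$late_hm, 145.2 / 95, tolerance = 1e-15)
  expect_equal(pm$wo_percent, tr$WO, tolerance = 1e-12)
})
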