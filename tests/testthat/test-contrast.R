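# one shared noiseless phantom for placement tests (coarse voxels keep it fast)
iec_default <- gen_iec_volume(noiseless = TRUE)

test_that("ROI placement: 60 background ROIs per size with valid margins", {
  rois <- place_rois(iec_default)
  expect_equal(rois$n_per_size, 60L)
  expect_length(rois$background_rois, 5L)  # sizes 13, 17, 22, 28, 37
  gt <- attr(iec_default, "ground_truth")
  for (bg in rois$background_rois) {
    expect_equal(nrow(bg$centres_mm), 12L)
    expect_length(bg$slices, 5L)
    r_roi <- bg$diameter_mm / 2
    # margin to the phantom wall
    rad <- sqrt(rowSums(bg$centres_mm^2))
    expect_true(all(rad + r_roi <= gt$phantom_radius_mm - 15 + 1e-9))
    # margin to every sphere edge
    for (s in seq_along(gt$sphere_diameters_mm)) {
      d <- sqrt((bg$centres_mm[, 1] - gt$sphere_centres_mm[s, 1])^2 +
                (bg$centres_mm[, 2] - gt$sphere_centres_mm[s, 2])^2)
      expect_true(all(d >= r_roi + gt$sphere_diameters_mm[s] / 2 + 15 - 1e-9))
    }
  }
})

test_that("slice offsets snap to the nearest slice of the 2.46 mm grid", {
  rois <- place_rois(iec_default)
  snapped <- sort(rois$snapped_offsets_mm)
  expect_equal(snapped, c(-19.68, -9.84, 0, 9.84, 19.68), tolerance = 1e-9)
})

test_that("ROI area approximates the analytic circle area", {
  idx <- spectqc:::roi_members(iec_default, c(0, 0), 37 / 2)
  area <- nrow(idx) * prod(iec_default$voxel_mm[1:2])
  expect_lt(abs(area - pi * 18.5^2) / (pi * 18.5^2), 0.05)
})

test_that("full-recovery phantom: Q = 100% for every sphere, N = 0", {
  vol <- gen_iec_volume(hot_flags = rep(TRUE, 6), noiseless = TRUE)
  ca <- contrast_analysis(vol)
  expect_true(all(abs(ca$recovery$Q_percent - 100) < 1e-9))
  expect_true(all(ca$background$N_percent == 0))

  # cold spheres with zero counts -> Q_C = 100 as well
  vol2 <- gen_iec_volume(noiseless = TRUE)
  ca2 <- contrast_analysis(vol2)
  cold <- !ca2$recovery$hot
  expect_true(all(abs(ca2$recovery$Q_percent[cold] - 100) < 1e-9))
})

test_that("cold sphere at background level gives zero cold contrast", {
  vol <- gen_iec_volume(sphere_multipliers = c(8, 8, 8, 8, 1, 0),
                        noiseless = TRUE)
  ca <- contrast_analysis(vol)
  q28cold <- ca$recovery$Q_percent[!ca$recovery$hot &
                                   ca$recovery$diameter_mm == 28]
  expect_equal(q28cold, 0, tolerance = 1e-9)
})

test_that("hot-sphere recovery inverts the contrast formula exactly", {
  vol <- gen_iec_volume(sphere_multipliers = c(8, 8, 8, 5.466, 0, 0),
                        noiseless = TRUE)
  ca <- contrast_analysis(vol, a_H_over_a_B = 8)
  q28hot <- ca$recovery$Q_percent[ca$recovery$hot &
                                  ca$recovery$diameter_mm == 28]
  expect_equal(q28hot, 100 * (5.466 - 1) / (8 - 1), tolerance = 1e-9)
})

test_that("background variability reproduces the hand-computed alternation", {
  vol <- gen_iec_volume(noiseless = TRUE)
  rois <- place_rois(vol)
  bg37 <- rois$background_rois[["d37"]]
  # overwrite each 37 mm background ROI to alternate 99 / 101
  val <- rep(c(99, 101), length.out = 60)
  n <- 0
  for (k in bg37$slices) {
    for (i in seq_len(nrow(bg37$centres_mm))) {
      n <- n + 1
      idx <- spectqc:::roi_members(vol, bg37$centres_mm[i, ], 37 / 2)
      vol$counts[cbind(idx, k)] <- val[n]
    }
  }
  bv <- background_variability(vol, rois)
  row37 <- bv[bv$diameter_mm == 37, ]
  expect_equal(row37$c_B, 100)
  expect_equal(row37$SD, sqrt(60 / 59), tolerance = 1e-9)   # = 1.00844
  expect_equal(row37$N_percent, 100 * sqrt(60 / 59) / 100,
               tolerance = 1e-9)
})

test_that("lung error endpoints and constructed ratio", {
  # lung filled to the background level -> 100% on every slice
  vol_bg <- gen_iec_volume(noiseless = TRUE, lung_multiplier = 1)
  le <- lung_error(vol_bg, place_rois(vol_bg))
  expect_true(all(abs(le$per_slice_percent - 100) < 1e-9))

  # perfect cold insert -> 0%
  vol0 <- gen_iec_volume(noiseless = TRUE, lung_multiplier = 0)
  le0 <- lung_error(vol0, place_rois(vol0))
  expect_true(all(le0$per_slice_percent == 0))

  vol_r <- gen_iec_volume(noiseless = TRUE, lung_multiplier = 0.458)
  ler <- lung_error(vol_r, place_rois(vol_r))
  expect_equal(ler$summary_percent, 45.8, tolerance = 1e-9)
})

test_that("contrast coefficients are invariant to global count scaling", {
  vol <- gen_iec_volume(psf_fwhm_mm = 8, noiseless = TRUE)
  ca1 <- contrast_analysis(vol)
  vol2 <- vol
  vol2$counts <- vol$counts * 4.2
  ca2 <- contrast_analysis(vol2)
  expect_equal(ca2$recovery$Q_percent, ca1$recovery$Q_percent,
               tolerance = 1e-9)
  expect_equal(ca2$background$N_percent, ca1$background$N_percent,
               tolerance = 1e-6)
})

test_that("PSF blur lowers hot recovery below 100% most for small spheres", {
  vol <- gen_iec_volume(psf_fwhm_mm = 10, noiseless = TRUE)
  ca <- contrast_analysis(vol)
  hot <- ca$recovery[ca$recovery$hot, ]
  hot <- hot[order(hot$diameter_mm), ]
  expect_true(all(hot$Q_percent < 100))
  expect_true(all(diff(hot$Q_percent) > 0))  # recovery grows with diameter
})

test_that("background variability scales as one over root counts", {
  levels <- c(10, 100, 1000)
  N37 <- vapply(seq_along(levels), function(i) {
    vol <- gen_iec_volume(background_level = levels[i], seed = 100 + i)
    bv <- background_variability(vol, place_rois(vol))
    bv$N_percent[bv$diameter_mm == 37]
  }, 0)
  slope <- stats::coef(stats::lm(log(N37) ~ log(levels)))[2]
  expect_lt(abs(slope + 0.5), 0.15)
})

test_that("lung error requires 37 mm background ROIs", {
  vol <- gen_iec_volume(sphere_diameters_mm = c(13, 17, 22, 28),
                        hot_flags = c(TRUE, TRUE, TRUE, FALSE),
                        noiseless = TRUE)
  rois <- place_rois(vol)
  expect_error(lung_error(vol, rois), "37 mm")
})
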