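test_that("generators are bit-for-bit reproducible under a fixed seed", {
  s1 <- gen_spectrum(140.5, 0.0527, 1e5, 0.5, 0.02, seed = 11)
  s2 <- gen_spectrum(140.5, 0.0527, 1e5, 0.5, 0.02, seed = 11)
  expect_identical(s1$counts, s2$counts)

  f1 <- gen_flood(total_counts = 1e6, seed = 3)
  f2 <- gen_flood(total_counts = 1e6, seed = 3)
  expect_identical(f1$counts, f2$counts)
  expect_false(identical(f1$counts,
                         gen_flood(total_counts = 1e6, seed = 4)$counts))

  resp <- response_model("identity")
  d1 <- gen_decay_series(10, tc99m_half_life, resp, 100, 5, seed = 7)
  d2 <- gen_decay_series(10, tc99m_half_life, resp, 100, 5, seed = 7)
  expect_identical(d1$counts, d2$counts)
})

test_that("generators do not disturb the caller's RNG stream", {
  set.seed(99)
  before <- .Random.seed
  invisible(gen_spectrum(140.5, 0.05, 1e4, 0.5, 0.02, seed = 1))
  invisible(gen_flood(total_counts = 1e5, seed = 2))
  expect_identical(.Random.seed, before)
})

test_that("noiseless totals match the request within 0.1%", {
  s <- gen_spectrum(140.5, 0.0527, 4.5e6, 0.5, 0.02, noiseless = TRUE)
  expect_lt(abs(sum(s$counts) - 4.5e6) / 4.5e6, 1e-3)

  f <- gen_flood(total_counts = 2e7, noiseless = TRUE)
  expect_equal(sum(f$counts), 2e7, tolerance = 1e-10)

  l <- gen_line_image(fwhm_mm = 7, total_counts = 1e7, noiseless = TRUE)
  expect_lt(abs(sum(l$counts) - 1e7) / 1e7, 1e-3)

  v <- gen_point_volume(rbind(c(0, 0, 0)), 4.2, counts_per_source = 1e6,
                        noiseless = TRUE)
  expect_lt(abs(sum(v$counts) - 1e6) / 1e6, 1e-3)
})

test_that("spectrum generator validates its inputs", {
  expect_error(gen_spectrum(300, 0.05, 1e5), "energy range")
  expect_error(gen_spectrum(30, 0.05, 1e5), "energy range")
  expect_error(gen_spectrum(140.5, 0.05, 0), "positive")
})

test_that("flood generator: uniform field is flat and shape is checked", {
  f <- gen_flood(total_counts = 2e6, noiseless = TRUE)
  expect_true(all(f$counts == f$counts[1, 1]))
  u <- uniformity_analysis(f)
  expect_equal(u$UFOV$integral_percent, 0)
  expect_equal(u$UFOV$differential_percent, 0)

  expect_error(gen_flood(gain_map = matrix(1, 4, 4)), "geometry requires")
  bad_gain <- matrix(1, 16, 112)
  bad_gain[3, 3] <- 0
  expect_error(gen_flood(gain_map = bad_gain), "strictly positive")
})

test_that("flood with a scaled super-pixel region yields IU = 2.0% downstream", {
  # broad plateaus at 102 and 98 on whole super-pixel blocks survive the
  # 9-point smoothing, so IU = (102 - 98)/(102 + 98) * 100 = 2.0 exactly
  gain <- matrix(100, 16, 112)
  gain[3:8, 9:28] <- 102
  gain[9:14, 61:84] <- 98
  img <- gen_flood(gain_map = gain / 100, total_counts = 1e6,
                   noiseless = TRUE)
  u <- uniformity_analysis(img)
  expect_equal(u$UFOV$integral_percent, 2.0, tolerance = 1e-8)
})

test_that("decay series: identity response lies on the bisector", {
  resp <- response_model("identity")
  s <- gen_decay_series(100, tc99m_half_life, resp, 1000,
                        background_cps = 0, noiseless = TRUE)
  gt <- attr(s, "ground_truth")
  # recovered OCR equals true ICR at the measurement start within 0.1%
  C <- net_counts(s$counts, s$dt_s, s$background_cps)
  ocr <- observed_rate(as.numeric(C), s$dt_s, s$tau_s)
  icr_true <- 1000 * 100 * 2^(-s$t_start_s / tc99m_half_life)
  expect_lt(max(abs(ocr - icr_true) / icr_true), 1e-3)
})

test_that("decay series: background-only counts are pure background", {
  resp <- response_model("identity")
  s <- gen_decay_series(0, tc99m_half_life, resp, 1000,
                        background_cps = 50, noiseless = TRUE)
  expect_equal(s$counts, 50 * s$dt_s, tolerance = 1e-9)
  C <- net_counts(s$counts, s$dt_s, s$background_cps)
  expect_true(all(abs(C) < 1e-6))
})

test_that("decay series rejects negative activities and rates", {
  resp <- response_model("identity")
  expect_error(gen_decay_series(-1, tc99m_half_life, resp, 100),
               "non-negative")
  expect_error(gen_decay_series(1, tc99m_half_life, resp, -5),
               "non-negative")
})

test_that("response models satisfy OCR(0) = 0 and OCR <= ICR", {
  x <- c(0, 10^(0:7))
  models <- list(
    response_model("identity"),
    response_model("saturating_exponential", ocr_max = 760000, k = 272920),
    response_model("nonparalyzable", dead_time_s = 1e-6),
    response_model("paralyzable", dead_time_s = 1e-6),
    response_model("clamped_linear", ocr_max = 1e5))
  for (m in models) {
    y <- response_eval(m, x)
    expect_equal(y[1], 0)
    expect_true(all(y <= x + 1e-9))
    if (m$model_kind %in% c("saturating_exponential", "clamped_linear",
                            "identity")) {
      expect_true(all(diff(y) >= -1e-9))  # non-decreasing
    }
  }
})

test_that("saturating shape constant reproduces the stated loss point", {
  k <- solve_saturating_k(760000, 917000, 0.8)
  m <- response_model("saturating_exponential", ocr_max = 760000, k = k)
  expect_equal(response_eval(m, 917000), 0.8 * 917000, tolerance = 1e-9)
  expect_lt(abs(response_eval(m, 1e8) - 760000) / 760000, 1e-6)
})

test_that("point-volume generator rejects overlapping blobs", {
  expect_error(
    gen_point_volume(rbind(c(0, 0, 0), c(10, 0, 0)), fwhm_mm = 4.2),
    "5 x max FWHM")
})

test_that("IEC generator rejects impossible sphere layouts", {
  expect_error(gen_iec_volume(sphere_diameters_mm = rep(37, 6),
                              hot_flags = rep(TRUE, 6),
                              ring_radius_mm = 20),
               "overlap")
  expect_error(gen_iec_volume(sphere_diameters_mm = c(13, 17, 22, 28, 28, 37),
                              ring_radius_mm = 140),
               "outside the phantom")
})

test_that("cylinder generator validates duration and factor count", {
  expect_error(gen_cylinder_projections(12, rep(1, 12), duration_s = 0),
               "positive")
  expect_error(gen_cylinder_projections(12, rep(1, 5)), "length")
})

test_that("ground truth round-trips through serialization unchanged", {
  vol <- gen_iec_volume(noiseless = TRUE, voxel_mm = 4.92)
  path <- tempfile(fileext = ".json")
  write_volume(vol, path)
  back <- read_volume(path)
  expect_equal(back$counts, vol$counts)
  expect_equal(back$voxel_mm, vol$voxel_mm)
  gt0 <- attr(vol, "ground_truth")
  gt1 <- attr(back, "ground_truth")
  expect_equal(gt1$sphere_diameters_mm, gt0$sphere_diameters_mm)
  expect_equal(gt1$sphere_centres_mm, gt0$sphere_centres_mm,
               tolerance = 1e-12, ignore_attr = TRUE)
  expect_equal(gt1$hot_flags, gt0$hot_flags)
  expect_equal(gt1$background_level, gt0$background_level)
})

test_that("recovery error shrinks monotonically with channel refinement", {
  errs <- vapply(c(2, 1, 0.5), function(w) {
    s <- gen_spectrum(140.5, 0.0527, 1e6, channel_keV = w,
                      background_fraction = 0, noiseless = TRUE)
    p <- find_photopeak(s)
    abs(as.numeric(fwhm_by_interpolation(s, p)) - 0.0527 * 140.5)
  }, 0)
  expect_true(all(diff(errs) < 0))
})
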