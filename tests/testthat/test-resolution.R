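test_that("profile width: symmetric triangle and Gaussian identities", {
  x <- seq(0, 20, by = 1)
  tri <- pmax(0, 10 - abs(x - 10))
  w <- profile_width(list(positions_mm = x, values = tri))
  expect_equal(as.numeric(w), 10)  # half-width of a symmetric triangle

  xs <- seq(-30, 30, by = 0.2)
  g <- exp(-xs^2 / (2 * 4^2))
  fwhm <- as.numeric(profile_width(list(positions_mm = xs, values = g)))
  fwtm <- as.numeric(profile_width(list(positions_mm = xs, values = g),
                                   0.1))
  expect_lt(abs(fwhm - gauss_width(4)) / gauss_width(4), 0.005)
  expect_lt(abs(fwtm / fwhm - 1.8226), 0.01)
})

test_that("profile width at detector pitch matches the brute-force oracle", {
  img <- gen_line_image(fwhm_mm = 9.91, centre_mm = 18.45, noiseless = TRUE)
  prof <- lsf_from_planar(img, "axial")
  est <- as.numeric(profile_width(prof))
  oracle <- brute_width(prof$positions_mm, prof$values)
  expect_lt(abs(est - oracle) / oracle, 0.02)
  expect_lt(abs(est - 9.91), 0.05)  # pixel-centred symmetric placement
})

test_that("line recovery within 2% of the dense-grid oracle at high counts", {
  img <- gen_line_image(fwhm_mm = 7.0, total_counts = 1e7, centre_mm = 18.45,
                        seed = 3)
  prof <- lsf_from_planar(img, "axial")
  est <- as.numeric(profile_width(prof))
  noiseless <- lsf_from_planar(gen_line_image(fwhm_mm = 7.0,
                                              centre_mm = 18.45,
                                              noiseless = TRUE), "axial")
  oracle <- brute_width(noiseless$positions_mm, noiseless$values)
  expect_lt(abs(est - oracle) / oracle, 0.02)
})

test_that("a flat pedestal does not change the estimated width", {
  img <- gen_line_image(fwhm_mm = 9.91, centre_mm = 18.45, noiseless = TRUE)
  w0 <- as.numeric(profile_width(lsf_from_planar(img, "axial")))
  img2 <- img
  img2$counts <- img$counts + 5
  w1 <- as.numeric(profile_width(lsf_from_planar(img2, "axial")))
  expect_lt(abs(w1 - w0) / w0, 0.01)
})

test_that("tilted lines are rejected with the measured tilt", {
  # build a line whose centroid drifts at 10 degrees across the image
  pitch <- 2.46
  n_perp <- 16
  n_along <- 112
  cnt <- matrix(0, n_perp, n_along)
  for (j in seq_len(n_along)) {
    centre <- 8 * pitch + tan(10 * pi / 180) * (j - 56) * pitch
    cnt[, j] <- exp(-(((seq_len(n_perp) - 0.5) * pitch) - centre)^2 / 18)
  }
  img <- planar_image(cnt * 1000, c(pitch, pitch))
  expect_error(lsf_from_planar(img, "axial"), "tilt")
})

test_that("distance extrapolation is exact, linear, and monotone in l_eff", {
  expect_equal(extrapolate_resolution(9.91, 150, 150, 17.72), 9.91)
  # linear in the measured width
  r1 <- extrapolate_resolution(5, 150, 100, 17.72)
  r2 <- extrapolate_resolution(10, 150, 100, 17.72)
  expect_equal(r2, 2 * r1)
  # monotone decreasing in l_eff when extrapolating inward
  leffs <- seq(0, 40, by = 5)
  vals <- extrapolate_resolution(10, 150, 100, 17.72) # baseline
  rs <- vapply(leffs, function(l) extrapolate_resolution(10, 150, 100, l), 0)
  expect_true(all(diff(rs) > 0))  # increases toward R_measured as l_eff grows
  expect_true(all(rs < 10))
})

test_that("orthogonal views of an isotropic source agree across axes", {
  vol <- gen_point_volume(rbind(c(0, 0, 0)), fwhm_mm = 4.2, voxel_mm = 1.23,
                          noiseless = TRUE)
  vw <- spect_point_views(vol, rbind(c(0, 0, 0)))[[1]]
  widths <- c(
    profile_width(spectqc:::view_marginal(vw$transverse, 1)),
    profile_width(spectqc:::view_marginal(vw$transverse, 2)),
    profile_width(spectqc:::view_marginal(vw$coronal, 2)),
    profile_width(spectqc:::view_marginal(vw$sagittal, 2)))
  expect_lt(max(widths) - min(widths), 1e-6)
})

test_that("anisotropic blob: per-view marginals match per-axis oracles", {
  fw <- c(3.4, 2.9, 2.8)
  vol <- gen_point_volume(rbind(c(0, 0, 0)), fwhm_mm = fw, voxel_mm = 1.23,
                          noiseless = TRUE)
  vw <- spect_point_views(vol, rbind(c(0, 0, 0)))[[1]]
  pairs <- list(list(view = vw$transverse, axis = 1, truth_axis = 1),
                list(view = vw$transverse, axis = 2, truth_axis = 2),
                list(view = vw$coronal, axis = 2, truth_axis = 3))
  for (p in pairs) {
    marg <- spectqc:::view_marginal(p$view, p$axis)
    est <- as.numeric(profile_width(marg))
    oracle <- brute_width(marg$positions_mm, marg$values)
    expect_lt(abs(est - oracle) / oracle, 0.02)
    # estimator also near the generating truth at this sampling
    expect_lt(abs(est - fw[p$truth_axis]), 1.23^2 / (2 * fw[p$truth_axis]))
  }
})

test_that("NEMA three-point layout labels central and peripheral sources", {
  pos <- rbind(c(0, 0, 0), c(73.8, 0, 0), c(-73.8, 0, 0))
  vol <- gen_point_volume(pos, fwhm_mm = 4.2, voxel_mm = 2.46,
                          noiseless = TRUE)
  rep <- spect_resolution_report(spect_point_views(vol, pos),
                                 "three_point_air")
  expect_true(all(c("central_transaxial_mm", "central_axial_mm",
                    "peripheral_radial_mm", "peripheral_tangential_mm",
                    "peripheral_axial_mm") %in% names(rep)))
  expect_length(rep$flags, 0)
})

test_that("isotropic truth fills every report entry with the same value", {
  pos <- rbind(c(0, 0, 0), c(73.8, 0, 0), c(-73.8, 0, 0))
  vol <- gen_point_volume(pos, fwhm_mm = 4.2, voxel_mm = 2.46,
                          noiseless = TRUE)
  rep <- spect_resolution_report(spect_point_views(vol, pos),
                                 "three_point_air")
  vals <- unlist(rep[c("central_transaxial_mm", "central_axial_mm",
                       "peripheral_radial_mm", "peripheral_tangential_mm",
                       "peripheral_axial_mm")])
  expect_lt(max(vals) - min(vals), 1e-6)
})

test_that("rotating the layout 90 degrees leaves isotropic results fixed", {
  pos1 <- rbind(c(0, 0, 0), c(73.8, 0, 0), c(-73.8, 0, 0))
  pos2 <- rbind(c(0, 0, 0), c(0, 73.8, 0), c(0, -73.8, 0))
  r1 <- spect_resolution_report(
    spect_point_views(gen_point_volume(pos1, 4.2, 2.46, noiseless = TRUE),
                      pos1), "three_point_air")
  r2 <- spect_resolution_report(
    spect_point_views(gen_point_volume(pos2, 4.2, 2.46, noiseless = TRUE),
                      pos2), "three_point_air")
  expect_equal(r1$peripheral_radial_mm, r2$peripheral_radial_mm,
               tolerance = 1e-9)
  expect_equal(r1$peripheral_tangential_mm, r2$peripheral_tangential_mm,
               tolerance = 1e-9)
})

test_that("a central-only layout flags the missing peripheral entries", {
  pos <- rbind(c(0, 0, 0))
  vol <- gen_point_volume(pos, 4.2, 2.46, noiseless = TRUE)
  rep <- spect_resolution_report(spect_point_views(vol, pos),
                                 "three_point_air")
  expect_true("no_peripheral_sources" %in% rep$flags)
  expect_null(rep$peripheral_radial_mm)
})

test_that("recovery error shrinks monotonically with voxel refinement", {
  errs <- vapply(c(4.92, 2.46, 1.23), function(v) {
    vol <- gen_point_volume(rbind(c(0, 0, 0)), fwhm_mm = 12, voxel_mm = v,
                            noiseless = TRUE)
    vw <- spect_point_views(vol, rbind(c(0, 0, 0)))[[1]]
    est <- as.numeric(profile_width(spectqc:::view_marginal(vw$transverse,
                                                            1)))
    abs(est - 12)
  }, 0)
  expect_true(all(diff(errs) < 0))
})

test_that("triple-line analysis recovers per-line transverse widths", {
  lp <- rbind(c(0, 0), c(73.8, 0), c(-73.8, 0))
  fw <- rbind(c(4.1, 4.1), c(3.6, 3.7), c(3.6, 3.7))
  lv <- gen_line_volume(lp, fw, voxel_mm = 1.23, noiseless = TRUE)
  rep <- triple_line_resolution(lv, lp)
  expect_equal(rep$layout, "triple_line_scatter")
  expect_lt(abs(rep$central_mm - 4.1), 1.23^2 / (2 * 4.1) + 0.05)
  expect_lt(abs(rep$radial_mm - 3.6), 1.23^2 / (2 * 3.6) + 0.05)
  expect_lt(abs(rep$tangential_mm - 3.7), 1.23^2 / (2 * 3.7) + 0.05)
})
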