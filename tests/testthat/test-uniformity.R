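test_that("binning sums blocks, conserves totals, and scales the pitch", {
  img <- planar_image(matrix(1, 16, 112), c(2.46, 2.46))
  b <- bin_pixels(img, c(2, 4))
  expect_equal(dim(b$counts), c(8L, 28L))
  expect_true(all(b$counts == 8))
  expect_equal(sum(b$counts), sum(img$counts))
  expect_equal(b$pixel_pitch_mm, c(4.92, 9.84))

  expect_equal(bin_pixels(img, c(1, 1))$counts, img$counts)
  expect_error(bin_pixels(img, c(3, 4)), "not divisible")

  # conservation on a non-trivial image
  set.seed(1)
  img2 <- planar_image(matrix(rpois(16 * 112, 50), 16, 112), c(2.46, 2.46))
  expect_equal(sum(bin_pixels(img2, c(2, 4))$counts), sum(img2$counts))
})

test_that("nine-point smoothing: constant field unchanged, impulse responses", {
  const <- planar_image(matrix(3.5, 8, 28), c(4.92, 9.84))
  expect_equal(nema_smooth(const)$counts, const$counts)

  # interior impulse of 16 spreads as the kernel itself
  m <- matrix(0, 7, 7)
  m[4, 4] <- 16
  sm <- nema_smooth(planar_image(m, c(1, 1)))$counts
  expect_equal(sm[3:5, 3:5],
               matrix(c(1, 2, 1, 2, 4, 2, 1, 2, 1), 3, 3))

  # corner impulse of 9: per-pixel renormalization over in-bounds weights.
  # At (1,1) the in-bounds weights are 4,2,2,1 (sum 9) -> 9*4/9 = 4;
  # at (1,2) in-bounds weights sum to 12 and the impulse has weight 2
  # -> 9*2/12 = 1.5; at (2,2) the full kernel applies -> 9*1/16 = 0.5625.
  m2 <- matrix(0, 5, 5)
  m2[1, 1] <- 9
  sm2 <- nema_smooth(planar_image(m2, c(1, 1)))$counts
  expect_equal(sm2[1, 1], 4)
  expect_equal(sm2[1, 2], 9 * 2 / 12)
  expect_equal(sm2[2, 1], 9 * 2 / 12)
  expect_equal(sm2[2, 2], 9 * 1 / 16)

  expect_error(nema_smooth(planar_image(matrix(1, 2, 5), c(1, 1))),
               "at least 3 x 3")
})

test_that("smoothing conserves totals for interior-supported images", {
  m <- matrix(0, 10, 12)
  m[3:8, 3:10] <- matrix(runif(48, 50, 150), 6, 8)
  sm <- nema_smooth(planar_image(m, c(1, 1)))
  expect_equal(sum(sm$counts), sum(m), tolerance = 1e-12)
})

test_that("uniformity metrics: extrema formula and scale invariance", {
  m <- matrix(100, 8, 28)
  m[4, 10] <- 102
  m[4, 12] <- 98
  img <- planar_image(m, c(4.92, 9.84))
  u <- uniformity_metrics(img, "UFOV")
  expect_equal(u$integral_percent, 2.0)
  expect_equal(u$differential_percent, 2.0)  # both extrema in one window

  u2 <- uniformity_metrics(planar_image(m * 13, c(4.92, 9.84)), "UFOV")
  expect_equal(u2$integral_percent, u$integral_percent)
  expect_equal(u2$differential_percent, u$differential_percent)

  expect_error(uniformity_metrics(planar_image(matrix(0, 8, 28),
                                               c(4.92, 9.84)), "UFOV"),
               "all-zero")
})

test_that("DU never exceeds IU within the same field of view", {
  set.seed(42)
  for (i in 1:5) {
    m <- matrix(100 + rnorm(8 * 28, 0, 5), 8, 28)
    img <- planar_image(pmax(m, 1), c(4.92, 9.84))
    u <- uniformity_metrics(img, "UFOV")
    expect_lte(u$differential_percent, u$integral_percent + 1e-12)
  }
})

test_that("CFOV metrics <= UFOV metrics when extrema sit outside the CFOV", {
  m <- matrix(100, 8, 28)
  m[1, 1] <- 130   # corner extrema, outside the central 75%
  m[8, 28] <- 70
  img <- planar_image(m, c(4.92, 9.84))
  u_u <- uniformity_metrics(img, "UFOV")
  u_c <- uniformity_metrics(img, "CFOV")
  expect_lt(u_c$integral_percent, u_u$integral_percent)
  expect_lte(u_c$differential_percent, u_u$differential_percent)
})

test_that("defect report: clean flood, constructed L-cluster, invariances", {
  clean <- gen_flood(total_counts = 2e7, noiseless = TRUE)
  d0 <- defect_report(clean)
  expect_equal(d0$n_bad_pixels, 0L)
  expect_equal(d0$percent_good_pixels, 100)
  expect_equal(d0$max_cluster_size, 0L)

  # 3 dead pixels in an L-shaped 8-connected cluster
  gain <- matrix(1, 16, 112)
  mask <- matrix(FALSE, 16, 112)
  dead <- rbind(c(5, 10), c(6, 10), c(6, 11))
  gain[dead] <- 0
  mask[dead] <- TRUE
  img <- gen_flood(gain_map = gain, defect_mask = mask, total_counts = 2e7,
                   noiseless = TRUE)
  d <- defect_report(img)
  expect_equal(d$n_bad_pixels, 3L)
  expect_equal(d$max_cluster_size, 3L)
  expect_equal(d$percent_good_pixels, 100 * (1 - 3 / (16 * 112)))

  # exposure invariance: doubling all counts changes nothing
  img2 <- img
  img2$counts <- img$counts * 2
  d2 <- defect_report(img2)
  expect_equal(d2$n_bad_pixels, d$n_bad_pixels)
  expect_equal(d2$max_cluster_size, d$max_cluster_size)

  expect_error(defect_report(planar_image(matrix(0, 4, 4), c(1, 1))),
               "median")
})

test_that("cluster labelling agrees with a brute-force oracle", {
  set.seed(7)
  for (i in 1:10) {
    mask <- matrix(runif(12 * 15) < 0.15, 12, 15)
    labels <- spectqc:::label_clusters(mask)
    sizes <- sort(tabulate(labels[labels > 0]))
    expect_equal(sizes, sort(brute_cluster_sizes(mask)))
  }
})

test_that("super-pixels dominated by defects can be excluded from metrics", {
  m <- matrix(100, 8, 28)
  excl <- matrix(FALSE, 8, 28)
  m[3, 7] <- 5      # a near-dead super-pixel
  excl[3, 7] <- TRUE
  img <- planar_image(m, c(4.92, 9.84))
  with_defect <- uniformity_metrics(img, "UFOV")
  without <- uniformity_metrics(img, "UFOV", exclude = excl)
  expect_gt(with_defect$integral_percent, 50)
  expect_equal(without$integral_percent, 0)
})
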