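#' Bin detector pixels into super-pixels
#'
#' Sums counts over non-overlapping blocks, conserving total counts exactly,
#' and scales the pixel pitch by the binning factors. The default 2 x 4
#' binning turns 2.46 mm pixels into the 4.92 x 9.84 mm super-pixels used
#' for uniformity analysis.
#'
#' @param image a [planar_image()].
#' @param factor length-2 integer binning factors (transaxial, axial); grid
#'   dimensions must be divisible (no partial bins).
#' @return a binned [planar_image()].
#' @export
bin_pixels <- function(image, factor = c(2L, 4L)) {
  stopifnot(inherits(image, "planar_image"), length(factor) == 2,
            all(factor >= 1), all(factor == round(factor)))
  cnt <- image$counts
  if (nrow(cnt) %% factor[1] != 0 || ncol(cnt) %% factor[2] != 0) {
    stop("grid ", nrow(cnt), " x ", ncol(cnt),
         " not divisible by binning factors ", factor[1], " x ", factor[2])
  }
  nr <- nrow(cnt) %/% factor[1]
  nc <- ncol(cnt) %/% factor[2]
  out <- matrix(0, nr, nc)
  for (i in seq_len(factor[1])) {
    for (j in seq_len(factor[2])) {
      out <- out + cnt[seq(i, by = factor[1], length.out = nr),
                       seq(j, by = factor[2], length.out = nc)]
    }
  }
  planar_image(out, image$pixel_pitch_mm * factor, image$detector_id,
               image$duration_s)
}

#' Nine-point NEMA smoothing
#'
#' Convolution with the standard kernel rows (1,2,1), (2,4,2), (1,2,1)
#' normalized to unit sum. At edges the kernel is renormalized over its
#' in-bounds weights: no padding values are invented, and a constant image
#' is left exactly unchanged everywhere.
#'
#' @param image a [planar_image()], at least 3 x 3.
#' @return the smoothed [planar_image()].
#' @export
nema_smooth <- function(image) {
  stopifnot(inherits(image, "planar_image"))
  cnt <- image$counts
  nr <- nrow(cnt)
  nc <- ncol(cnt)
  if (nr < 3 || nc < 3) stop("image must be at least 3 x 3 super-pixels")
  w1 <- c(1, 2, 1)
  out <- matrix(0, nr, nc)
  for (i in seq_len(nr)) {
    di <- max(1, i - 1):min(nr, i + 1)
    wi <- w1[di - i + 2]
    for (j in seq_len(nc)) {
      dj <- max(1, j - 1):min(nc, j + 1)
      wj <- w1[dj - j + 2]
      w <- outer(wi, wj)
      out[i, j] <- sum(w * cnt[di, dj]) / sum(w)
    }
  }
  planar_image(out, image$pixel_pitch_mm, image$detector_id,
               image$duration_s)
}

# field-of-view mask: UFOV = full binned grid (pixelated column detector has
# no Anger-style edge artefacts); CFOV = central 75% of each linear
# dimension, rounded inward to whole super-pixels
fov_mask <- function(dim, fov = c("UFOV", "CFOV"), cfov_fraction = 0.75) {
  fov <- match.arg(fov)
  m <- matrix(TRUE, dim[1], dim[2])
  if (fov == "CFOV") {
    keep <- pmax(1L, floor(dim * cfov_fraction))
    start <- pmax(1L, floor((dim - keep) / 2) + 1L)
    m[] <- FALSE
    m[start[1]:(start[1] + keep[1] - 1L),
      start[2]:(start[2] + keep[2] - 1L)] <- TRUE
  }
  m
}

#' Integral and differential flood-field uniformity
#'
#' On a binned and smoothed flood image:
#' `IU = 100 * (max - min) / (max + min)` over the field-of-view mask, and
#' `DU` is the same statistic maximized over all 5-super-pixel 1-D sliding
#' windows (along rows and columns) lying fully inside the mask.
#'
#' @param image a binned, smoothed [planar_image()].
#' @param fov `"UFOV"` (full binned grid) or `"CFOV"` (central 75% of each
#'   linear dimension, rounded inward to whole super-pixels).
#' @param window differential-uniformity window length in super-pixels
#'   (NEMA standard 5).
#' @param exclude optional logical matrix of super-pixels to exclude (e.g.
#'   super-pixels dominated by defective raw pixels); excluded pixels drop
#'   out of IU and invalidate any DU window containing them.
#' @return list with `integral_percent` and `differential_percent`.
#' @export
uniformity_metrics <- function(image, fov = c("UFOV", "CFOV"), window = 5L,
                               exclude = NULL) {
  fov <- match.arg(fov)
  stopifnot(inherits(image, "planar_image"))
  cnt <- image$counts
  mask <- fov_mask(dim(cnt), fov)
  if (!is.null(exclude)) {
    stopifnot(all(dim(exclude) == dim(cnt)))
    mask <- mask & !exclude
  }
  if (!any(mask)) stop("field-of-view mask is empty")
  vals <- cnt[mask]
  if (max(vals) + min(vals) == 0) stop("uniformity undefined: all-zero mask")
  iu <- 100 * (max(vals) - min(vals)) / (max(vals) + min(vals))

  du <- 0
  win_du <- function(v) 100 * (max(v) - min(v)) / (max(v) + min(v))
  # vertical (along rows / transaxial) and horizontal (along columns) windows
  for (j in seq_len(ncol(cnt))) {
    col_ok <- mask[, j]
    for (i in seq_len(nrow(cnt) - window + 1L)) {
      sel <- i:(i + window - 1L)
      if (all(col_ok[sel])) du <- max(du, win_du(cnt[sel, j]))
    }
  }
  for (i in seq_len(nrow(cnt))) {
    row_ok <- mask[i, ]
    for (j in seq_len(ncol(cnt) - window + 1L)) {
      sel <- j:(j + window - 1L)
      if (all(row_ok[sel])) du <- max(du, win_du(cnt[i, sel]))
    }
  }
  list(integral_percent = iu, differential_percent = du)
}

#' Full uniformity analysis of one detector flood
#'
#' Convenience wrapper: bins, smooths, and computes IU/DU on both UFOV and
#' CFOV.
#'
#' @param image raw [planar_image()] flood.
#' @param factor binning factors passed to [bin_pixels()].
#' @return object of class `uniformity_result` with `$UFOV` and `$CFOV`
#'   metric lists.
#' @export
uniformity_analysis <- function(image, factor = c(2L, 4L)) {
  sm <- nema_smooth(bin_pixels(image, factor))
  structure(list(detector_id = image$detector_id,
                 UFOV = uniformity_metrics(sm, "UFOV"),
                 CFOV = uniformity_metrics(sm, "CFOV")),
            class = "uniformity_result")
}

#' @export
print.uniformity_result <- function(x, ...) {
  cat(sprintf("Uniformity [%s]: UFOV IU %.2f%% DU %.2f%%; CFOV IU %.2f%% DU %.2f%%\n",
              x$detector_id, x$UFOV$integral_percent,
              x$UFOV$differential_percent, x$CFOV$integral_percent,
              x$CFOV$differential_percent))
  invisible(x)
}

# 8-connected component labelling of a logical matrix; returns integer
# labels (0 = background). Small grids only; plain flood fill.
label_clusters <- function(mask) {
  nr <- nrow(mask)
  nc <- ncol(mask)
  labels <- matrix(0L, nr, nc)
  current <- 0L
  for (start in which(mask)) {
    if (labels[start] != 0L) next
    current <- current + 1L
    queue <- start
    labels[start] <- current
    while (length(queue)) {
      p <- queue[[1]]
      queue <- queue[-1]
      i <- (p - 1L) %% nr + 1L
      j <- (p - 1L) %/% nr + 1L
      for (di in -1:1) for (dj in -1:1) {
        ii <- i + di
        jj <- j + dj
        if (ii >= 1 && ii <= nr && jj >= 1 && jj <= nc &&
            mask[ii, jj] && labels[ii, jj] == 0L) {
          labels[ii, jj] <- current
          queue <- c(queue, (jj - 1L) * nr + ii)
        }
      }
    }
  }
  labels
}

#' Defective-pixel report on a raw flood
#'
#' A pixel is defective when its counts divided by the detector median fall
#' outside `[low_threshold, high_threshold]`. Clusters are 8-connected
#' components of defective pixels. Classification is exposure-invariant
#' (counts enter only as a ratio to the median).
#'
#' @param raw_image raw (unbinned) [planar_image()] flood, ideally with at
#'   least 100 counts/pixel for stable classification.
#' @param low_threshold,high_threshold acceptance band on counts/median
#'   (defaults 0.7 and 1.3; the manufacturer's criterion is undisclosed).
#' @return object of class `defect_report`: `n_bad_pixels`,
#'   `percent_good_pixels`, `max_cluster_size`, `bad_pixel_coordinates`
#'   (two-column matrix of row/col indices).
#' @export
defect_report <- function(raw_image, low_threshold = 0.7,
                          high_threshold = 1.3) {
  stopifnot(inherits(raw_image, "planar_image"),
            low_threshold < high_threshold)
  cnt <- raw_image$counts
  med <- stats::median(cnt)
  if (med == 0) stop("median counts is zero; flood too sparse to classify")
  ratio <- cnt / med
  bad <- ratio < low_threshold | ratio > high_threshold
  labels <- label_clusters(bad)
  max_cluster <- if (any(bad)) max(tabulate(labels[labels > 0L])) else 0L
  structure(list(
    detector_id = raw_image$detector_id,
    n_bad_pixels = sum(bad),
    percent_good_pixels = 100 * (1 - sum(bad) / length(bad)),
    max_cluster_size = max_cluster,
    bad_pixel_coordinates = which(bad, arr.ind = TRUE),
    thresholds = c(low = low_threshold, high = high_threshold)),
    class = "defect_report")
}

#' @export
print.defect_report <- function(x, ...) {
  cat(sprintf("Defects [%s]: %d bad pixel(s) (%.2f%% good), max cluster %d\n",
              x$detector_id, x$n_bad_pixels, x$percent_good_pixels,
              x$max_cluster_size))
  invisible(x)
}
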