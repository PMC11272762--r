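#' Simulate a flood-field acquisition on one detector column
#'
#' Expected per-pixel counts are proportional to a per-pixel gain map;
#' defective pixels are injected through the gain map itself (gain 0 for dead
#' pixels, an outlier multiplier for hot ones) and flagged in `defect_mask`.
#'
#' @param geometry a [detector_geometry()].
#' @param gain_map matrix of per-pixel gain multipliers
#'   (`pixels_transaxial` x `pixels_axial`); strictly positive except at
#'   defects. Default: uniform gain 1.
#' @param defect_mask logical matrix marking injected defects (bookkeeping
#'   only; the counts come from `gain_map`).
#' @param total_counts expected total counts for the column.
#' @param seed integer seed.
#' @param noiseless if TRUE, return expected counts (no Poisson noise).
#' @param detector_id label.
#' @return a [planar_image()] with a `ground_truth` attribute (gain map,
#'   defect mask, requested totals).
#' @export
gen_flood <- function(geometry = detector_geometry(), gain_map = NULL,
                      defect_mask = NULL, total_counts = 2e7, seed = NULL,
                      noiseless = FALSE, detector_id = "D01") {
  nx <- geometry$pixels_transaxial
  ny <- geometry$pixels_axial
  if (is.null(gain_map)) gain_map <- matrix(1, nx, ny)
  if (is.null(defect_mask)) defect_mask <- matrix(FALSE, nx, ny)
  gain_map <- as.matrix(gain_map)
  if (!all(dim(gain_map) == c(nx, ny))) {
    stop("gain_map is ", nrow(gain_map), " x ", ncol(gain_map),
         " but the geometry requires ", nx, " x ", ny)
  }
  stopifnot(all(dim(defect_mask) == c(nx, ny)), all(gain_map >= 0),
            total_counts > 0)
  if (any(gain_map[!defect_mask] <= 0)) {
    stop("gain_map must be strictly positive outside defective pixels")
  }

  expected <- gain_map / sum(gain_map) * total_counts
  counts <- if (noiseless) expected else
    with_seed(seed, matrix(stats::rpois(length(expected), expected), nx, ny))

  img <- planar_image(counts, rep(geometry$pixel_pitch_mm, 2), detector_id)
  attr(img, "ground_truth") <- list(
    gain_map = gain_map, defect_mask = defect_mask,
    n_defects = sum(defect_mask), total_counts = total_counts,
    seed = seed, noiseless = noiseless)
  img
}
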