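#' Detector geometry of a pixelated CZT column
#'
#' Describes one detector column of the ring system: a grid of square CZT
#' pixels, `pixels_transaxial` wide and `modules_axial * pixels_per_module_axial`
#' tall. The defaults give the 27.5 cm axial coverage of the reference system
#' (7 modules of 16 x 16 pixels at 2.46 mm pitch).
#'
#' @param pixel_pitch_mm pixel pitch in mm (square pixels).
#' @param pixels_transaxial number of pixels across the column.
#' @param modules_axial number of detector modules stacked axially.
#' @param pixels_per_module_axial axial pixels per module.
#' @param n_columns number of detector columns in the ring.
#' @return an object of class `detector_geometry`.
#' @export
detector_geometry <- function(pixel_pitch_mm = 2.46, pixels_transaxial = 16L,
                              modules_axial = 7L, pixels_per_module_axial = 16L,
                              n_columns = 12L) {
  stopifnot(pixel_pitch_mm > 0, pixels_transaxial >= 1, modules_axial >= 1,
            pixels_per_module_axial >= 1, n_columns >= 1)
  g <- list(pixel_pitch_mm = pixel_pitch_mm,
            pixels_transaxial = as.integer(pixels_transaxial),
            modules_axial = as.integer(modules_axial),
            pixels_per_module_axial = as.integer(pixels_per_module_axial),
            n_columns = as.integer(n_columns))
  g$pixels_axial <- g$modules_axial * g$pixels_per_module_axial
  g$axial_extent_mm <- g$pixels_axial * pixel_pitch_mm
  structure(g, class = "detector_geometry")
}

#' @export
print.detector_geometry <- function(x, ...) {
  cat(sprintf("Detector geometry: %d x %d pixels at %.2f mm (%d columns, axial extent %.2f mm)\n",
              x$pixels_transaxial, x$pixels_axial, x$pixel_pitch_mm,
              x$n_columns, x$axial_extent_mm))
  invisible(x)
}

#' Channelized energy spectrum
#'
#' @param counts non-negative counts per channel.
#' @param channel_keV uniform channel width in keV (0.5 in the low-energy
#'   front-end mode, 1.0 in the medium-energy mode).
#' @param e_min_keV energy at the lower edge of the first channel.
#' @param isotope isotope label.
#' @param detector_id detector column identifier.
#' @return an object of class `qc_spectrum`.
#' @export
qc_spectrum <- function(counts, channel_keV, e_min_keV = 40,
                        isotope = "Tc99m", detector_id = "D01") {
  stopifnot(is.numeric(counts), all(counts >= 0), channel_keV > 0)
  structure(list(counts = as.numeric(counts), channel_keV = channel_keV,
                 e_min_keV = e_min_keV, isotope = isotope,
                 detector_id = detector_id),
            class = "qc_spectrum")
}

# channel centres in keV
spectrum_energies <- function(s) {
  s$e_min_keV + (seq_along(s$counts) - 0.5) * s$channel_keV
}

#' @export
print.qc_spectrum <- function(x, ...) {
  cat(sprintf("Spectrum [%s, %s]: %d channels of %.1f keV, %.3g counts\n",
              x$isotope, x$detector_id, length(x$counts), x$channel_keV,
              sum(x$counts)))
  invisible(x)
}

#' Planar count image
#'
#' @param counts matrix of non-negative counts; rows index the transaxial
#'   direction, columns the axial direction.
#' @param pixel_pitch_mm length-2 pitch (transaxial, axial) in mm.
#' @param detector_id detector column identifier.
#' @param duration_s acquisition duration in seconds.
#' @return an object of class `planar_image`.
#' @export
planar_image <- function(counts, pixel_pitch_mm, detector_id = "D01",
                         duration_s = NA_real_) {
  counts <- as.matrix(counts)
  stopifnot(all(counts >= 0), length(pixel_pitch_mm) == 2,
            all(pixel_pitch_mm > 0))
  structure(list(counts = counts, pixel_pitch_mm = as.numeric(pixel_pitch_mm),
                 detector_id = detector_id, duration_s = duration_s),
            class = "planar_image")
}

#' @export
print.planar_image <- function(x, ...) {
  cat(sprintf("Planar image [%s]: %d x %d pixels at %.2f x %.2f mm, %.3g counts\n",
              x$detector_id, nrow(x$counts), ncol(x$counts),
              x$pixel_pitch_mm[1], x$pixel_pitch_mm[2], sum(x$counts)))
  invisible(x)
}

#' Timed count-rate series from a decaying source
#'
#' @param t_start_s start time of each measurement (s), strictly increasing.
#' @param dt_s elapsed time of each measurement (s), all positive.
#' @param counts total recorded counts per measurement.
#' @param background_cps background count rate measured without the source.
#' @param half_life_s isotope half-life (s).
#' @param isotope isotope label.
#' @return an object of class `count_rate_series`.
#' @export
count_rate_series <- function(t_start_s, dt_s, counts, background_cps = 0,
                              half_life_s = isotope_half_life("Tc99m"),
                              isotope = "Tc99m") {
  stopifnot(length(t_start_s) == length(dt_s),
            length(t_start_s) == length(counts),
            all(diff(t_start_s) > 0), all(dt_s > 0), all(counts >= 0),
            background_cps >= 0, half_life_s > 0)
  structure(list(t_start_s = as.numeric(t_start_s), dt_s = as.numeric(dt_s),
                 counts = as.numeric(counts), background_cps = background_cps,
                 half_life_s = half_life_s, tau_s = mean_life(half_life_s),
                 isotope = isotope),
            class = "count_rate_series")
}

#' @export
print.count_rate_series <- function(x, ...) {
  cat(sprintf("Count-rate series [%s]: %d points over %.0f s, background %.3g cps\n",
              x$isotope, length(x$counts),
              utils::tail(x$t_start_s + x$dt_s, 1) - x$t_start_s[1],
              x$background_cps))
  invisible(x)
}

#' Reconstructed 3-D count volume
#'
#' Axis convention: right-handed, axial = third array dimension (Z), all
#' lengths in mm, voxel centres at `(index - 0.5) * spacing` so the volume
#' origin sits at the corner of voxel (1, 1, 1). An optional world-space
#' `origin_mm` shifts voxel centres to `origin_mm + (index - 0.5) * spacing`,
#' letting phantoms be centred on the rotation axis.
#'
#' @param counts 3-D non-negative array.
#' @param voxel_mm length-3 voxel spacing (x, y, z) in mm.
#' @param origin_mm world coordinate of the corner of voxel (1,1,1).
#' @param annotations optional free-form ground-truth list.
#' @return an object of class `volume_image`.
#' @export
volume_image <- function(counts, voxel_mm, origin_mm = c(0, 0, 0),
                         annotations = NULL) {
  stopifnot(length(dim(counts)) == 3, all(counts >= 0))
  voxel_mm <- rep_len(as.numeric(voxel_mm), 3)
  stopifnot(all(voxel_mm > 0))
  structure(list(counts = counts, voxel_mm = voxel_mm,
                 origin_mm = as.numeric(origin_mm), annotations = annotations),
            class = "volume_image")
}

#' @export
print.volume_image <- function(x, ...) {
  d <- dim(x$counts)
  cat(sprintf("Volume image: %d x %d x %d voxels at %.2f x %.2f x %.2f mm\n",
              d[1], d[2], d[3], x$voxel_mm[1], x$voxel_mm[2], x$voxel_mm[3]))
  invisible(x)
}

# voxel-centre coordinates along one axis
voxel_centres <- function(vol, axis) {
  n <- dim(vol$counts)[axis]
  vol$origin_mm[axis] + (seq_len(n) - 0.5) * vol$voxel_mm[axis]
}
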