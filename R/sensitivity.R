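#' Planar-sensitivity measurement record
#'
#' One detector's static acquisition of a calibrated source at 150 mm.
#'
#' @param A_cal_MBq summed source activity at calibration time.
#' @param T_cal_s calibration timestamp, s (any common epoch).
#' @param T_150_s acquisition start timestamp, s (>= `T_cal_s`).
#' @param T_acq_150_s acquisition duration, s.
#' @param C_D150 total counts summed over the image.
#' @param half_life_s isotope half-life.
#' @param detector_id label.
#' @return an object of class `sensitivity_measurement`.
#' @export
sensitivity_measurement <- function(A_cal_MBq, T_cal_s, T_150_s, T_acq_150_s,
                                    C_D150,
                                    half_life_s = isotope_half_life("Tc99m"),
                                    detector_id = "D01") {
  stopifnot(A_cal_MBq > 0, T_150_s >= T_cal_s, T_acq_150_s > 0, C_D150 >= 0,
            half_life_s > 0)
  structure(list(A_cal_MBq = A_cal_MBq, T_cal_s = T_cal_s, T_150_s = T_150_s,
                 T_acq_150_s = T_acq_150_s, C_D150 = C_D150,
                 half_life_s = half_life_s, detector_id = detector_id),
            class = "sensitivity_measurement")
}

#' Decay-corrected count rate of a sensitivity acquisition
#'
#' `R = (C / tau) * exp((T_150 - T_cal) / tau) / (1 - exp(-T_acq / tau))`
#' with `tau = T_half / ln 2`: the exponential undoes the decay from
#' calibration to acquisition start, and the last factor the decay during
#' the acquisition. In the no-decay limit this is `C / T_acq`.
#'
#' @param m a [sensitivity_measurement()].
#' @return decay-corrected count rate at calibration time, cps.
#' @export
decay_corrected_rate <- function(m) {
  stopifnot(inherits(m, "sensitivity_measurement"))
  tau <- mean_life(m$half_life_s)
  (m$C_D150 / tau) * exp((m$T_150_s - m$T_cal_s) / tau) /
    -expm1(-m$T_acq_150_s / tau)
}

#' System planar sensitivity
#'
#' Per-detector sensitivity `S = R_D150 / A_cal` (cps/MBq) with the fleet
#' average and (min-max) range.
#'
#' @param measurements list of [sensitivity_measurement()] objects sharing
#'   one calibrated source.
#' @return object of class `planar_sensitivity_result`: per-detector table,
#'   `average_cps_per_MBq`, `range_cps_per_MBq`.
#' @export
planar_sensitivity <- function(measurements) {
  if (inherits(measurements, "sensitivity_measurement")) {
    measurements <- list(measurements)
  }
  stopifnot(length(measurements) >= 1)
  A <- vapply(measurements, `[[`, 0, "A_cal_MBq")
  if (any(A <= 0)) stop("calibrated activity must be positive")
  if (length(unique(A)) > 1) {
    stop("measurements do not share a common calibrated activity")
  }
  S <- vapply(measurements, function(m) decay_corrected_rate(m) / m$A_cal_MBq,
              0)
  per_detector <- data.frame(
    detector_id = vapply(measurements, `[[`, "", "detector_id"),
    sensitivity_cps_per_MBq = S, stringsAsFactors = FALSE)
  structure(list(per_detector = per_detector,
                 average_cps_per_MBq = mean(S),
                 range_cps_per_MBq = range(S)),
            class = "planar_sensitivity_result")
}

#' @export
print.planar_sensitivity_result <- function(x, ...) {
  cat(sprintf("Planar sensitivity: %.1f cps/MBq (%.1f-%.1f) over %d detector(s)\n",
              x$average_cps_per_MBq, x$range_cps_per_MBq[1],
              x$range_cps_per_MBq[2], nrow(x$per_detector)))
  invisible(x)
}

#' Volume sensitivity and detector-detector variation
#'
#' From the twelve per-detector summed images of a uniform cylinder:
#' `A = sum(counts) / duration` (average cps), `B_c` the activity
#' concentration decay-corrected to the time halfway through the
#' acquisition, `SVS = A / B_c`, `VSAC = SVS / length`, and
#' `DDS = 100 * (c_max - c_min) / c_max`.
#'
#' @param per_detector_counts per-detector total counts (n >= 2).
#' @param duration_s acquisition duration, s.
#' @param activity_conc_at_cal_MBq_per_cc concentration at calibration.
#' @param T_cal_s,T_mid_s calibration time and acquisition midpoint, s; the
#'   decay correction is `2^(-(T_mid - T_cal) / half_life)`.
#' @param half_life_s isotope half-life.
#' @param length_cm axial length of the cylinder, cm (a required
#'   configuration value; 20 cm for the standard phantom).
#' @return object of class `volume_sensitivity_result` with
#'   `SVS_cps_cc_per_MBq`, `VSAC_cps_cc_per_MBq_cm`, `DDS_percent`,
#'   `A_cps`, `B_c_MBq_per_cc`, `per_detector_counts`.
#' @export
volume_sensitivity <- function(per_detector_counts, duration_s,
                               activity_conc_at_cal_MBq_per_cc,
                               T_cal_s = 0, T_mid_s = 0,
                               half_life_s = isotope_half_life("Tc99m"),
                               length_cm = 20) {
  stopifnot(length(per_detector_counts) >= 2, duration_s > 0,
            activity_conc_at_cal_MBq_per_cc > 0, length_cm > 0,
            T_mid_s >= T_cal_s)
  c_max <- max(per_detector_counts)
  c_min <- min(per_detector_counts)
  if (c_max == 0) stop("DDS undefined: all detector totals are zero")

  A <- sum(per_detector_counts) / duration_s
  B_c <- activity_conc_at_cal_MBq_per_cc *
    2^(-(T_mid_s - T_cal_s) / half_life_s)
  svs <- A / B_c
  structure(list(SVS_cps_cc_per_MBq = svs,
                 VSAC_cps_cc_per_MBq_cm = svs / length_cm,
                 DDS_percent = 100 * (c_max - c_min) / c_max,
                 A_cps = A, B_c_MBq_per_cc = B_c, length_cm = length_cm,
                 per_detector_counts = per_detector_counts),
            class = "volume_sensitivity_result")
}

#' @export
print.volume_sensitivity_result <- function(x, ...) {
  cat(sprintf("Volume sensitivity: SVS %.1f cps cc/MBq (%.1f kcps/MBq/cc), VSAC %.2f kcps/MBq/cm, DDS %.1f%%\n",
              x$SVS_cps_cc_per_MBq, x$SVS_cps_cc_per_MBq / 1000,
              x$VSAC_cps_cc_per_MBq_cm / 1000, x$DDS_percent))
  invisible(x)
}
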