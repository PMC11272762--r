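#' Simulate per-detector summed counts from a uniform cylinder acquisition
#'
#' Each detector column's total counts are proportional to its sensitivity
#' factor, the activity concentration, the phantom volume and the acquisition
#' duration. Used for volume sensitivity (SVS/VSAC) and detector-detector
#' variation (DDS) recovery.
#'
#' @param n_detectors number of detector columns.
#' @param sensitivity_factors per-detector relative sensitivities in (0, 1].
#' @param activity_conc_MBq_per_cc activity concentration at acquisition
#'   midpoint.
#' @param cylinder list with `diameter_mm` (200 standard) and
#'   `length_mm` (200 standard).
#' @param duration_s acquisition duration.
#' @param cps_per_MBq nominal detector sensitivity at factor 1 (cps per MBq
#'   of in-field activity).
#' @param counts_at_reference optional: expected counts for a factor-1.0
#'   detector, overriding the physical scaling (convenient for recovery
#'   studies at a stated count level).
#' @param seed integer seed.
#' @param noiseless if TRUE, expected counts without Poisson noise.
#' @return list with `detector_counts` (numeric vector), `duration_s`,
#'   `cylinder`, and a `ground_truth` attribute (factors, expected counts,
#'   true DDS and SVS).
#' @export
gen_cylinder_projections <- function(n_detectors = 12L,
                                     sensitivity_factors = rep(1, n_detectors),
                                     activity_conc_MBq_per_cc = 0.02,
                                     cylinder = list(diameter_mm = 200,
                                                     length_mm = 200),
                                     duration_s = 900,
                                     cps_per_MBq = 8,
                                     counts_at_reference = NULL,
                                     seed = NULL, noiseless = FALSE) {
  stopifnot(length(sensitivity_factors) == n_detectors,
            all(sensitivity_factors > 0), all(sensitivity_factors <= 1))
  if (duration_s <= 0) stop("duration_s must be positive")
  stopifnot(activity_conc_MBq_per_cc > 0)

  volume_cc <- pi * (cylinder$diameter_mm / 20)^2 * (cylinder$length_mm / 10)
  activity_MBq <- activity_conc_MBq_per_cc * volume_cc
  ref_counts <- if (is.null(counts_at_reference)) {
    cps_per_MBq * activity_MBq * duration_s
  } else {
    counts_at_reference
  }
  expected <- sensitivity_factors * ref_counts
  counts <- if (noiseless) expected else
    with_seed(seed, stats::rpois(n_detectors, expected))

  out <- list(detector_counts = as.numeric(counts), duration_s = duration_s,
              cylinder = cylinder,
              activity_conc_MBq_per_cc = activity_conc_MBq_per_cc)
  attr(out, "ground_truth") <- list(
    sensitivity_factors = sensitivity_factors, expected_counts = expected,
    true_dds_percent = 100 * (max(sensitivity_factors) -
                              min(sensitivity_factors)) /
                              max(sensitivity_factors),
    true_svs_cps_cc_per_MBq = sum(expected) / duration_s /
                              activity_conc_MBq_per_cc,
    volume_cc = volume_cc, seed = seed, noiseless = noiseless)
  out
}

#' Simulate planar-sensitivity acquisitions for a detector fleet
#'
#' Each detector counts a point-like source of calibrated activity; recorded
#' counts integrate the decaying true rate
#' `S * A_cal * exp(-(t - T_cal)/tau)` over the acquisition window.
#'
#' @param true_cps_per_MBq per-detector true sensitivities (recycled to
#'   `n_detectors`).
#' @param n_detectors fleet size.
#' @param A_cal_MBq calibrated activity at `T_cal`.
#' @param delay_s delay from calibration to acquisition start
#'   (`T_150 - T_cal`).
#' @param target_counts expected counts per detector; sets the acquisition
#'   duration.
#' @param half_life_s isotope half-life.
#' @param seed integer seed.
#' @param noiseless if TRUE, expected counts without Poisson noise.
#' @return list of `sensitivity_measurement` objects (one per detector) with
#'   a `ground_truth` attribute.
#' @export
gen_sensitivity_measurements <- function(true_cps_per_MBq = 97.1,
                                         n_detectors = 12L, A_cal_MBq = 74,
                                         delay_s = 1800, target_counts = 4e7,
                                         half_life_s = isotope_half_life("Tc99m"),
                                         seed = NULL, noiseless = FALSE) {
  stopifnot(A_cal_MBq > 0, delay_s >= 0, target_counts > 0)
  S <- rep_len(true_cps_per_MBq, n_detectors)
  tau <- mean_life(half_life_s)
  rate0 <- S * A_cal_MBq * exp(-delay_s / tau)  # true rate at T_150
  # duration solving expected counts = rate0 * tau * (1 - exp(-T/tau))
  T_acq <- -tau * log(1 - target_counts / (rate0 * tau))
  expected <- rate0 * tau * (1 - exp(-T_acq / tau))
  counts <- if (noiseless) expected else
    with_seed(seed, stats::rpois(n_detectors, expected))

  ms <- lapply(seq_len(n_detectors), function(d) {
    sensitivity_measurement(
      A_cal_MBq = A_cal_MBq, T_cal_s = 0, T_150_s = delay_s,
      T_acq_150_s = T_acq[d], C_D150 = counts[d],
      half_life_s = half_life_s,
      detector_id = sprintf("D%02d", d))
  })
  attr(ms, "ground_truth") <- list(
    true_cps_per_MBq = S, expected_counts = expected,
    seed = seed, noiseless = noiseless)
  ms
}
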