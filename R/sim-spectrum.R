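#' Simulate a photopeak energy spectrum
#'
#' Generates a channelized spectrum consisting of a Gaussian photopeak of
#' known fractional FWHM on a flat background, with Poisson counting noise.
#' The peak model is Gaussian + flat background only: the NEMA FWHM estimator
#' operates in a window around the peak, so the Compton continuum is not
#' modelled.
#'
#' @param peak_keV photopeak energy, within the 40-279 keV acquisition range.
#' @param fwhm_fraction true fractional FWHM (FWHM / peak energy), in (0, 1).
#' @param total_counts expected total counts in the spectrum.
#' @param channel_keV channel width: 0.5 (low-energy mode) or 1.0 keV
#'   (medium-energy mode) by default, any positive width accepted.
#' @param background_fraction fraction of total counts in the flat background.
#' @param seed integer seed; ignored when `noiseless = TRUE`.
#' @param noiseless if TRUE, return expected counts with no Poisson sampling.
#' @param e_min_keV,e_max_keV energy range of the front end.
#' @param isotope,detector_id labels carried on the spectrum.
#' @return a [qc_spectrum()] with a `ground_truth` attribute recording the
#'   generating parameters.
#' @export
gen_spectrum <- function(peak_keV, fwhm_fraction, total_counts,
                         channel_keV = 0.5, background_fraction = 0.02,
                         seed = NULL, noiseless = FALSE,
                         e_min_keV = 40, e_max_keV = 279,
                         isotope = "Tc99m", detector_id = "D01") {
  if (peak_keV < e_min_keV || peak_keV > e_max_keV) {
    stop("peak_keV = ", peak_keV, " outside the [", e_min_keV, ", ",
         e_max_keV, "] keV energy range")
  }
  if (total_counts <= 0) stop("total_counts must be positive")
  stopifnot(fwhm_fraction > 0, fwhm_fraction < 1,
            background_fraction >= 0, background_fraction < 1)

  n_chan <- floor((e_max_keV - e_min_keV) / channel_keV)
  lo <- e_min_keV + (seq_len(n_chan) - 1) * channel_keV
  hi <- lo + channel_keV
  sigma <- fwhm_fraction * peak_keV / FWHM_PER_SIGMA

  peak_mass <- gauss_bin_mass(lo, hi, peak_keV, sigma)
  # renormalize over the recorded range so the expected total is exact
  peak_mass <- peak_mass / sum(peak_mass)
  expected <- total_counts * ((1 - background_fraction) * peak_mass +
                              background_fraction / n_chan)
  counts <- if (noiseless) expected else
    with_seed(seed, stats::rpois(n_chan, expected))

  s <- qc_spectrum(counts, channel_keV, e_min_keV, isotope, detector_id)
  attr(s, "ground_truth") <- list(
    peak_keV = peak_keV, fwhm_fraction = fwhm_fraction,
    fwhm_keV = fwhm_fraction * peak_keV, sigma_keV = sigma,
    total_counts = total_counts, background_fraction = background_fraction,
    channel_keV = channel_keV, seed = seed, noiseless = noiseless)
  s
}
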