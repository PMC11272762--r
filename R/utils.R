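#' @keywords internal
"_PACKAGE"

# Mean lifetime tau = T_half / ln 2; every decay correction goes through this.
mean_life <- function(half_life_s) {
  stopifnot(is.numeric(half_life_s), half_life_s > 0)
  half_life_s / log(2)
}

#' Isotope half-lives
#'
#' Physical half-lives (seconds) for the isotopes used in the QC tests.
#'
#' @param isotope one of `"Tc99m"`, `"I123"`, `"Co57"`.
#' @return half-life in seconds.
#' @export
isotope_half_life <- function(isotope) {
  tab <- c(Tc99m = 6.0067 * 3600, I123 = 13.2235 * 3600, Co57 = 271.74 * 86400)
  if (!isotope %in% names(tab)) {
    stop("unknown isotope: ", isotope, " (expected one of ",
         paste(names(tab), collapse = ", "), ")")
  }
  unname(tab[[isotope]])
}

# Run code under a given integer seed without disturbing the caller's RNG
# stream. All generators route their randomness through this; no global state
# escapes.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    stopifnot(length(seed) == 1L, is.finite(seed), seed == round(seed))
    old <- get0(".Random.seed", envir = globalenv(), inherits = FALSE)
    on.exit({
      if (is.null(old)) {
        rm(".Random.seed", envir = globalenv())
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(as.integer(seed))
  }
  force(code)
}

# FWHM of a Gaussian = 2*sqrt(2*ln 2) * sigma
FWHM_PER_SIGMA <- 2 * sqrt(2 * log(2))

# Probability mass of N(mu, sigma) in each [lo, hi) channel.
gauss_bin_mass <- function(lo, hi, mu, sigma) {
  stats::pnorm(hi, mu, sigma) - stats::pnorm(lo, mu, sigma)
}
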