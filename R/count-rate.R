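# Count-rate performance by the decay-source method. Three steps per
# measurement i: background-corrected net counts, decay-compensated observed
# rate, and the input rate extrapolated from a loss-free reference point n:
#   C_i   = K_i - R_bkg * dt_i
#   OCR_i = C_i / (tau * (1 - exp(-dt_i / tau)))
#   ICR_i = OCR_n * exp((t_n - t_i) / tau)
# with tau the mean lifetime, tau = T_half / ln 2.

#' Background-corrected net counts
#'
#' @param K_i recorded counts of the measurement.
#' @param dt_i elapsed time of the measurement, s.
#' @param R_bkg background count rate, cps.
#' @return net counts; negative values are clipped to 0 and flagged via the
#'   `clipped` attribute.
#' @export
net_counts <- function(K_i, dt_i, R_bkg) {
  stopifnot(all(K_i >= 0), all(dt_i > 0), R_bkg >= 0)
  C <- K_i - R_bkg * dt_i
  # a measurement fully consumed by background is flagged, not just the
  # strictly negative ones
  clipped <- C <= 0 & R_bkg > 0
  C[C < 0] <- 0
  structure(C, clipped = clipped)
}

#' Decay-compensated observed count rate
#'
#' Corrects the net counts for the physical decay of the source during the
#' measurement: `OCR = C / (tau * (1 - exp(-dt / tau)))`. As `dt / tau -> 0`
#' this reduces to `C / dt`.
#'
#' @param C_i net counts.
#' @param dt_i elapsed time, s.
#' @param tau_s mean lifetime, s.
#' @return observed count rate, cps.
#' @export
observed_rate <- function(C_i, dt_i, tau_s) {
  stopifnot(all(dt_i > 0), tau_s > 0)
  # -expm1(-x) = 1 - exp(-x) without cancellation for dt << tau
  C_i / (tau_s * -expm1(-dt_i / tau_s))
}

#' Input count rate extrapolated from a loss-free reference
#'
#' `ICR_i = OCR_n * exp((t_n - t_i) / tau)`: the observed rate of the
#' reference measurement (taken where dead-time losses are negligible)
#' extrapolated back in time along the physical decay of the source.
#'
#' @param OCR_n observed rate of the reference measurement, cps.
#' @param t_n start time of the reference measurement, s.
#' @param t_i start time(s) of the measurement(s) of interest, s.
#' @param tau_s mean lifetime, s.
#' @return input count rate(s), cps.
#' @export
input_rate <- function(OCR_n, t_n, t_i, tau_s) {
  stopifnot(tau_s > 0)
  OCR_n * exp((t_n - t_i) / tau_s)
}

#' Observed-vs-input count-rate curve with NEMA readouts
#'
#' Applies the three-step pipeline to all measurements, selects the
#' reference point as the latest (lowest-rate) measurement whose observed
#' rate is below `reference_max_cps` (falling back, flagged, to the last
#' point), and reads off the maximum observed rate and the input rate at 20%
#' loss. The 20%-loss point is found by linear interpolation of the OCR/ICR
#' ratio against log(ICR) between the two bracketing measurements; with
#' multiple crossings the highest-ICR crossing is used. Points with
#' OCR > ICR (possible under noise) are retained in the curve but excluded
#' from the crossing search.
#'
#' @param series a [count_rate_series()].
#' @param loss_fraction loss level defining the headline input rate
#'   (default 0.2, i.e. the OCR = 0.8 x ICR crossing).
#' @param reference_max_cps observed-rate ceiling for the loss-free
#'   reference point (default 1e4 cps).
#' @return an object of class `rate_curve`: per-point data.frame `points`
#'   (`t_start_s`, `icr_cps`, `ocr_cps`, `ratio`), `reference_index`,
#'   `max_ocr_cps`, `icr_at_loss_cps`, `flags`.
#' @export
rate_curve <- function(series, loss_fraction = 0.2,
                       reference_max_cps = 1e4) {
  stopifnot(inherits(series, "count_rate_series"),
            loss_fraction > 0, loss_fraction < 1)
  if (length(series$counts) < 5) {
    stop("need at least 5 measurements spanning saturated to low-loss rates")
  }
  tau <- series$tau_s
  C <- net_counts(series$counts, series$dt_s, series$background_cps)
  ocr <- observed_rate(as.numeric(C), series$dt_s, tau)

  flags <- character()
  low <- which(ocr < reference_max_cps)
  if (length(low)) {
    n_ref <- max(low)
  } else {
    n_ref <- length(ocr)
    flags <- c(flags, "reference_not_loss_free")
  }
  icr <- input_rate(ocr[n_ref], series$t_start_s[n_ref], series$t_start_s,
                    tau)

  ratio <- ocr / icr
  pts <- data.frame(t_start_s = series$t_start_s, icr_cps = icr,
                    ocr_cps = ocr, ratio = ratio)

  max_ocr <- max(ocr)
  if (which.max(ocr) == 1) flags <- c(flags, "max_censored")

  target <- 1 - loss_fraction
  ok <- ratio <= 1  # exclude unphysical OCR > ICR noise points
  ord <- order(icr[ok], decreasing = TRUE)
  r <- ratio[ok][ord]
  li <- log(icr[ok][ord])
  icr_at_loss <- NA_real_
  for (j in seq_len(length(r) - 1)) {
    if ((r[j] - target) * (r[j + 1] - target) <= 0 && r[j] != r[j + 1]) {
      f <- (target - r[j]) / (r[j + 1] - r[j])
      icr_at_loss <- exp(li[j] + f * (li[j + 1] - li[j]))
      break  # highest-ICR crossing
    }
  }
  if (is.na(icr_at_loss)) {
    stop("OCR/ICR ratio never crosses ", target,
         ": the ", 100 * loss_fraction, "% loss point is undefined")
  }

  structure(list(points = pts, reference_index = n_ref,
                 max_ocr_cps = max_ocr, icr_at_loss_cps = icr_at_loss,
                 loss_fraction = loss_fraction, flags = flags),
            class = "rate_curve")
}

#' @export
print.rate_curve <- function(x, ...) {
  cat(sprintf("Rate curve: %d points; max OCR %.1f kcps; ICR at %.0f%% loss %.1f kcps\n",
              nrow(x$points), x$max_ocr_cps / 1000, 100 * x$loss_fraction,
              x$icr_at_loss_cps / 1000))
  if (length(x$flags)) cat("  flags:", paste(x$flags, collapse = ", "), "\n")
  invisible(x)
}

#' @export
plot.rate_curve <- function(x, ...) {
  icr <- x$points$icr_cps / 1000
  ocr <- x$points$ocr_cps / 1000
  plot(icr, ocr, log = "x", xlab = "ICR (kcps)", ylab = "OCR (kcps)",
       type = "b", pch = 16, ...)
  graphics::lines(sort(icr), sort(icr), col = "grey")
  graphics::lines(sort(icr), (1 - x$loss_fraction) * sort(icr), lty = 2)
  graphics::abline(h = x$max_ocr_cps / 1000, col = "red")
  invisible(x)
}
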