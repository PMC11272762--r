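#' Acquisition schedule for the decay-source method
#'
#' Builds the measurement schedule used for count-rate performance: the first
#' acquisition lasts `dt0_s` (10 s), and subsequent durations grow as
#' `dt0_s * 2^(elapsed / half_life)` so the expected counts per measurement
#' stay roughly constant as the source decays, capped at `dt_max_s`. Start
#' times are spaced so the true input rate falls by a constant factor
#' (`rate_step`) between consecutive points, spanning the full rate range
#' from saturation down to the loss-free regime.
#'
#' @param half_life_s source half-life (s).
#' @param rate_span total factor by which the input rate decays over the
#'   schedule (default 4000: e.g. 3 Mcps down to below 1 kcps).
#' @param rate_step input-rate ratio between consecutive measurements
#'   (default 1.25, i.e. about 3.1 points per halving).
#' @param dt0_s duration of the first measurement (s).
#' @param dt_max_s duration cap (s).
#' @return data.frame with columns `t_start_s`, `dt_s`.
#' @export
decay_schedule <- function(half_life_s, rate_span = 4000, rate_step = 1.25,
                           dt0_s = 10, dt_max_s = 600) {
  stopifnot(half_life_s > 0, rate_span > 1, rate_step > 1, dt0_s > 0)
  n <- ceiling(log(rate_span) / log(rate_step)) + 1L
  t_start <- (seq_len(n) - 1L) * half_life_s * log2(rate_step)
  dt <- pmin(dt_max_s, dt0_s * 2^(t_start / half_life_s))
  # guard: durations must not overlap the next start (they never do for
  # rate_step > 1 with the cap, but keep the invariant explicit)
  stopifnot(all(t_start + dt <= c(t_start[-1], Inf)))
  data.frame(t_start_s = t_start, dt_s = dt)
}

#' Simulate a decay-source count-rate series
#'
#' The true input rate at time t is
#' `cps_per_MBq * A0 * 2^(-t / half_life)`; each measurement integrates the
#' detector response to that rate, plus background, over its interval.
#' Integration is closed-form for the identity response and adaptive
#' quadrature (relative tolerance 1e-8) for nonlinear responses.
#'
#' @param initial_activity_MBq source activity at t = 0.
#' @param half_life_s isotope half-life (s).
#' @param response a [response_model()].
#' @param cps_per_MBq detector sensitivity (true cps per MBq).
#' @param background_cps background count rate.
#' @param schedule data.frame with `t_start_s`, `dt_s` (see
#'   [decay_schedule()]); must be strictly increasing and non-overlapping.
#' @param seed integer seed.
#' @param noiseless if TRUE, record expected counts without Poisson noise.
#' @param isotope label.
#' @return a [count_rate_series()] with a `ground_truth` attribute holding
#'   the response model and the true (ICR, OCR) at each measurement midpoint.
#' @export
gen_decay_series <- function(initial_activity_MBq, half_life_s, response,
                             cps_per_MBq, background_cps = 0,
                             schedule = decay_schedule(half_life_s),
                             seed = NULL, noiseless = FALSE,
                             isotope = "Tc99m") {
  if (initial_activity_MBq < 0 || cps_per_MBq < 0 || background_cps < 0) {
    stop("activities and rates must be non-negative")
  }
  stopifnot(half_life_s > 0, inherits(response, "response_model"),
            all(diff(schedule$t_start_s) > 0), all(schedule$dt_s > 0))
  ends <- schedule$t_start_s + schedule$dt_s
  if (any(ends[-nrow(schedule)] > schedule$t_start_s[-1])) {
    stop("schedule measurements overlap")
  }

  r0 <- cps_per_MBq * initial_activity_MBq
  icr_at <- function(t) r0 * 2^(-t / half_life_s)
  tau <- mean_life(half_life_s)

  expected <- mapply(function(t0, dt) {
    if (response$model_kind == "identity") {
      # closed form: integral of r0*exp(-t/tau) over [t0, t0+dt]
      src <- r0 * tau * (exp(-t0 / tau) - exp(-(t0 + dt) / tau))
    } else {
      src <- stats::integrate(function(t) response_eval(response, icr_at(t)),
                              t0, t0 + dt, rel.tol = 1e-8,
                              subdivisions = 500L)$value
    }
    src + background_cps * dt
  }, schedule$t_start_s, schedule$dt_s)

  counts <- if (noiseless) expected else
    with_seed(seed, stats::rpois(length(expected), expected))

  s <- count_rate_series(schedule$t_start_s, schedule$dt_s, counts,
                         background_cps, half_life_s, isotope)
  t_mid <- schedule$t_start_s + schedule$dt_s / 2
  true_icr <- icr_at(t_mid)
  attr(s, "ground_truth") <- list(
    response = response, initial_activity_MBq = initial_activity_MBq,
    cps_per_MBq = cps_per_MBq, true_icr_cps = true_icr,
    true_ocr_cps = response_eval(response, true_icr),
    seed = seed, noiseless = noiseless)
  s
}
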