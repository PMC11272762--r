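#' Detector count-rate response models
#'
#' A response model maps the true input count rate (ICR, cps) to the observed
#' count rate (OCR, cps). All models satisfy OCR(0) = 0 and OCR(x) <= x.
#'
#' * `saturating_exponential`: `min(x, ocr_max * (1 - exp(-x / k)))`. The
#'   clamp keeps the detector lossless at low rates (so a loss-free reference
#'   point exists) while the exponential plateau reproduces the constant
#'   response digital CZT systems show once the maximum rate is reached.
#' * `nonparalyzable`: `x / (1 + x * dead_time_s)`.
#' * `paralyzable`: `x * exp(-x * dead_time_s)`.
#' * `clamped_linear`: `min(x, ocr_max)`.
#' * `identity`: lossless detector, `OCR = ICR`.
#'
#' @param model_kind one of the model names above.
#' @param ... model parameters: `ocr_max`, `k` (cps) or `dead_time_s` (s).
#' @return an object of class `response_model`; call it on rates with
#'   [response_eval()].
#' @export
response_model <- function(model_kind = c("identity", "saturating_exponential",
                                          "nonparalyzable", "paralyzable",
                                          "clamped_linear"), ...) {
  model_kind <- match.arg(model_kind)
  pars <- list(...)
  need <- switch(model_kind,
    identity = character(),
    saturating_exponential = c("ocr_max", "k"),
    nonparalyzable = "dead_time_s",
    paralyzable = "dead_time_s",
    clamped_linear = "ocr_max")
  missing <- setdiff(need, names(pars))
  if (length(missing)) {
    stop("response_model '", model_kind, "' needs parameter(s): ",
         paste(missing, collapse = ", "))
  }
  for (p in need) stopifnot(pars[[p]] > 0)
  structure(list(model_kind = model_kind, parameters = pars[need]),
            class = "response_model")
}

#' Evaluate a response model
#'
#' @param model a [response_model()].
#' @param icr_cps input count rate(s), cps, non-negative.
#' @return observed count rate(s), cps.
#' @export
response_eval <- function(model, icr_cps) {
  stopifnot(inherits(model, "response_model"), all(icr_cps >= 0))
  p <- model$parameters
  switch(model$model_kind,
    identity = icr_cps,
    saturating_exponential =
      pmin(icr_cps, p$ocr_max * (1 - exp(-icr_cps / p$k))),
    nonparalyzable = icr_cps / (1 + icr_cps * p$dead_time_s),
    paralyzable = icr_cps * exp(-icr_cps * p$dead_time_s),
    clamped_linear = pmin(icr_cps, p$ocr_max))
}

#' @export
print.response_model <- function(x, ...) {
  cat("Response model:", x$model_kind)
  if (length(x$parameters)) {
    cat(" (", paste(names(x$parameters), unlist(x$parameters),
                    sep = " = ", collapse = ", "), ")", sep = "")
  }
  cat("\n")
  invisible(x)
}

#' Solve the shape constant of the saturating-exponential response
#'
#' Given a plateau `ocr_max` and one anchor point where the observed rate is a
#' stated fraction of the input rate, solve
#' `ocr_max * (1 - exp(-icr / k)) = frac * icr` for `k`.
#'
#' @param ocr_max plateau observed rate, cps.
#' @param icr_at_frac anchor input rate, cps.
#' @param frac observed/input ratio at the anchor (default 0.8, the 20%-loss
#'   condition).
#' @return shape constant `k` in cps.
#' @export
solve_saturating_k <- function(ocr_max, icr_at_frac, frac = 0.8) {
  stopifnot(ocr_max > 0, icr_at_frac > 0, frac > 0,
            frac * icr_at_frac < ocr_max)
  -icr_at_frac / log(1 - frac * icr_at_frac / ocr_max)
}
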