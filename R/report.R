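#' Daily-QC tolerance set
#'
#' Named pass/fail limits with comparator and units. Defaults mirror the
#' manufacturer's daily-QC tolerances for the reference system:
#' differential uniformity < 3.6%, integral uniformity < 4.5%, energy
#' resolution < 7.5%, peak position in 120.6-123.6 keV (Co-57 source), good
#' pixels in 93.8-100%, maximum cluster size < 8. Limits are configuration,
#' not code: pass a YAML file or a named list to override.
#'
#' @param overrides named list (or path to a YAML file) of limits; each
#'   entry is `list(comparator, limit, units)` with comparator one of
#'   `"<"`, `"<="`, `">"`, `">="`, `"range"` (limit of length 2).
#' @return an object of class `tolerance_set`.
#' @export
qc_tolerances <- function(overrides = NULL) {
  defaults <- list(
    differential_uniformity = list(comparator = "<", limit = 3.6,
                                   units = "%"),
    integral_uniformity = list(comparator = "<", limit = 4.5, units = "%"),
    energy_resolution = list(comparator = "<", limit = 7.5, units = "%"),
    peak_position = list(comparator = "range", limit = c(120.6, 123.6),
                         units = "keV"),
    good_pixels = list(comparator = "range", limit = c(93.8, 100),
                       units = "%"),
    max_cluster_size = list(comparator = "<", limit = 8, units = "count"))
  if (is.character(overrides)) overrides <- yaml::read_yaml(overrides)
  for (nm in names(overrides)) defaults[[nm]] <- overrides[[nm]]
  for (nm in names(defaults)) {
    tol <- defaults[[nm]]
    if (!tol$comparator %in% c("<", "<=", ">", ">=", "range")) {
      stop("malformed comparator for ", nm, ": ", tol$comparator)
    }
    if (tol$comparator == "range" && length(tol$limit) != 2) {
      stop("range comparator for ", nm, " needs a length-2 limit")
    }
  }
  structure(defaults, class = "tolerance_set")
}

#' Evaluate metrics against a tolerance set
#'
#' Each supplied metric is compared against its named limit; the verdict is
#' `PASS`, `FAIL`, or `NOT-EVALUATED` when the metric is missing (a missing
#' metric never passes). Comparators are strict where stated: a cluster of
#' size 8 fails the `< 8` limit.
#'
#' @param metrics named list of numeric values (with units matching the
#'   tolerance units).
#' @param tolerances a [qc_tolerances()] set.
#' @return data.frame with `metric`, `value`, `comparator`, `limit`,
#'   `units`, `verdict`.
#' @export
evaluate_qc <- function(metrics, tolerances = qc_tolerances()) {
  stopifnot(inherits(tolerances, "tolerance_set"))
  rows <- lapply(names(tolerances), function(nm) {
    tol <- tolerances[[nm]]
    val <- metrics[[nm]]
    verdict <- if (is.null(val) || is.na(val)) "NOT-EVALUATED" else {
      ok <- switch(tol$comparator,
        "<" = val < tol$limit, "<=" = val <= tol$limit,
        ">" = val > tol$limit, ">=" = val >= tol$limit,
        range = val >= tol$limit[1] && val <= tol$limit[2])
      if (ok) "PASS" else "FAIL"
    }
    data.frame(metric = nm,
               value = if (is.null(val)) NA_real_ else val,
               comparator = tol$comparator,
               limit = paste(tol$limit, collapse = "-"),
               units = tol$units, verdict = verdict,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Assemble a structured QC report
#'
#' Collects per-test result blocks into one report object with metadata and
#' pass/fail verdicts, and optionally serializes it to JSON (full-precision
#' values plus a rounded `display` field).
#'
#' @param results named list of result blocks (e.g.
#'   `energy_resolution_result`, `uniformity_result`, `defect_report`,
#'   `rate_curve`, `planar_sensitivity_result`,
#'   `volume_sensitivity_result`, `contrast_result`).
#' @param tolerances a [qc_tolerances()] set used for the verdict block.
#' @param metrics optional named metric values for [evaluate_qc()]; by
#'   default pulled from the result blocks where unambiguous.
#' @param path optional JSON output path.
#' @return an object of class `qc_report` (invisibly if written to `path`).
#' @export
qc_report <- function(results, tolerances = qc_tolerances(), metrics = NULL,
                      path = NULL) {
  if (is.null(metrics)) {
    metrics <- list()
    er <- results$energy_resolution
    if (inherits(er, "energy_resolution_result")) {
      metrics$energy_resolution <- er$average_percent
    }
    un <- results$uniformity
    if (inherits(un, "uniformity_result")) {
      metrics$integral_uniformity <- un$UFOV$integral_percent
      metrics$differential_uniformity <- un$UFOV$differential_percent
    }
    de <- results$defects
    if (inherits(de, "defect_report")) {
      metrics$good_pixels <- de$percent_good_pixels
      metrics$max_cluster_size <- de$max_cluster_size
    }
  }
  report <- structure(list(
    results = results,
    verdicts = evaluate_qc(metrics, tolerances),
    metadata = list(package_version =
                      as.character(utils::packageVersion("spectqc")),
                    schema_version = 1L,
                    created = format(Sys.time(), tz = "UTC"))),
    class = "qc_report")
  if (!is.null(path)) {
    serial <- rapply(unclass(report), function(x) x, how = "replace")
    serial$verdicts <- report$verdicts
    serial$display <- lapply(metrics, function(v) round(v, 2))
    jsonlite::write_json(serial, path, auto_unbox = TRUE, digits = NA,
                         null = "null", force = TRUE)
    return(invisible(report))
  }
  report
}

#' @export
print.qc_report <- function(x, ...) {
  cat("QC report (", length(x$results), " result block(s) )\n", sep = "")
  print(x$verdicts)
  invisible(x)
}
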