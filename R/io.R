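# Plain-text fixture IO. Spectra and count-rate series travel as CSV with a
# '#'-prefixed metadata header; planar images as CSV grids; volumes as a
# JSON container (flat counts + dims). Every container can carry a JSON
# ground-truth sidecar that round-trips unchanged.

write_meta_csv <- function(df, meta, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (nm in names(meta)) {
    writeLines(sprintf("# %s: %s", nm, format(meta[[nm]], digits = 15)), con)
  }
  utils::write.csv(df, con, row.names = FALSE)
}

read_meta_csv <- function(path) {
  lines <- readLines(path)
  is_meta <- grepl("^#", lines)
  meta <- list()
  for (l in lines[is_meta]) {
    kv <- sub("^#\\s*", "", l)
    key <- sub(":.*$", "", kv)
    meta[[trimws(key)]] <- trimws(sub("^[^:]*:", "", kv))
  }
  df <- utils::read.csv(text = paste(lines[!is_meta], collapse = "\n"))
  list(data = df, meta = meta)
}

#' Write / read a spectrum fixture (CSV)
#'
#' Columns `channel_keV` (channel centre) and `counts`; channel width,
#' isotope and detector id in the metadata header. Non-uniform channel grids
#' are rejected on read.
#'
#' @param spectrum a [qc_spectrum()].
#' @param path file path.
#' @return `read_spectrum()` returns a [qc_spectrum()].
#' @export
write_spectrum <- function(spectrum, path) {
  stopifnot(inherits(spectrum, "qc_spectrum"))
  write_meta_csv(
    data.frame(channel_keV = spectrum_energies(spectrum),
               counts = spectrum$counts),
    list(channel_width_keV = spectrum$channel_keV,
         e_min_keV = spectrum$e_min_keV, isotope = spectrum$isotope,
         detector_id = spectrum$detector_id),
    path)
  invisible(path)
}

#' @rdname write_spectrum
#' @export
read_spectrum <- function(path) {
  x <- read_meta_csv(path)
  w <- as.numeric(x$meta$channel_width_keV)
  d <- diff(x$data$channel_keV)
  if (length(d) && max(abs(d - w)) > 1e-9 * w) {
    stop("non-uniform channel grid in ", path)
  }
  qc_spectrum(x$data$counts, w, as.numeric(x$meta$e_min_keV),
              x$meta$isotope, x$meta$detector_id)
}

#' Write / read a count-rate series fixture (CSV)
#'
#' Columns `t_start_s`, `dt_s`, `counts`; background rate, half-life and
#' isotope in the metadata header.
#'
#' @param series a [count_rate_series()].
#' @param path file path.
#' @return `read_count_series()` returns a [count_rate_series()].
#' @export
write_count_series <- function(series, path) {
  stopifnot(inherits(series, "count_rate_series"))
  write_meta_csv(
    data.frame(t_start_s = series$t_start_s, dt_s = series$dt_s,
               counts = series$counts),
    list(background_cps = series$background_cps,
         half_life_s = series$half_life_s, isotope = series$isotope),
    path)
  invisible(path)
}

#' @rdname write_count_series
#' @export
read_count_series <- function(path) {
  x <- read_meta_csv(path)
  count_rate_series(x$data$t_start_s, x$data$dt_s, x$data$counts,
                    as.numeric(x$meta$background_cps),
                    as.numeric(x$meta$half_life_s), x$meta$isotope)
}

#' Write / read a planar image fixture (CSV grid + JSON sidecar)
#'
#' The CSV holds the count grid (rows = transaxial); pitch, detector id and
#' duration go to `<path>.json`, together with any ground truth.
#'
#' @param image a [planar_image()].
#' @param path file path for the CSV.
#' @return `read_planar()` returns a [planar_image()].
#' @export
write_planar <- function(image, path) {
  stopifnot(inherits(image, "planar_image"))
  utils::write.table(image$counts, path, sep = ",", row.names = FALSE,
                     col.names = FALSE)
  meta <- list(pixel_pitch_mm = image$pixel_pitch_mm,
               detector_id = image$detector_id,
               duration_s = image$duration_s,
               ground_truth = attr(image, "ground_truth"))
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_planar
#' @export
read_planar <- function(path) {
  cnt <- as.matrix(utils::read.table(path, sep = ","))
  dimnames(cnt) <- NULL
  meta_path <- paste0(path, ".json")
  if (!file.exists(meta_path)) {
    stop("missing sidecar ", meta_path, ": pixel pitch metadata is required")
  }
  meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
  if (is.null(meta$pixel_pitch_mm)) {
    stop("sidecar lacks the required attribute pixel_pitch_mm")
  }
  img <- planar_image(cnt, meta$pixel_pitch_mm, meta$detector_id,
                      if (is.null(meta$duration_s)) NA_real_ else
                        meta$duration_s)
  if (!is.null(meta$ground_truth)) {
    attr(img, "ground_truth") <- meta$ground_truth
  }
  img
}

#' Write / read a volume fixture (JSON container)
#'
#' Counts stored flat (column-major) with `dim`, voxel spacing and origin;
#' ground truth rides along and round-trips unchanged.
#'
#' @param volume a [volume_image()].
#' @param path file path.
#' @return `read_volume()` returns a [volume_image()].
#' @export
write_volume <- function(volume, path) {
  stopifnot(inherits(volume, "volume_image"))
  obj <- list(dim = dim(volume$counts),
              voxel_mm = volume$voxel_mm, origin_mm = volume$origin_mm,
              counts = as.numeric(volume$counts),
              annotations = volume$annotations,
              ground_truth = attr(volume, "ground_truth"))
  jsonlite::write_json(obj, path, digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_volume
#' @export
read_volume <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(obj$voxel_mm)) {
    stop("volume container lacks the required attribute voxel_mm")
  }
  vol <- volume_image(array(obj$counts, dim = obj$dim), obj$voxel_mm,
                      obj$origin_mm, obj$annotations)
  if (!is.null(obj$ground_truth)) {
    gt <- obj$ground_truth
    if (!is.null(gt$sphere_centres_mm)) {
      gt$sphere_centres_mm <- matrix(unlist(gt$sphere_centres_mm),
                                     ncol = 3,
                                     nrow = length(gt$sphere_diameters_mm))
    }
    attr(vol, "ground_truth") <- gt
  }
  vol
}
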