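# IEC body-phantom tomographic contrast analysis: automated circular ROI
# placement, hot/cold contrast recovery, background variability and
# residual lung error. ROIs are single-slice 2-D circles; a voxel belongs
# to a ROI when its centre lies strictly inside the circle, so membership
# is deterministic and independent of traversal order.

# indices (arr.ind matrix) of voxels whose centres lie strictly inside the
# circle of radius r at (cx, cy) on one transverse slice
roi_members <- function(volume, centre_xy, radius_mm) {
  x <- voxel_centres(volume, 1)
  y <- voxel_centres(volume, 2)
  inside <- outer((x - centre_xy[1])^2, (y - centre_xy[2])^2, `+`) <
    radius_mm^2
  which(inside, arr.ind = TRUE)
}

roi_mean <- function(volume, centre_xy, radius_mm, slice) {
  idx <- roi_members(volume, centre_xy, radius_mm)
  if (!nrow(idx)) stop("empty ROI at (", centre_xy[1], ", ", centre_xy[2],
                       ") r = ", radius_mm)
  mean(volume$counts[cbind(idx, slice)])
}

nearest_slice <- function(volume, z_mm) {
  which.min(abs(voxel_centres(volume, 3) - z_mm))
}

#' Place sphere, background and lung ROIs on an IEC phantom volume
#'
#' Sphere ROIs have the inner diameter of each sphere and sit on the slice
#' centred on the spheres. Background ROIs of each sphere size are placed at
#' 12 template positions (30 degree increments) on a ring between the
#' sphere ring and the phantom wall, on the central slice and the slices
#' closest to +/-1 and +/-2 cm (K = 60 per size); positions violating the
#' 15 mm margins to any sphere edge or to the phantom boundary are nudged
#' radially before placement fails. The lung ROI is a 30 mm circle at the
#' lung-insert centre, evaluated per analysis slice.
#'
#' @param volume a [volume_image()] of the IEC phantom.
#' @param phantom_spec list with `sphere_centres_mm` (n x 3),
#'   `sphere_diameters_mm`, `hot_flags`, `phantom_radius_mm`, and optionally
#'   `lung_centre_xy` (default c(0, 0)); the `ground_truth` attribute of
#'   [gen_iec_volume()] works directly.
#' @param slice_offsets_mm nominal background slice offsets (default
#'   0, +/-10, +/-20 mm, snapped to the nearest slice).
#' @param margin_mm minimum edge-to-edge clearance for background ROIs
#'   (default 15).
#' @param n_angles background template positions per ring (default 12).
#' @return an object of class `roi_set`.
#' @export
place_rois <- function(volume, phantom_spec = attr(volume, "ground_truth"),
                       slice_offsets_mm = c(0, -10, 10, -20, 20),
                       margin_mm = 15, n_angles = 12L) {
  stopifnot(inherits(volume, "volume_image"), !is.null(phantom_spec))
  centres <- phantom_spec$sphere_centres_mm
  diams <- phantom_spec$sphere_diameters_mm
  hot <- phantom_spec$hot_flags
  wall <- phantom_spec$phantom_radius_mm
  lung_xy <- phantom_spec$lung_centre_xy
  if (is.null(lung_xy)) lung_xy <- c(0, 0)
  stopifnot(nrow(centres) == length(diams), length(hot) == length(diams))

  central_slice <- nearest_slice(volume, centres[1, 3])
  slices <- vapply(slice_offsets_mm, function(off)
    nearest_slice(volume, centres[1, 3] + off), 0L)
  snapped_mm <- voxel_centres(volume, 3)[slices] - centres[1, 3]
  if (anyDuplicated(slices)) {
    stop("slice offsets collapse onto duplicate slices; volume too coarse")
  }

  sphere_rois <- lapply(seq_along(diams), function(s) {
    list(centre_mm = centres[s, 1:2], diameter_mm = diams[s],
         hot = hot[s], slice = central_slice)
  })

  ring_r <- sqrt(sum(centres[1, 1:2]^2))
  angles <- (seq_len(n_angles) - 0.5) * 2 * pi / n_angles
  sphere_r_trans <- sqrt(rowSums(centres[, 1:2, drop = FALSE]^2))

  bg_for_size <- function(d) {
    r_roi <- d / 2
    # start midway between the sphere ring and the wall, then nudge
    r0 <- (max(sphere_r_trans) + max(diams) / 2 + wall) / 2
    valid_at <- function(rad, ang) {
      cx <- rad * cos(ang)
      cy <- rad * sin(ang)
      if (rad + r_roi > wall - margin_mm) return(FALSE)
      dd <- sqrt((cx - centres[, 1])^2 + (cy - centres[, 2])^2)
      all(dd >= r_roi + diams / 2 + margin_mm)
    }
    pts <- lapply(angles, function(ang) {
      for (rad in seq(r0, wall, by = volume$voxel_mm[1])) {
        if (valid_at(rad, ang)) {
          return(c(rad * cos(ang), rad * sin(ang)))
        }
      }
      for (rad in seq(r0, 0, by = -volume$voxel_mm[1])) {
        if (valid_at(rad, ang)) {
          return(c(rad * cos(ang), rad * sin(ang)))
        }
      }
      stop("cannot place a valid ", d, " mm background ROI at angle ",
           round(ang * 180 / pi, 1), " deg: margin ", margin_mm,
           " mm to spheres/boundary unsatisfiable")
    })
    do.call(rbind, pts)
  }

  sizes <- sort(unique(diams))
  background_rois <- lapply(sizes, function(d) {
    list(diameter_mm = d, centres_mm = bg_for_size(d), slices = slices)
  })
  names(background_rois) <- paste0("d", sizes)

  structure(list(sphere_rois = sphere_rois,
                 background_rois = background_rois,
                 lung_roi = list(centre_mm = lung_xy, diameter_mm = 30,
                                 slices = slices),
                 central_slice = central_slice, slices = slices,
                 snapped_offsets_mm = snapped_mm,
                 n_per_size = length(slices) * n_angles),
            class = "roi_set")
}

#' @export
print.roi_set <- function(x, ...) {
  cat(sprintf("ROI set: %d sphere ROI(s), %d background size(s) x %d ROIs, lung ROI 30 mm\n",
              length(x$sphere_rois), length(x$background_rois),
              x$n_per_size))
  invisible(x)
}

# all K background ROI means for one size
bg_means <- function(volume, bg) {
  unlist(lapply(bg$slices, function(k) {
    apply(bg$centres_mm, 1, function(ce)
      roi_mean(volume, ce, bg$diameter_mm / 2, k))
  }))
}

#' Hot and cold contrast recovery coefficients
#'
#' For hot sphere j,
#' `Q_H = 100 * (c_H/c_B - 1) / (a_H/a_B - 1)`; for cold sphere j,
#' `Q_C = 100 * (1 - c_C/c_B)`, with `c_B` the mean of the K background ROI
#' means of the matching size.
#'
#' @param volume a [volume_image()].
#' @param rois a [place_rois()] result.
#' @param a_H_over_a_B hot-sphere to background activity-concentration
#'   ratio (> 1; default 8, the standard sphere-to-background ratio).
#' @return data.frame with one row per sphere: `diameter_mm`, `hot`,
#'   `roi_mean`, `c_B`, `Q_percent`.
#' @export
contrast_recovery <- function(volume, rois, a_H_over_a_B = 8) {
  stopifnot(inherits(rois, "roi_set"))
  if (any(vapply(rois$sphere_rois, `[[`, TRUE, "hot")) &&
      a_H_over_a_B <= 1) {
    stop("a_H/a_B must exceed 1 for hot spheres")
  }
  cB_by_size <- vapply(rois$background_rois, function(bg)
    mean(bg_means(volume, bg)), 0)
  rows <- lapply(rois$sphere_rois, function(sp) {
    cB <- cB_by_size[[paste0("d", sp$diameter_mm)]]
    if (is.na(cB) || cB == 0) stop("undefined contrast: background mean is 0")
    cS <- roi_mean(volume, sp$centre_mm, sp$diameter_mm / 2, sp$slice)
    Q <- if (sp$hot) {
      100 * (cS / cB - 1) / (a_H_over_a_B - 1)
    } else {
      100 * (1 - cS / cB)
    }
    data.frame(diameter_mm = sp$diameter_mm, hot = sp$hot, roi_mean = cS,
               c_B = cB, Q_percent = Q)
  })
  do.call(rbind, rows)
}

#' Background variability per sphere size
#'
#' `N_j = 100 * SD_j / c_B_j`, with `c_B_j` the mean of the K background
#' ROI means of size j and `SD_j` their standard deviation (K - 1
#' denominator).
#'
#' @param volume a [volume_image()].
#' @param rois a [place_rois()] result.
#' @return data.frame with `diameter_mm`, `K`, `c_B`, `SD`, `N_percent`.
#' @export
background_variability <- function(volume, rois) {
  stopifnot(inherits(rois, "roi_set"))
  rows <- lapply(rois$background_rois, function(bg) {
    m <- bg_means(volume, bg)
    if (length(m) < 2) stop("need K >= 2 background ROIs per size")
    data.frame(diameter_mm = bg$diameter_mm, K = length(m), c_B = mean(m),
               SD = stats::sd(m), N_percent = 100 * stats::sd(m) / mean(m))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Residual lung error
#'
#' `dC_lung_i = 100 * C_lung_i / C_B_37mm` per analysis slice, where
#' `C_lung_i` is the mean in the 30 mm lung ROI on slice i and `C_B_37mm`
#' the mean of the sixty 37 mm background ROIs; the summary is the mean
#' over slices.
#'
#' @param volume a [volume_image()].
#' @param rois a [place_rois()] result; must include 37 mm background ROIs.
#' @return list with `per_slice_percent` and `summary_percent`.
#' @export
lung_error <- function(volume, rois) {
  stopifnot(inherits(rois, "roi_set"))
  bg37 <- rois$background_rois[["d37"]]
  if (is.null(bg37)) {
    stop("lung error requires 37 mm background ROIs (none in the ROI set)")
  }
  cB37 <- mean(bg_means(volume, bg37))
  lung <- rois$lung_roi
  per_slice <- vapply(lung$slices, function(k)
    100 * roi_mean(volume, lung$centre_mm, lung$diameter_mm / 2, k) / cB37,
    0)
  list(per_slice_percent = per_slice, summary_percent = mean(per_slice))
}

#' Full IEC contrast analysis
#'
#' Convenience wrapper running [place_rois()], [contrast_recovery()],
#' [background_variability()] and [lung_error()].
#'
#' @param volume a [volume_image()] of the IEC phantom.
#' @param phantom_spec see [place_rois()].
#' @param a_H_over_a_B activity ratio (default 8).
#' @return object of class `contrast_result`.
#' @export
contrast_analysis <- function(volume,
                              phantom_spec = attr(volume, "ground_truth"),
                              a_H_over_a_B = 8) {
  rois <- place_rois(volume, phantom_spec)
  structure(list(recovery = contrast_recovery(volume, rois, a_H_over_a_B),
                 background = background_variability(volume, rois),
                 lung = lung_error(volume, rois),
                 a_H_over_a_B = a_H_over_a_B, rois = rois),
            class = "contrast_result")
}

#' @export
print.contrast_result <- function(x, ...) {
  cat("IEC tomographic contrast (a_H/a_B =", x$a_H_over_a_B, "):\n")
  for (i in seq_len(nrow(x$recovery))) {
    r <- x$recovery[i, ]
    cat(sprintf("  %2.0f mm %s: Q = %.1f%%\n", r$diameter_mm,
                if (r$hot) "hot " else "cold", r$Q_percent))
  }
  for (i in seq_len(nrow(x$background))) {
    b <- x$background[i, ]
    cat(sprintf("  N_%.0fmm = %.2f%%\n", b$diameter_mm, b$N_percent))
  }
  cat(sprintf("  lung error = %.1f%%\n", x$lung$summary_percent))
  invisible(x)
}
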