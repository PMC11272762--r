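# 3-D phantom generators: point sources, triple-line cylinder, IEC body
# phantom. Coordinate convention: right-handed, axial = Z (third array
# dimension), mm, voxel centres at origin + (index - 0.5) * spacing. The
# rotation axis is x = y = 0.

# relative expected counts of a 1-D Gaussian sampled at voxel centres along
# one axis: reconstructed voxel values represent samples of the smooth
# activity distribution, so the stated FWHM is exact at any voxel pitch
axis_mass <- function(n, spacing, origin, centre, sigma) {
  stats::dnorm(origin + (seq_len(n) - 0.5) * spacing, centre, sigma)
}

#' Simulate point sources in air as a reconstructed volume
#'
#' Each source is a 3-D Gaussian blob with stated per-axis FWHM, generated
#' directly in reconstructed space (no projection/reconstruction physics).
#'
#' @param source_positions_mm list (or n x 3 matrix) of source centres, mm,
#'   relative to the rotation axis (x = y = 0) and axial centre.
#' @param fwhm_mm per-axis FWHM, length 3 (x, y, z) or scalar (isotropic).
#' @param voxel_mm voxel size, mm (scalar or length 3).
#' @param counts_per_source expected counts in each blob.
#' @param seed integer seed.
#' @param noiseless if TRUE, expected counts without Poisson noise.
#' @param margin_mm padding around the sources; default 6 x max FWHM,
#'   at least 20 mm.
#' @return a [volume_image()] with a `ground_truth` attribute.
#' @export
gen_point_volume <- function(source_positions_mm, fwhm_mm, voxel_mm = 2.46,
                             counts_per_source = 1e6, seed = NULL,
                             noiseless = FALSE, margin_mm = NULL) {
  pos <- if (is.matrix(source_positions_mm)) source_positions_mm else
    do.call(rbind, source_positions_mm)
  stopifnot(ncol(pos) == 3, all(fwhm_mm > 0), counts_per_source > 0)
  fwhm_mm <- rep_len(as.numeric(fwhm_mm), 3)
  voxel_mm <- rep_len(as.numeric(voxel_mm), 3)

  # separation guard: blobs must not overlap (> 5 x max FWHM apart)
  if (nrow(pos) > 1) {
    d <- as.matrix(stats::dist(pos))
    diag(d) <- Inf
    if (min(d) <= 5 * max(fwhm_mm)) {
      stop("sources separated by ", signif(min(d), 4),
           " mm; need > 5 x max FWHM = ", signif(5 * max(fwhm_mm), 4), " mm")
    }
  }

  if (is.null(margin_mm)) margin_mm <- max(6 * max(fwhm_mm), 20)
  lo <- pmin(apply(pos, 2, min), 0) - margin_mm
  hi <- pmax(apply(pos, 2, max), 0) + margin_mm
  # align the grid so the first source sits on a voxel centre (the
  # reconstruction grid is ours to choose; symmetric placement keeps the
  # discrete profile symmetric about its peak)
  lo <- lo + ((pos[1, ] - lo) / voxel_mm -
              (floor((pos[1, ] - lo) / voxel_mm - 0.5) + 0.5)) * voxel_mm
  n <- pmax(3L, ceiling((hi - lo) / voxel_mm))
  origin <- lo
  sigma <- fwhm_mm / FWHM_PER_SIGMA

  expected <- array(0, dim = n)
  for (s in seq_len(nrow(pos))) {
    mx <- axis_mass(n[1], voxel_mm[1], origin[1], pos[s, 1], sigma[1])
    my <- axis_mass(n[2], voxel_mm[2], origin[2], pos[s, 2], sigma[2])
    mz <- axis_mass(n[3], voxel_mm[3], origin[3], pos[s, 3], sigma[3])
    blob <- outer(outer(mx, my), mz)
    expected <- expected + counts_per_source * blob / sum(blob)
  }
  counts <- if (noiseless) expected else
    with_seed(seed, array(stats::rpois(length(expected), expected), dim = n))

  vol <- volume_image(counts, voxel_mm, origin)
  attr(vol, "ground_truth") <- list(
    source_positions_mm = pos, fwhm_mm = fwhm_mm,
    counts_per_source = counts_per_source, seed = seed, noiseless = noiseless)
  vol
}

#' Simulate a triple-line (scatter) phantom volume
#'
#' Line sources run along the axial (Z) direction inside a water cylinder;
#' each line has its own transverse FWHM pair (x, y), emulating the
#' radial/tangential resolution of a reconstructed SPECT volume. Only the
#' line profiles are generated; scatter enters as an optional flat
#' background.
#'
#' @param line_positions_mm n x 2 matrix of transverse (x, y) line centres,
#'   mm from the rotation axis.
#' @param fwhm_mm n x 2 matrix of per-line (x, y) FWHM, mm.
#' @param line_length_mm axial extent of the lines.
#' @param counts_per_line expected counts per line.
#' @param background_per_voxel flat background level (counts/voxel).
#' @param voxel_mm voxel size.
#' @param seed,noiseless as in [gen_point_volume()].
#' @return a [volume_image()] with a `ground_truth` attribute.
#' @export
gen_line_volume <- function(line_positions_mm, fwhm_mm,
                            line_length_mm = 150, counts_per_line = 2e6,
                            background_per_voxel = 0, voxel_mm = 2.46,
                            seed = NULL, noiseless = FALSE) {
  pos <- as.matrix(line_positions_mm)
  fw <- as.matrix(fwhm_mm)
  if (ncol(fw) == 1) fw <- cbind(fw, fw)
  stopifnot(ncol(pos) == 2, nrow(fw) == nrow(pos), all(fw > 0))
  voxel_mm <- rep_len(as.numeric(voxel_mm), 3)

  margin <- max(6 * max(fw), 20)
  lo <- c(pmin(apply(pos, 2, min), 0) - margin, -line_length_mm / 2)
  hi <- c(pmax(apply(pos, 2, max), 0) + margin, line_length_mm / 2)
  # align the transverse grid so the first line sits on a voxel centre
  p1 <- c(pos[1, ], NA)
  for (a in 1:2) {
    off <- (p1[a] - lo[a]) / voxel_mm[a]
    lo[a] <- lo[a] + (off - (floor(off - 0.5) + 0.5)) * voxel_mm[a]
  }
  n <- pmax(3L, ceiling((hi - lo) / voxel_mm))
  origin <- lo

  expected <- array(background_per_voxel, dim = n)
  for (s in seq_len(nrow(pos))) {
    sx <- fw[s, 1] / FWHM_PER_SIGMA
    sy <- fw[s, 2] / FWHM_PER_SIGMA
    mx <- axis_mass(n[1], voxel_mm[1], origin[1], pos[s, 1], sx)
    my <- axis_mass(n[2], voxel_mm[2], origin[2], pos[s, 2], sy)
    plane <- outer(mx, my)
    plane <- counts_per_line * plane / sum(plane) / n[3]
    expected <- expected + outer(plane, rep(1, n[3]))
  }
  counts <- if (noiseless) expected else
    with_seed(seed, array(stats::rpois(length(expected), expected), dim = n))

  vol <- volume_image(counts, voxel_mm, origin)
  attr(vol, "ground_truth") <- list(
    line_positions_mm = pos, fwhm_mm = fw, line_length_mm = line_length_mm,
    counts_per_line = counts_per_line,
    background_per_voxel = background_per_voxel,
    seed = seed, noiseless = noiseless)
  vol
}

# separable 3-D Gaussian blur with zero boundary; kernel normalized to unit
# sum, truncated at 4 sigma
blur_volume <- function(x, fwhm_mm, voxel_mm) {
  for (axis in 1:3) {
    if (fwhm_mm <= 0) next
    sigma <- fwhm_mm / FWHM_PER_SIGMA / voxel_mm[axis]
    r <- max(1L, ceiling(4 * sigma))
    k <- stats::dnorm(-r:r, sd = sigma)
    k <- k / sum(k)
    x <- apply(x, setdiff(1:3, axis), function(f) {
      n <- length(f)
      padded <- c(rep(0, r), f, rep(0, r))
      out <- numeric(n)
      for (j in -r:r) out <- out + k[j + r + 1] * padded[seq_len(n) + r + j]
      out
    })
    x <- aperm(x, order(c(axis, setdiff(1:3, axis))))
  }
  x
}

#' Simulate an IEC body-phantom volume
#'
#' Voxelizes the NEMA IEC image-quality phantom: six fillable spheres on a
#' coplanar ring in the central transverse slice, a low-density lung insert
#' along the axis, and a uniform background, optionally convolved with an
#' isotropic Gaussian PSF and Poisson sampled. The phantom body is modelled
#' as a cylinder.
#'
#' @param sphere_diameters_mm inner sphere diameters (default the reference
#'   set 13, 17, 22, 28, 28, 37 mm).
#' @param hot_flags logical per sphere; hot spheres share one activity ratio,
#'   cold spheres contain no activity (default: four smallest hot, two
#'   largest cold).
#' @param sphere_to_background_ratio hot-sphere to background activity
#'   concentration ratio (default 8).
#' @param background_level expected background counts per voxel.
#' @param lung_insert include the 50 mm foam lung cylinder (counts 0 before
#'   PSF).
#' @param psf_fwhm_mm isotropic Gaussian PSF FWHM; 0 disables blurring.
#' @param voxel_mm voxel size.
#' @param seed,noiseless as in [gen_point_volume()].
#' @param sphere_multipliers optional per-sphere voxel values as multiples of
#'   the background, overriding the hot/cold assignment (used to construct
#'   volumes with a stated apparent recovery).
#' @param lung_multiplier lung voxel value as a multiple of background
#'   (default 0).
#' @param ring_radius_mm radius of the sphere ring (57.2 mm standard).
#' @param phantom_radius_mm body cylinder radius.
#' @param phantom_length_mm body cylinder axial length.
#' @return a [volume_image()] with a `ground_truth` attribute recording
#'   sphere centres, diameters, hot flags and true ROI-mean ratios.
#' @export
gen_iec_volume <- function(sphere_diameters_mm = c(13, 17, 22, 28, 28, 37),
                           hot_flags = c(TRUE, TRUE, TRUE, TRUE, FALSE, FALSE),
                           sphere_to_background_ratio = 8,
                           background_level = 100, lung_insert = TRUE,
                           psf_fwhm_mm = 0, voxel_mm = 2.46, seed = NULL,
                           noiseless = FALSE, sphere_multipliers = NULL,
                           lung_multiplier = 0, ring_radius_mm = 57.2,
                           phantom_radius_mm = 147,
                           phantom_length_mm = 180) {
  ns <- length(sphere_diameters_mm)
  stopifnot(all(sphere_diameters_mm > 0), length(hot_flags) == ns,
            sphere_to_background_ratio > 0, background_level > 0)
  voxel_mm <- rep_len(as.numeric(voxel_mm), 3)

  angles <- (seq_len(ns) - 1) * 2 * pi / ns
  centres <- cbind(ring_radius_mm * cos(angles),
                   ring_radius_mm * sin(angles), 0)
  radii <- sphere_diameters_mm / 2

  # guards: spheres inside the phantom and mutually disjoint
  if (any(ring_radius_mm + radii > phantom_radius_mm)) {
    stop("sphere(s) extend outside the phantom body")
  }
  if (ns > 1) {
    d <- as.matrix(stats::dist(centres))
    diag(d) <- Inf
    if (any(d < outer(radii, radii, `+`))) stop("spheres overlap")
  }
  lung_radius <- 25
  if (lung_insert && any(sqrt(rowSums(centres[, 1:2, drop = FALSE]^2)) -
                           radii < lung_radius)) {
    stop("sphere(s) overlap the lung insert")
  }

  if (is.null(sphere_multipliers)) {
    sphere_multipliers <- ifelse(hot_flags, sphere_to_background_ratio, 0)
  }
  stopifnot(length(sphere_multipliers) == ns)

  half_xy <- phantom_radius_mm + 2 * voxel_mm[1]
  nxy <- ceiling(2 * half_xy / voxel_mm[1:2])
  nz <- ceiling(phantom_length_mm / voxel_mm[3])
  n <- c(nxy, nz)
  origin <- c(-half_xy, -half_xy, -phantom_length_mm / 2)
  # align the axial grid so the sphere plane (z = 0) is a slice centre
  offz <- -origin[3] / voxel_mm[3]
  origin[3] <- origin[3] + (offz - (floor(offz - 0.5) + 0.5)) * voxel_mm[3]

  xc <- origin[1] + (seq_len(n[1]) - 0.5) * voxel_mm[1]
  yc <- origin[2] + (seq_len(n[2]) - 0.5) * voxel_mm[2]
  zc <- origin[3] + (seq_len(n[3]) - 0.5) * voxel_mm[3]

  r2 <- outer(xc^2, yc^2, `+`)
  body <- r2 <= phantom_radius_mm^2
  plane <- array(0, dim = n[1:2])
  plane[body] <- background_level
  expected <- outer(plane, rep(1, n[3]))

  if (lung_insert) {
    lung <- r2 <= lung_radius^2
    for (k in seq_len(n[3])) {
      sl <- expected[, , k]
      sl[lung] <- background_level * lung_multiplier
      expected[, , k] <- sl
    }
  }

  for (s in seq_len(ns)) {
    dz2 <- (zc - centres[s, 3])^2
    kz <- which(dz2 <= radii[s]^2)
    dx2 <- (xc - centres[s, 1])^2
    dy2 <- (yc - centres[s, 2])^2
    for (k in kz) {
      inside <- outer(dx2, dy2, `+`) <= radii[s]^2 - dz2[k]
      sl <- expected[, , k]
      sl[inside] <- background_level * sphere_multipliers[s]
      expected[, , k] <- sl
    }
  }

  if (psf_fwhm_mm > 0) expected <- blur_volume(expected, psf_fwhm_mm, voxel_mm)
  counts <- if (noiseless) expected else
    with_seed(seed, array(stats::rpois(length(expected), pmax(expected, 0)),
                          dim = n))

  vol <- volume_image(counts, voxel_mm, origin)
  attr(vol, "ground_truth") <- list(
    sphere_centres_mm = centres, sphere_diameters_mm = sphere_diameters_mm,
    hot_flags = hot_flags, sphere_multipliers = sphere_multipliers,
    sphere_to_background_ratio = sphere_to_background_ratio,
    background_level = background_level, lung_insert = lung_insert,
    lung_multiplier = lung_multiplier, lung_diameter_mm = 2 * lung_radius,
    ring_radius_mm = ring_radius_mm, phantom_radius_mm = phantom_radius_mm,
    phantom_length_mm = phantom_length_mm, psf_fwhm_mm = psf_fwhm_mm,
    seed = seed, noiseless = noiseless)
  vol
}
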