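# Shared NEMA peak estimator: parabolic fit through the maximum sample and
# its two neighbours for the peak position/height, then linear interpolation
# of the fractional-height crossings on each side. Used by the spectrometry
# module (keV) and the resolution module (mm).

# Parabola through (x0 - h, y1), (x0, y2), (x0 + h, y3); returns vertex.
# On a plateau (zero curvature) the tie is broken to the lower-index sample
# and flagged by the caller.
parabola_vertex <- function(y1, y2, y3, x0, h) {
  denom <- y1 - 2 * y2 + y3
  if (denom == 0) return(list(x = x0, y = y2, degenerate = TRUE))
  delta <- 0.5 * (y1 - y3) / denom
  list(x = x0 + delta * h,
       y = y2 - 0.25 * (y1 - y3) * delta,
       degenerate = FALSE)
}

# Locate the peak of a sampled profile on a uniform grid.
# x: sample positions; y: values. Returns position, height (parabola vertex)
# and the index of the raw maximum, plus flags.
locate_peak <- function(x, y) {
  stopifnot(length(x) == length(y), length(y) >= 3)
  if (max(y) == min(y)) stop("no peak: window is flat")
  i <- which.max(y)  # which.max breaks ties to the lower index
  flags <- character()
  if (sum(y == y[i]) > 1) flags <- c(flags, "tie_lower_index")
  if (i == 1 || i == length(y)) stop("peak at window boundary")
  h <- x[2] - x[1]
  v <- parabola_vertex(y[i - 1], y[i], y[i + 1], x[i], h)
  if (v$degenerate) flags <- c(flags, "plateau")
  # vertex must stay within the 3-point support; otherwise fall back
  if (abs(v$x - x[i]) > h) {
    v <- list(x = x[i], y = y[i])
    flags <- c(flags, "vertex_outside_support")
  }
  list(position = v$x, height = v$y, index = i, flags = flags)
}

# Width of the profile at fraction * height. Crossings are linearly
# interpolated between the two samples bracketing the threshold nearest the
# peak on each side (innermost bracket, robust to tail noise); a flag is set
# when the descent is non-monotone so outer brackets also exist.
width_at_fraction <- function(x, y, peak_index, height, fraction = 0.5) {
  thr <- fraction * height
  n <- length(y)
  i <- peak_index

  cross <- function(j_in, j_out) {
    # interpolate between sample below threshold (j_out) and above (j_in)
    x[j_out] + (thr - y[j_out]) / (y[j_in] - y[j_out]) * (x[j_in] - x[j_out])
  }

  left <- NA_real_
  multi <- FALSE
  if (i > 1) {
    for (j in seq(i - 1, 1)) {
      if (y[j] <= thr && y[j + 1] > thr) {
        left <- cross(j + 1, j)
        if (j > 1 && any(y[seq_len(j - 1)] > thr)) multi <- TRUE
        break
      }
    }
  }
  if (is.na(left)) stop("width undefined: no crossing below ",
                        signif(fraction, 3), " x height on the left side")

  right <- NA_real_
  if (i < n) {
    for (j in seq(i + 1, n)) {
      if (y[j] <= thr && y[j - 1] > thr) {
        right <- cross(j - 1, j)
        if (j < n && any(y[seq(j + 1, n)] > thr)) multi <- TRUE
        break
      }
    }
  }
  if (is.na(right)) stop("width undefined: no crossing below ",
                         signif(fraction, 3), " x height on the right side")

  structure(right - left, left = left, right = right,
            multiple_brackets = multi)
}
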