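# Independent oracles used across the suite. These never share code with
# the estimators they check: widths come from dense-grid scanning of a
# linearly interpolated profile, not from the parabolic-fit/bracket
# algorithm under test.

# brute-force fractional-height width of a sampled profile: linearly
# interpolate onto a dense grid, threshold at fraction * dense maximum,
# return the extent of the above-threshold support
brute_width <- function(x, y, fraction = 0.5, n_dense = 200001L) {
  dense <- seq(min(x), max(x), length.out = n_dense)
  yi <- stats::approx(x, y, dense)$y
  thr <- fraction * max(yi)
  above <- which(yi >= thr)
  dense[max(above)] - dense[min(above)]
}

# analytic width of a Gaussian at a fractional height
gauss_width <- function(sigma, fraction = 0.5) {
  2 * sigma * sqrt(-2 * log(fraction))
}

# brute-force 8-connected cluster sizes by repeated neighbour expansion
# over coordinate sets (independent of the package's flood fill)
brute_cluster_sizes <- function(mask) {
  coords <- which(mask, arr.ind = TRUE)
  if (!nrow(coords)) return(integer())
  remaining <- seq_len(nrow(coords))
  sizes <- integer()
  while (length(remaining)) {
    comp <- remaining[1]
    remaining <- remaining[-1]
    repeat {
      adj <- remaining[vapply(remaining, function(i) {
        any(abs(coords[i, 1] - coords[comp, 1]) <= 1 &
            abs(coords[i, 2] - coords[comp, 2]) <= 1)
      }, TRUE)]
      if (!length(adj)) break
      comp <- c(comp, adj)
      remaining <- setdiff(remaining, adj)
    }
    sizes <- c(sizes, length(comp))
  }
  sizes
}

tc99m_half_life <- isotope_half_life("Tc99m")
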