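---
title: "NEMA performance analysis for pixelated CZT SPECT: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{NEMA performance analysis for pixelated CZT SPECT: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spectqc)
```

## Scope and model of the instrument

`spectqc` implements the NEMA NU 1-2018 performance analyses as they apply
to a 3D-ring SPECT system built from pixelated CZT detector columns: twelve
columns, each a 16-pixel-wide, 7-module (112-pixel) tall grid of
2.46 mm square pixels, giving 27.5 cm axial coverage. Several classic
Anger-camera tests (intrinsic linearity, multi-window registration,
whole-body resolution) do not apply to this architecture and are not
implemented. Reconstruction is likewise out of scope: SPECT volumes are
*consumed* (point sources, triple-line cylinder, uniform cylinder, IEC body
phantom), never reconstructed, and the simulators generate them directly in
reconstructed space.

The coordinate convention, used everywhere without exception: right-handed
axes, axial = third array dimension (Z), all lengths in millimetres, voxel
centres at `origin + (index − 0.5) · spacing` with 1-based R indices. The
rotation axis is x = y = 0.

## The shared peak-width estimator

Energy resolution and every spatial-resolution figure go through one
estimator (`locate_peak()` + `width_at_fraction()`), matching the NEMA
prescription:

1. the peak is the vertex of the parabola through the maximum sample and
   its two neighbours — exactly three points, the minimal form NEMA
   permits. A plateau (zero curvature) breaks the tie to the lower index
   and flags the result; a vertex falling outside the three-point support
   falls back to the raw maximum, flagged.
2. the width at fraction *f* (0.5 for FWHM, 0.1 for FWTM) interpolates the
   crossings of *f* × (vertex height) linearly between the two samples
   bracketing the threshold **nearest the peak** on each side. The
   innermost bracket is deliberate: tail noise can generate additional
   outer brackets, which are detected and flagged but never used. The
   threshold uses the parabola-vertex ordinate, not the raw channel
   maximum, so peak location and height come from the same fit.

Degenerate inputs fail loudly: a flat window is a no-peak error, a peak at
the window boundary or a profile that never falls below the threshold is a
width-undefined error.

The estimator's discretization error is bounded by
`h² / (2 · FWHM)` for sample spacing `h`; the property suite verifies the
bound empirically over σ = 1–5 keV and verifies that the error shrinks
monotonically as channels/voxels are refined (2 → 1 → 0.5 keV;
4.92 → 2.46 → 1.23 mm). Two channels per σ is genuinely coarse — the
linear interpolation then carries about 1% systematic width error — which
is why the bound, not a fixed percentage, is the contract.

## Energy resolution

Spectra are channelized histograms (0.5 keV channels in the low-energy
front-end mode, 1.0 keV in the medium-energy mode) over the 40–279 keV
acquisition range. The analysis window defaults to the located peak
± 15% — wider than the ± 10% (Tc-99m) and +6/−5% (I-123) acquisition
windows so that the full peak shape, including the tenth-height crossings,
is available; the width of this window is a recorded package default, not a
standard value. Per-detector resolution is 100 · FWHM / E_peak; the fleet
report carries each detector, the average and the min–max range. Mixed
isotopes in one fleet are rejected.

## Flood-field uniformity and defect accounting

Raw floods are binned 2 × 4 into 4.92 × 9.84 mm super-pixels (block sums,
totals conserved exactly; partial bins are rejected rather than padded),
then smoothed with the nine-point kernel (1,2,1; 2,4,2; 1,2,1)/16. At
edges the kernel is renormalized over its in-bounds weights — no padding
values are invented, and a constant image passes through unchanged
everywhere.

Field-of-view choices for this detector: the UFOV is the full binned grid
(a pixelated column has no Anger-style edge-unpacking artefacts to trim);
the CFOV is the central 75% of each linear dimension, rounded inward to
whole super-pixels. IU = 100 · (max − min)/(max + min) over the mask; DU is
the same statistic maximized over 5-super-pixel one-dimensional windows
(rows and columns) lying fully inside the mask — 5 is the NEMA window
length. Super-pixels dominated by defective raw pixels can be excluded via
an explicit mask, which also invalidates any DU window containing them.

Defective pixels are classified on the *raw* flood: a pixel is defective
when counts / median(detector) falls outside [0.7, 1.3]. The manufacturer's
actual criterion is undisclosed, so these thresholds are configurable
defaults; because only the ratio to the median enters, classification is
invariant to exposure time. Clusters are 8-connected components (a small
flood-fill written here, cross-checked in the tests against a brute-force
neighbour-expansion oracle). Daily-QC pass/fail limits are configuration,
not code: the defaults (`qc_tolerances()`) are DU < 3.6%, IU < 4.5%,
energy resolution < 7.5%, peak position 120.6–123.6 keV, good pixels
93.8–100%, maximum cluster < 8, with strict comparators (a cluster of 8
fails "< 8") and missing metrics reported NOT-EVALUATED, never PASS.

## Count-rate performance

The decay-source method records, per measurement, the start time, elapsed
time and total counts of a source decaying through the system's full rate
range. Three steps produce the curve: background subtraction
(net counts clipped at zero and flagged when background consumes the
measurement), decay compensation
`OCR = C / (τ · (1 − e^(−Δt/τ)))` with τ the mean lifetime, and
extrapolation from a loss-free reference point
`ICR_i = OCR_n · e^((t_n − t_i)/τ)`.

Design choices where the standard text says only "where there is no time
loss":

* the reference is the **latest** (lowest-rate) measurement with
  OCR < 10 kcps; if none qualifies the last point is used and flagged.
* the 20%-loss input rate interpolates the OCR/ICR ratio against
  **log ICR** between the bracketing measurements (the ratio is smoother in
  log-rate); multiple crossings resolve to the highest-ICR one, and points
  with OCR > ICR (possible under noise) stay on the curve but are excluded
  from the crossing search.
* the simulated acquisition schedule starts at 10 s and grows subsequent
  durations as 2^(elapsed/half-life), capped at 600 s, so expected counts
  per point stay roughly constant as the source decays; start times are
  spaced at a constant input-rate ratio (default 1.25) spanning saturation
  down to the loss-free regime (about 39 points over a 4000-fold rate
  range).

One caveat the tests exercise deliberately: the decay compensation assumes
the recorded counts follow the source's decay, so on a hard-saturated
plateau (output constant while the source decays) the compensation inflates
the plateau readout by about Δt/(2τ) — under 0.2% for a 600 s cap on
Tc-99m. The observed maximum is additionally flagged as censored when the
first (highest-rate) point is already the maximum.

The saturating response used by the generator is
`OCR(x) = min(x, ocr_max · (1 − e^(−x/k)))`. The clamp matters: the two
headline readouts this curve is built to pass through (a 760 kcps plateau
with 20% loss at 917 kcps) are not jointly consistent with any classical
dead-time model — the unclamped exponential would exceed the bisector at
low rates. Clamping keeps the detector lossless at low rate (so a
loss-free reference exists and OCR ≤ ICR everywhere) while preserving both
readouts; the pipeline therefore validates the *readout procedure*, not a
physics model, and no paralyzable/non-paralyzable parameter fitting is
attempted.

## Spatial resolution

Planar: the line-spread function is extracted from a static line-source
image by estimating the line tilt (regression of per-slice centroids;
> 5° is rejected with the measured tilt), subtracting a pedestal estimated
from the outer 20% tails of the perpendicular profile, and summing along
the line over the central 80% band. FWHM/FWTM at the 150 mm measurement
distance are extrapolated to the 100 mm reporting distance by
`R_100 = (100 + l_eff)/(150 + l_eff) · R_150` with the effective collimator
septal length l_eff (17.72 mm for Tc-99m on this system's collimator).

SPECT (three-point, in air): around each expected source position a slab of
half-width 4 × (coarse FWHM estimate) — the 4 is a recorded default; the
standard does not restate it — is cut at the refined centroid and summed
along each axis into transverse, coronal and sagittal views. Views are
analyzed at native voxel pitch with no interpolation upsampling: NEMA
analyzes the measured pitch, and upsampling would trade a known
discretization bound for an estimator-dependent bias. Central transaxial =
mean of the central source's X/Y transverse FWHMs; central axial = mean of
its axial FWHMs from the two other views; peripheral radial/tangential are
taken along/perpendicular to each off-axis source's transverse position
vector — the generator guarantees axis-aligned layouts, so the nearer grid
axis is used — and averaged over the peripheral sources. Per-source values
are kept alongside the means. SPECT with scatter (triple-line cylinder):
per-slice transverse profiles through each line, averaged over the central
80% of the line extent, reported as central/radial/tangential.

## Sensitivity

Planar: `R_D150 = (C/τ) · e^((T_150 − T_cal)/τ) / (1 − e^(−T_acq/τ))` is
read exactly as printed — decay from calibration to acquisition *start* in
the exponential, in-acquisition decay in the last factor — and
`S = R_D150 / A_cal` per detector, fleet average and range reported. The
`expm1` form is used so the no-decay limit (T_acq ≪ τ) degrades gracefully
to C/T_acq.

Volume: `A` is total counts per second across the fleet, `B_c` the activity
concentration decay-corrected to the acquisition midpoint, `SVS = A/B_c`,
`VSAC = SVS / length` with the cylinder axial length an explicit
configuration value (20 cm for the standard phantom — never silently
assumed for real data), and `DDS = 100 · (c_max − c_min)/c_max`. The
published unit string for VSAC (kcps · MBq⁻¹ · cm⁻²) is dimensionally
inconsistent with SVS/length; the implementation follows the formula and
reports cps · cc · MBq⁻¹ · cm⁻¹.

## IEC tomographic contrast

Sphere ROIs are circles with the sphere's inner diameter on the single
transverse slice centred on the spheres; a voxel belongs to a ROI when its
centre lies strictly inside the circle (boundary ties excluded), making
membership deterministic and traversal-independent. Background ROIs of each
sphere size sit at 12 template positions, 30° apart, on a ring between the
sphere ring and the phantom wall, on the central slice and the slices
closest to ± 1 and ± 2 cm (snapped offsets are recorded; at 2.46 mm slices
they land at ± 9.84 and ± 19.68 mm), K = 60 per size. The standard only
says where background ROIs must *not* be, so positions violating the 15 mm
edge-to-edge margins to spheres or to the wall are nudged radially before
placement fails with the violated margins listed. Contrast recovery,
background variability (K − 1 denominator) and the residual lung error
(30 mm ROI over the insert, normalized by the 37 mm background mean) follow
the formulas in the README; the lung summary is the mean over the five
analysis slices — the published reports print one number per
reconstruction without stating the aggregation, so the per-slice values are
always emitted alongside. The activity ratio a_H/a_B defaults to 8 (the
standard 8:1 filling) and is configuration.

## What the generators emulate — and what they do not

Every generator takes one explicit integer seed (no global RNG state; the
caller's stream is saved and restored), records its full ground truth, and
has a noiseless mode in which expected totals match the request to well
inside 0.1% and all downstream error is attributable to discretization.

* **Spectra**: Gaussian photopeak (σ = fraction · E / 2.3548) on a flat
  background carrying a stated fraction (default 2%) of the counts,
  channel-integrated, Poisson-sampled. No Compton continuum, escape peaks
  or CZT hole-tailing — the NEMA estimator only looks inside a window
  around the peak, so the omissions do not touch what is being tested.
* **Floods**: expected counts proportional to a per-pixel gain map; dead
  pixels are gain 0, hot pixels an outlier multiplier.
* **Decay series**: true rate `S · A₀ · 2^(−t/T½)` pushed through the
  response model and integrated over each acquisition — closed form for the
  identity response, adaptive quadrature at relative tolerance 1e−8
  otherwise.
* **Line images and point/line volumes**: Gaussian profiles *sampled at
  pixel/voxel centres* (then normalized), rather than bin-integrated. The
  sampled convention represents reconstructed values as samples of a smooth
  spread function, keeps the stated FWHM exact at any pitch, and makes the
  symmetric two-pixel-FWHM case recover exactly. The volume generators
  align their grid so the first source falls on a voxel centre — the
  reconstruction grid is free to choose, and symmetric placement keeps the
  discrete profile symmetric about its peak; off-centre placement is still
  available by passing explicit margins.
* **IEC phantom**: body cylinder of radius 147 mm and length 180 mm,
  spheres (default 13, 17, 22, 28, 28, 37 mm — two 28 mm spheres, one hot
  and one cold — taken as inputs, not assumed) on a 57.2 mm ring in one
  transverse plane, 50 mm foam lung insert at zero counts, optional
  isotropic Gaussian PSF (separable convolution, kernel truncated at 4σ),
  Poisson sampling. Per-sphere multipliers can override the hot/cold
  assignment to construct volumes with a stated *apparent* recovery — that
  is how partial-volume conditions are emulated without reconstruction.
* **Cylinder projections / sensitivity fleets**: per-detector totals
  proportional to sensitivity factors, with either physical scaling or a
  stated expected count at the reference detector.

None of the generators model scatter or attenuation beyond a flat term, and
none model the projection/reconstruction chain. Passing recovery tests
therefore demonstrates that the *analysis* is correct and well-conditioned
at realistic count levels and samplings — not that a physical scanner would
produce these numbers. Resolution values in particular depend on the
reconstruction protocol on real systems; here they are properties of the
generated blobs.

## Problem sizes and runtime

The suite runs on study-scale inputs chosen to match the acquisitions the
analyses are specified for: 4.5 × 10⁶-count spectra across a 12-detector
fleet, 2 × 10⁷-count floods, 39-point decay series spanning a 4000-fold
rate range, 4 × 10⁷-count sensitivity acquisitions, 10⁶ counts per detector
for the cylinder, and IEC volumes of about 124 × 124 × 74 voxels at
2.46 mm. The full test suite completes in well under a minute on one CPU;
the acceptance script in a few seconds.

## Known limitations

* DICOM and HDF5 containers are not read; fixtures travel as CSV/JSON
  (plain-text, versionable, and sufficient for the synthetic validation
  path this package is built around).
* Radial/tangential directions for peripheral SPECT sources use the grid
  axis nearest the position vector rather than rotating the view; layouts
  far from axis alignment would need profile extraction along oblique
  directions.
* The defective-pixel thresholds and several window/margin defaults stand
  in for undisclosed manufacturer criteria; all are configurable and
  recorded in the outputs.
* Hot-sphere ROIs are single-slice, as are the background ROIs; slice-set
  conventions beyond the ± 2 cm rule are recorded choices.
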