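# spectqc

Quality-control analysis for gamma cameras and SPECT systems following the
NEMA NU 1-2018 standard, adapted to 3D-ring pixelated CZT detector systems
(detector columns of 16 × 112 pixels at 2.46 mm pitch, twelve columns per
ring). It is aimed at medical physicists who commission or routinely check
such systems, and at anyone who wants the NEMA analysis chain as plain,
testable code rather than a vendor script.

The package has two halves:

* **Analysis** — the NEMA metrics themselves:
  * *Energy resolution*: photopeak located by a parabolic fit through the
    maximum channel and its neighbours; FWHM from linearly interpolated
    half-height crossings; resolution = 100 · FWHM / E_peak per detector,
    with the fleet average and range.
  * *Flood-field uniformity*: 2 × 4 super-pixel binning (4.92 × 9.84 mm),
    the nine-point smoothing kernel (1,2,1; 2,4,2; 1,2,1)/16 with
    edge renormalization, then
    IU = 100 · (max − min)/(max + min) over the UFOV/CFOV and DU as the
    same statistic maximized over 5-super-pixel sliding windows; plus
    defective-pixel counts and 8-connected cluster sizes.
  * *Count-rate performance* by the decay-source method:
    C_i = K_i − R_bkg·Δt_i, OCR_i = C_i / (τ·(1 − e^(−Δt_i/τ))),
    ICR_i = OCR_n · e^((t_n − t_i)/τ), with the curve maximum and the input
    rate at 20% loss (OCR = 0.8 · ICR) read off the OCR-vs-ICR curve.
  * *Spatial resolution*: LSF/PSF FWHM and FWTM by the same
    parabola-plus-interpolation estimator, with collimator extrapolation
    R_target = (d_target + l_eff)/(d_measured + l_eff) · R_measured, and
    the NEMA three-point / triple-line SPECT aggregations
    (central transaxial/axial, peripheral radial/tangential/axial).
  * *Sensitivity*: planar sensitivity S = R_D150 / A_cal with the
    decay-corrected rate R_D150, and volume sensitivity
    SVS = A / B_c, VSAC = SVS / length,
    DDS = 100 · (c_max − c_min)/c_max across the detector fleet.
  * *IEC body-phantom contrast*: automated circular ROI placement, hot and
    cold contrast recovery Q_H = 100 · (c_H/c_B − 1)/(a_H/a_B − 1) and
    Q_C = 100 · (1 − c_C/c_B), background variability N_j = 100 · SD_j/c_B_j
    over K = 60 background ROIs per sphere size, and the residual lung
    error ΔC_lung = 100 · C_lung / C_B,37mm.
* **Simulation** — `gen_*()` generators that produce every input the
  analyses consume (spectra, floods, decay series, line images, point /
  line / IEC / cylinder volumes) with explicit seeds and recorded ground
  truth, so each metric is validated by parameter recovery without a
  scanner.

## Worked example

Twelve simulated Tc-99m spectra (4.5 × 10⁶ counts each, 0.5 keV channels,
true fractional FWHM 5.27%), a noiseless decay-source series through a
saturating detector response, and a PSF-blurred IEC phantom:

```r
library(spectqc)

spectra <- lapply(1:12, function(i)
  gen_spectrum(140.5, 0.0527, 4.5e6, 0.5, 0.02, seed = i,
               detector_id = sprintf("D%02d", i)))
energy_resolution(spectra)
#> Energy resolution [Tc99m]: 5.28% (5.27-5.30%) over 12 detector(s)

k <- solve_saturating_k(760000, 917000, 0.8)
resp <- response_model("saturating_exponential", ocr_max = 760000, k = k)
series <- gen_decay_series(300, isotope_half_life("Tc99m"), resp,
                           cps_per_MBq = 10000, noiseless = TRUE)
rate_curve(series)
#> Rate curve: 39 points; max OCR 760.1 kcps; ICR at 20% loss 920.0 kcps

vol <- gen_iec_volume(psf_fwhm_mm = 10, noiseless = TRUE)
contrast_analysis(vol)
#> IEC tomographic contrast (a_H/a_B = 8 ):
#>   13 mm hot : Q = 35.4%
#>   17 mm hot : Q = 49.9%
#>   22 mm hot : Q = 61.3%
#>   28 mm hot : Q = 71.3%
#>   28 mm cold: Q = 71.3%
#>   37 mm cold: Q = 79.5%
#>   ...
#>   lung error = 0.2%
```

The energy-resolution line shows the estimator recovering the generating
5.27% fleet resolution from Poisson-noisy spectra; the rate curve reads the
plateau (maximum observed rate) and the 20%-loss input rate off the
simulated saturating response; the contrast block shows partial-volume loss
growing as spheres shrink under a 10 mm PSF, with zero background
variability and lung counts because the phantom is noiseless.

A thin command-line wrapper is installed at `inst/cli/qc.R`
(`Rscript qc.R <simulate|energy-res|uniformity|count-rate|resolution|sensitivity|contrast|report> ...`);
see `?qc_cli`.

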