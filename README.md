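# presir

Phase-restoring subpixel image registration for phase-sensitive
Fourier-domain optical coherence tomography (FD-OCT).

## The problem

Phase-sensitive FD-OCT reads nanometre-scale tissue motion from the phase of
the complex-valued image: a bulk axial displacement Δz adds a phase
2·k₀·Δz at every pixel (k₀ the centre wavenumber), so optoretinography,
Doppler OCT, and elastography can track optical-path-length (OPL) changes far
below the imaging resolution. But when the sample itself moves between
frames, the sampling points of the image move with respect to the scatterers.
Each pixel is a coherent sum of scattered contributions, and the displacement
changes every scatterer's weight in that sum, producing a *pixel-specific,
deterministic* phase error on top of the true 2·k₀·Δz — the
displacement-induced phase error, visible as speckle decorrelation. Because
it differs from pixel to pixel, self-referencing between two depths does not
cancel it.

Being deterministic, the error can be removed by restoring the original
sampling points. The catch is how to shift a complex OCT image by an
arbitrary subpixel displacement *with physically correct phase*:

* Axially, the FD-OCT signal is not a camera image. A scatterer at OPL z
  contributes exp(i·2·k·z) to the spectral interferogram Ĩ(x, k), so a
  displacement Δz is **exactly** the spectral factor exp(i·2·k·Δz). The
  axial correction is therefore applied in the k domain:

  Ĩ_c(x, k) = Ĩ_T(x, k) · exp(−i·2·k₀·Δz) · exp(−i·2·(k−k₀)·Δz)

  Multiplying both factors ("full" mode) reconstructs the image as if the
  sample had been physically shifted back; multiplying only the
  (k−k₀)-dependent factor ("error-only" mode) removes the
  displacement-induced error while keeping the true 2·k₀·Δz OPL signal.
* Laterally, the image *is* a camera-like convolution with the beam profile,
  so an oversampled scan is shifted in the spatial-frequency domain:
  F_x{Ã_C} = F_x{Ã_T} · exp(i·u·Δx).

This package implements that registration method (PRESIR) together with
everything needed to study it quantitatively:

* a discrete-scatterer FD-OCT speckle simulator (spectral interferograms per
  the signal model above, DFT reconstruction, an analytic superposition
  oracle, calibrated detector noise);
* subpixel motion estimation: the single-step DFT upsampled
  cross-correlation estimator (2× FFT stage plus κ-fold matrix-multiply DFT
  refinement on a 1.5 × 1.5 px window, κ = 1000 by default), surface-phase
  axial estimation, and coarse-to-fine registration of repeated volumes;
* the two conventional baselines for comparison: whole-pixel rolling and the
  2-D Fourier-shift ("FT-based") method;
* phase metrics: temporal unwrapping, OPL = φ/(2·k₀), spatial accuracy σₛ,
  temporal sensitivity σₜ, SNR-limited sensitivity 1/√SNR, self-referenced
  phase, and outlier masking.

It is intended for researchers processing phase-sensitive OCT time series
(ORG, Doppler, elastography) and for validating registration pipelines
against a controlled forward model.

## Worked example

Simulate a fully developed speckle sample matched to a 1.9 µm axial /
19.5 µm lateral resolution system, translate it axially to 3 µm in 0.01 µm
steps, and measure the motion-detection accuracy (spatial standard deviation
σₛ of per-pixel measured OPL change):

```r
library(presir)
sys <- oct_system(n_k = 1024, n_x = 128)   # 0.84 um, 1.9/19.5 um FWHM
sweep <- run_translation_sweep(sys, "axial", seed = 1)
sweep
#> <presir_sweep> (simulated)
#>   direction: axial, correction: none
#>   sweep: 0 to 3 um in 301 frames, 12672 analysis pixels
#>   sigma_s at endpoint: 125 nm
```

Uncorrected, the accuracy degrades to ~125 nm at 3 µm displacement — the
displacement-induced phase error. With PRESIR error-only correction at the
known shifts the error vanishes to numerical precision:

```r
fixed <- run_translation_sweep(sys, "axial",
                               correction = "presir_error_only", seed = 1)
max(fixed$sigma_s_nm)
#> [1] 1.33e-11        # nm
```

Estimate and undo an unknown 2-D subpixel displacement:

```r
f   <- generate_scatterer_field(sys, x_range_um = c(50, 200),
                                z_range_um = c(100, 150), seed = 2)
ref <- reconstruct_image(simulate_interferogram(f, sys))
tgt <- reconstruct_image(simulate_interferogram(
         translate_field(f, 1.2, -0.35), sys))
est <- estimate_shift_2d(ref, tgt, kappa = 1000)
est
#> <shift_estimate> dz = -0.7000 px (-0.3500 um), dx = 0.6150 px (1.1992 um),
#>                  ncc = 1.0000 (kappa = 1000, complex)
reg <- presir_register(tgt, est$dx_um, est$dz_um, mode = "full")
max(Mod(reg$data - ref$data)[, reg$valid_cols]) / max(Mod(ref$data))
#> [1] 4.86e-05
```

The axial part of the correction is exact for the FD-OCT signal model; the
lateral part is exact up to the Gaussian beam's band limit (the residual
above). See `vignette("presir-methods")` for the model, parameter choices,
and limitations.

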