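---
title: "Phase-restoring registration for FD-OCT: model, choices, limitations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Phase-restoring registration for FD-OCT: model, choices, limitations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(presir)
```

## The signal model

The package models a 2-D (x, z) point-scan FD-OCT acquisition of discrete
point scatterers. Scatterer *j*, with field reflectivity $r_j$ at lateral
position $x_j$ and axial optical path length (OPL) $z_j$, contributes to the
complex spectral interferogram of the A-line at $x$:

$$\tilde I(x,k) \;=\; S(k)\sum_j r_j\,
  \exp\!\left[-\tfrac{2 (x-x_j)^2}{w_l^2}\right] \exp(i\,2 k z_j),$$

with $S(k)$ the source amplitude spectrum on a uniform wavenumber grid and
$w_l$ the $1/e^2$ beam radius. The image follows by the discrete transform
$\tilde A(x, z_m) = \sum_n \tilde I(x,k_n)\,e^{-i 2 k_n z_m}$ over depth
pixels $z_m = m\,\delta_z$, keeping the positive-OPD half
($m < M_z = N_k/2$). A single scatterer then peaks with phase zero at its
own depth and carries a local axial phase slope of $-2k_0$.

Two consequences shape everything else:

* an axial bulk displacement $\Delta z$ is *exactly* the spectral factor
  $e^{i 2k\Delta z}$ — no interpolation, no band-limit argument;
* a lateral displacement moves a Gaussian-blurred profile, so at sufficient
  lateral oversampling it is a spatial-frequency phase ramp, accurate up to
  the beam's (effectively total) band limit.

Registration ("PRESIR") composes the inverse operations: zero-pad the image
back to the $2M_z$-sample full-range spectrum, multiply
$e^{-i2k\Delta z}$ (full mode) or $e^{-i2(k-k_0)\Delta z}$ (error-only
mode, which keeps the physical $2k_0\Delta z$ OPL signal), transform back,
then apply the lateral ramp $e^{iu\Delta x}$. Modulus is preserved
elementwise in the k domain, full-mode shifts form a one-parameter group,
and the whole pipeline is exactly invertible. The two conventional
correctors are provided as baselines: whole-pixel circular rolling (nearest-integer correction, ties
rounded away from zero) and the 2-D Fourier shift that treats the complex
image as an ordinary digital image.

Assumptions inherited from the model: translation-only inter-frame motion in
the (x, z) plane; a collimated (depth-invariant) beam, i.e. no defocus or
NA effects; no intra-A-scan fringe washout; no structural change of the
sample itself.

## Tunable parameters

| Parameter | Default | Units | Rationale |
|---|---|---|---|
| `lambda0_um` | 0.84 | µm | typical retinal SD-OCT source; sets $k_0 = 2\pi/\lambda_0$ |
| `axial_fwhm_um` | 1.9 | µm OPL | intensity PSF FWHM; fixes the Gaussian $S(k)$ width $\sigma_k = \sqrt{\ln 2}/\mathrm{FWHM}$ |
| `lateral_fwhm_um` | 19.5 | µm | intensity PSF FWHM; $w_l = \mathrm{FWHM}/\sqrt{\ln 2}$ |
| `dx_um` | lateral FWHM/10 | µm | 10× lateral oversampling, the regime subpixel estimation requires |
| `dz_um` | 0.5 | µm OPL | axial pixel pitch; sets $\Delta k = \pi/(N_k \delta_z)$ |
| `n_k` | 2048 | — | wavenumber samples; $M_z = N_k/2$ image rows |
| `guard_frac` | 0.10 | — | depth guard band against wrap/DC overlap |
| density | 5 | per $L_c^2$ | scatterers per coherence-length-squared of area; fully developed speckle |
| `kappa` | 1000 | — | local NCC upsampling: 0.001-px refinement grid on a 1.5 × 1.5 px window |
| `subvolume_size`, `stride` | 20, 50 | B-scans | coarse stage of volumetric registration |

The coherence length used for density bookkeeping is the axial intensity
FWHM. The closed-form $\sigma_k$ makes the *discrete* axial PSF FWHM match
the configured resolution well within 1% at the default grids; the test
suite measures it on an 8× axially upsampled point target.

**Two axial-sampling regimes.** The default `dz_um = 0.5` pads the k grid to
about ±7σ of the source spectrum, so spectral truncation (~1e−11 at the grid
edge) is negligible and the axial correction operators meet their
\<1e−9 exactness contracts. A real spectrometer is not padded like this: its
array spans the source with modest margin, which for a 1.9 µm resolution at
840 nm means an axial pitch near 1 µm OPL (grid ≈ ±3.5σ). The
moving-phantom-style experiment (`run_sinusoid_experiment`) defaults to that
spectrometer-limited regime, because it is the physically realistic one and
the one in which the Fourier-shift baseline genuinely fails: there the
image's aliased axial carrier band straddles a Nyquist boundary, so the
image-domain phase ramp mis-restores part of the spectrum. On a heavily
padded grid the FT method's error collapses to a global phase that
self-referencing cancels — a padded-grid comparison would make that baseline
look spuriously good.

**SNR convention.** `snr_limited_sensitivity` takes the pixel's signal power
over the *per-quadrature* noise variance, under which $1/\sqrt{\mathrm{SNR}}$
is the exact high-SNR single-pixel phase noise and
$\sqrt{1/\mathrm{SNR}_1 + 1/\mathrm{SNR}_2}$ the two-pixel self-referenced
floor. (Against the total complex noise variance, the same expressions
describe the equal-SNR pair difference.) Detector noise in the simulator is
circular complex Gaussian in the spectral domain, calibrated so a unit
reflector's reconstructed peak SNR equals the requested dB value.

## What the synthetic data emulate — and what they do not

`generate_scatterer_field` draws equal-reflectivity scatterers uniformly at
5 per coherence length squared, which produces fully developed speckle;
`run_translation_sweep` translates that sample to 3 µm in 0.01 µm steps
(axially, laterally, or both), reads per-pixel phase against the initial
frame, unwraps temporally, and reports the spatial standard deviation
$\sigma_s$ of the measured OPL change — the accuracy metric. The per-pixel
traces in these experiments are generated *exactly*: one interferogram is
simulated from the scatterers, axial steps enter as the exact spectral
factor, and lateral steps as a circular Fourier shift of a **laterally
periodic** field (beam profiles wrap at the image width). The periodic
construction makes a circular shift the true translation of a tiled sample,
so every column remains statistically valid and no interpolation error
enters the measured phase. The analysis mask is fixed a priori: rows that
remain inside the speckle band at every sweep position, less a two-axial-FWHM
margin.

Features of real data deliberately *not* emulated: out-of-plane (y) motion
and its decorrelation, rotation/scaling/shear and non-rigid deformation,
defocus, intra-frame fringe washout, galvanometer jitter and reference-arm
drift, multiple scattering (vessel tail artifacts), sample-intrinsic
dynamics, and 1/f or non-Gaussian detector noise. Passing tests therefore
demonstrate correctness of the registration physics and estimators under
translation-only motion — not robustness to everything an in-vivo recording
contains.

`run_sinusoid_experiment` emulates the moving-phantom protocol: 1 Hz axial
sinusoid, ~2.7 µm peak-to-peak, repeated B-scans (600 at 200 Hz by
default), calibrated detector noise, per-frame correction by each method
(ground-truth shifts by default, or accumulated surface-phase estimates),
self-referenced readout against a bright surface strip of the sample, and
per-pixel temporal standard deviation $\sigma_t$ as the sensitivity metric,
with a piezo-off static run as the noise-floor reference. Quantities
reported by hardware studies of physical phantoms and retinas are not
reproducible here; the simulated analogue reproduces the *ordering and
structure* of those comparisons (pixel-level and FT baselines degraded by
residual motion, phase-restoring correction at the static floor).

## Numerical choices

* **DFT conventions.** Unnormalized forward transform in reconstruction,
  $1/N$ on the inverse; any self-consistent pair passes the round-trip
  invariant. Zero-padding appends rows *below* the image (the positive-OPD
  half keeps rows $0..M_z-1$). Axial upsampling extends the k support
  symmetrically, preserving $k_0$ and the physical energy
  $\delta_z \delta_x \sum |A|^2$.
* **Shift bookkeeping.** All public shifts are physical (µm), converted by
  the current pixel pitches, so they survive axial upsampling; estimator
  outputs carry both px and µm. Displacements are reference→target; the
  correctors apply the negative.
* **Lateral edges.** Circular shifts plus a validity mask
  (`ceiling(|dx|/dx)` wrapped edge columns invalidated) rather than
  apodization, keeping the operator exactly invertible.
* **Estimator details.** Complex-valued correlation by default (amplitude
  mode available); first maximum in column-major scan order breaks ties;
  the refinement grid is centred on the 2×-upsampled FFT peak, so with
  integer `kappa` it contains the exact planted grid shifts. Flat images
  raise an error rather than returning an undefined peak.
* **Unwrapping.** Temporal unwrapping accumulates wrapped per-step
  increments; it is correct only for sub-π steps, so traces with any step
  above 0.9π are flagged `suspect`. Surface-phase axial estimation
  accumulates per-step estimates for the same reason (each step must stay
  below λ₀/4).
* **Statistics.** $\sigma_s$ and $\sigma_t$ use the population (1/N)
  standard deviation — immaterial at the pixel counts involved, fixed for
  reproducibility. Outlier masking (amplitude SNR below 10 dB against a
  supplied noise floor, or deviation beyond 5 per-frame MADs from the
  spatial median trace) is a configurable surrogate criterion.
* **Containers.** Stacks are stored as versioned, schema-checked serialized
  containers (endianness-portable), system configurations as YAML, scatterer
  fields and metric tables as CSV.

## Problem sizes

The package-default system (2048 wavenumber samples) matches a realistic
spectrometer, but the shipped experiments and tests run on reduced scenes
chosen to converge statistically while staying desk-scale: the translation
sweeps use 1024 k-samples × 128 A-lines (≈ 12 700 analysis pixels,
≈ 450 speckle cells — a few-percent standard error on $\sigma_s$, averaged
over three speckle realizations in the acceptance script), the sinusoid
comparison 512 × 96 with 200 frames at 100 Hz, and the unit tests smaller
still. Scene geometry (60 µm speckle band centred in the guarded depth
range, full-width periodic lateral extent) is part of the generator
defaults.

## Limitations

Beyond the emulation gaps listed above: the lateral correction presumes
oversampling — at or below Nyquist-critical lateral sampling its accuracy
degrades and no warning is currently raised; the pixel-level baseline's
behaviour at exact half-pixel displacements depends on the tie rule; the
volumetric coarse stage assumes mostly-rigid sub-volumes and integer scan
shifts, with scan-direction (y) correction limited to whole scans; and
temporal unwrapping cannot recover once a per-step phase change exceeds π
(it can only flag it).
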