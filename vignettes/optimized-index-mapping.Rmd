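---
title: "Optimized spectral indices for mapping foliar heavy metals"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Optimized spectral indices for mapping foliar heavy metals}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem and the method

Plants growing on polluted ground take up heavy metals, and the metals leave
a spectral fingerprint: chromium, copper and nickel degrade chlorophyll and
carotenoids, which raises reflectance in the green (~550 nm) and red-edge
(~700 nm) regions; zinc stress promotes anthocyanin synthesis, which raises
red (~650 nm) reflectance. `specmetal` turns that fingerprint into a
quantitative estimator of foliar metal content (mg kg⁻¹) usable from the
single-leaf scale up to airborne hyperspectral imagery.

The estimator is deliberately simple and univariate. For a metal with
per-sample concentrations $y$ and reflectance spectra $\rho(\lambda)$:

1. **Split.** Samples are partitioned into calibration (2/3) and validation
   (1/3) sets with the Kennard–Stone max–min design on the smoothed spectra,
   so the calibration set spans the spectral space.
2. **Search.** Every two-band normalized-difference index
   $\mathrm{NDVI}_{ij} = (\rho_i - \rho_j)/(\rho_i + \rho_j)$ over the VNIR
   grid is correlated (Pearson, two-sided) with $y$ on the calibration set;
   the pair with the largest significant $|r|$ ($p < 0.05$) is the
   *optimized index* for that metal.
3. **Calibrate.** An ordinary least-squares line $y = a\,x + b$ links the
   index $x$ to concentration (exponential and logarithmic transform fits
   are available, but the linear form is the default and generally wins).
4. **Validate.** The line predicts the held-out third; quality is reported
   as Pearson $r$, $\mathrm{RMSE} = \sqrt{\tfrac{1}{n}\sum (y'_j - y_j)^2}$,
   and the residual predictive deviation
   $\mathrm{RPD} = \sigma / \mathrm{RMSE}$, with RPD > 2 the conventional
   threshold for a good chemometric model.
5. **Map.** On an image cube, the same index plus a pixel-level
   recalibration of $(a, b)$ yields a concentration per vegetated pixel;
   vegetation is isolated by a red/NIR NDVI threshold of 0.3 and the map is
   clipped to the site polygon.

The band pair is selected once, at leaf level, and then *held fixed* across
canopy and image levels — only the regression coefficients are refit per
level, sharing one Kennard–Stone split (the same plots are measured at every
level). Normalized-difference indices are used precisely because the ratio
form cancels multiplicative illumination and geometry effects, which is what
makes the leaf-selected pair transferable to field and airborne data.

All of this is wrapped in `specmetal_fit()`, which returns a classed model
object with `print`, `summary`, `coef`, `predict`, `plot` and `residuals`
methods, and in `run_pipeline()`, which drives the full
simulate → preprocess → optimize → fit → validate → map chain.

## Choices the data cannot make for you

**σ in the RPD.** RPD is the ratio of a standard deviation to the RMSE, but
*whose* standard deviation is ambiguous when a dataset has been split. We use
the SD of the measured concentrations in the assessed (validation) set, which
keeps the identity $\mathrm{RPD}\cdot\mathrm{RMSE} = \mathrm{sd(measured)}$
exact within each report; `assess(sigma = ...)` accepts any externally
preferred σ (for instance the full-campaign SD).

**Kennard–Stone feature space.** The split is computed on the smoothed
spectra only (standard chemometric practice), not on spectra concatenated
with concentrations; a custom feature matrix can be passed via `features`.

**Tie-breaking and orientation.** Index search ties (equal $|r|$) resolve by
smaller p-value, then by the lexicographically smaller wavelength pair;
the reported orientation always puts the longer wavelength first, so the
sign of $r$ is well defined. Kennard–Stone distance ties resolve to the
smallest sample index. Every result is therefore deterministic given the
inputs.

**Degenerate inputs.** An index is undefined (NA, never a crash) when its
denominator falls below 1e-9; zero-variance concentration vectors flag the
whole correlation map as undefined; a search in which no pair reaches
significance raises an explicit "no significant index" error; negative
predicted concentrations are retained but flagged, on the view that silently
truncating a linear model hides diagnostic information.

**Preprocessing defaults.** Savitzky–Golay smoothing uses window 11,
polynomial order 3 — at 5.2-nm sampling this suppresses band-level noise
while leaving the red-edge inflection essentially untouched (the filter is
exact on cubic segments). The empirical-line correction fits one gain/offset
per band from ≥ 2 reference panels and is exactly the inverse of any linear
radiance model, which the property tests verify to 1e-9.

**Band matching.** A requested wavelength (say "720 nm") resolves to the
nearest grid center within 2.6 nm — half the imager's sampling interval;
cross-grid comparisons go through `resample_to_grid()`, which uses
nearest-band lookup within that tolerance and linear interpolation beyond
it.

## What the synthetic generator emulates

The real campaign this methodology targets — co-located soil and leaf
chemistry plus leaf, canopy and airborne reflectance over an industrial
brownfield — is not publicly available, so the package ships a generator
whose *mechanism* is planted and therefore fully known:

* **Chemistry.** Four metals (Cr, Cu, Ni, Zn) drawn from truncated normal
  distributions whose means, SDs and ranges default to the published
  brownfield campaign values (e.g. leaf Cu 17.44 ± 5.91 mg kg⁻¹, leaf Zn
  86.91 ± 24.27 mg kg⁻¹). A shared latent contamination factor (default
  correlation 0.9) makes the metals co-vary as they do on a single polluted
  site; without it, no single metal could reach the observed |r| ≈ 0.9 with
  a pigment pool that all of them influence jointly.
* **Spectra.** A parametric green-leaf model: visible baseline, Gaussian
  green peak whose height grows as the chlorophyll proxy falls, logistic red
  edge whose inflection slides from 725 nm down to 685 nm with declining
  chlorophyll, an anthocyanin-proportional red bump at 650 nm, and an NIR
  plateau (0.30–0.45) set by a leaf-structure proxy. Cr/Cu/Ni depress the
  chlorophyll proxy; Zn raises the anthocyanin proxy, each with a
  configurable effect size.
* **Nuisance variation.** Per-sample pigment jitter (SD 0.04), independent
  structure variation (SD 0.12), multiplicative brightness (log-SD 0.08,
  exactly cancelled by the ratio indices but dominant in Euclidean spectral
  distance, as illumination is in the field), smooth sample-specific
  spectral fine structure (SD 0.006, correlation length ≈ 13 nm), and
  multiplicative (2%) plus additive (0.005) sensor noise.
* **Levels.** Canopy and plot-pixel spectra are convex leaf/soil mixtures
  with per-sample soil fractions in [0.05, 0.35]; the soil endmember is a
  fixed 0.08 → 0.25 ramp whose only required property is spectral contrast
  with vegetation.
* **The cube.** 100 × 100 pixels on the 414–992 nm, 5.2-nm grid: bramble-like
  vegetation discs over bare soil, a smooth contamination field with a
  central hotspot, dense patch interiors (soil fraction ≤ ~0.1) and
  soil-mixed margins (+0.2 soil fraction) that reproduce the well-known
  overestimation of metal content at patch edges under a negative-slope
  calibration — `mixed_pixel_diagnostic()` quantifies it. Pixel-scale pigment
  scatter is one third of the leaf-scale scatter because a 1-m pixel averages
  many leaves.

Two generator features deserve an honest caveat. First, the spectral fine
structure term exists because a purely three-factor spectral manifold makes
nearly all band pairs collinear, which no real spectrometer dataset shows;
without it, recovering a specific planted band pair under noise would be
ill-posed. Second, the defaults were set so that the optimized-index
correlations land in the strong regime observed in practice (planted
noise-free |r| ≈ 0.89 for Cr/Ni and 0.94–0.97 for Cu/Zn); the search step
then reports slightly higher calibration |r| than the planted truth, a
selection effect inherent to picking the maximum of thousands of correlated
statistics — one more reason the validation metrics, not the calibration r,
are the numbers to trust.

What passing tests on these data do **not** show: performance under real
atmospheric residuals, BRDF and canopy-geometry effects, co-contaminant
interactions (hydrocarbons alter metal uptake on real brownfields), species
mixtures, or phenology. The generator is a mechanism check, not a field
trial.

## Problem sizes and runtime choices

The test-suite and acceptance ensembles use 40-plot campaigns, 112-band
spectra, 100 × 100-pixel cubes, and 25–50 replicate seeds; a full
simulate-to-map pipeline run takes about a second, so the distributional
checks (e.g. "validation RPD > 2 for Cu and Zn in the majority of seeds",
"median per-pixel truth correlation ≥ 0.8") complete in about a minute.
These sizes mirror the reference campaign rather than stress-testing scale;
the implementation is vectorized over band pairs and pixels and handles
larger cubes in memory without special handling.

## Worked example

```{r, eval = FALSE}
library(specmetal)

cfg <- generator_config(seed = 11)
sim <- generate_sample_set(cfg)

fit <- specmetal_fit(sim$samples, "Cu")   # split + search + calibrate + validate
print(fit)
plot(fit)

# transfer the leaf-selected band pair to image pixels
fit_px <- specmetal_fit(sim$samples, "Cu", level = "pixel",
                        split = fit$split, index = fit$index)

cube <- generate_cube(cfg)
cu_map <- map_metal(cube$cube, fit_px$index, fit_px$model, threshold = 0.3)
print(cu_map)
cor(unclass(cu_map)[cu_map != -9999 & is.finite(cube$truth$conc$Cu)],
    cube$truth$conc$Cu[cu_map != -9999 & is.finite(cube$truth$conc$Cu)])

write_envi(unclass(cu_map), "cu_map", geotransform = cube$cube$geotransform)
```

## Known limitations

* Univariate by design: no PLS or machine-learning regression; the point of
  the method is a transferable two-band index, not maximal leaf-level fit.
* Only normalized-difference (two-band ratio) indices are searched; simple
  ratio indices are expressible through the same machinery but are not on
  the default path, and multi-band or derivative transforms are out of scope.
* The empirical-line step is the only atmospheric correction offered; there
  is no radiative-transfer option.
* Raster I/O is ENVI (BSQ) only, with double-precision storage for exact
  round-trips; the margin diagnostic flags mixed pixels but no unmixing
  correction is attempted.
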