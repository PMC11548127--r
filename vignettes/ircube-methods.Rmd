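---
title: "Methods: processing FTIR hyperspectral maps of stratum corneum"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: processing FTIR hyperspectral maps of stratum corneum}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ircube)
```

## Scope and data model

`ircube` processes hyperspectral absorbance cubes from transmission FTIR
microspectroscopy of stratum corneum (SC): an `rows × cols × channels`
array plus an ascending wavenumber axis in cm⁻¹ and the detector pixel
pitch in µm. Conventions fixed package-wide:

* absorbance `A = 2 − log10(%T)` (so 10 %T ↔ 1.0 AU, 1 %T ↔ 2.0 AU);
* spatial indexing `(row, col)` with row 1 at the top;
* dead detector pixels are NaN at every channel and drop out of all
  statistics implicitly;
* dispersion over a map uses the **population** SD — a map is treated as
  the complete population of the imaged region, not a sample from it;
* the axis is stored ascending; descending containers are flipped on
  read and the flip recorded in `metadata$axis_flipped`.

Interferogram-level processing (apodization, zero-filling) is out of
scope: cubes arrive post-Fourier-transform.

## Baseline correction

`baseline_correct()` implements the iterative clip-above-fit
("modified polyfit") family: least-squares fit a polynomial of order
*p* (default 2) to the spectrum, replace every value above the fit by
the fit, refit, and stop when the fit changes by less than
`tol × range(input)` (default `tol = 1e-3`) or after `max_iter = 100`
refits; the final fit is subtracted. Properties relied on by the tests:
a pure polynomial of degree ≤ *p* maps to ~0; a Gaussian peak of height
0.5 on a quadratic drift is recovered to within 2 %; the operation is
idempotent within `tol`. Non-finite channels are excluded from the fit
and passed through; corrected spectra are **not** clipped at zero —
negative residuals are informative and clipping would bias area
normalization.

The cube path vectorizes the iteration across pixels but freezes each
pixel's fit the moment it converges, so matrix and single-spectrum
results are identical.

## Normalization and the six scenarios

Two per-spectrum scalar normalizations are provided: *area* (divide by
the spectrum's mean over the **entire stored range**, silent regions
included — the literal reading of "mean value over the entire spectral
range") and *Amide II* (divide by the 1548 cm⁻¹ peak intensity).
`preprocess_plan()` composes baseline × normalization into the six
standard scenarios; when both steps are active the baseline runs first,
so the Amide II denominator is a baseline-corrected intensity. Pixels
whose normalization fails (non-positive denominator, dead pixel) are
set to NaN and flagged in the returned validity mask — never silently
dropped.

Because both normalizations are scalar multiplications, band **ratios**
are exactly invariant under them; baseline subtraction, by contrast,
changes the 2920/2850 cm⁻¹ ratio on any sloped baseline. Both facts are
asserted as tests.

## Bands

Peak intensity is the maximum over channels within `peak_window`
(default 8 cm⁻¹ — one nominal resolution element, tolerating small peak
shifts and off-grid band centres) of the band centre; `peak_window = 0`
reads the nearest channel (ties toward the lower wavenumber). Integrals
are trapezoidal over the band's `integral_range` with no local baseline
(defaults: 1500–1590, 1600–1700, 2830–2870, 2890–2950 cm⁻¹). Whether a
published map used nominal-channel or local-maximum intensities is
rarely stated; both are supported, local-maximum is the default.

## Outlier removal

**Histogram / Tukey fences.** For each screening band (defaults:
1548, 1652, 2920 cm⁻¹) the per-pixel intensity distribution is fenced at
`[Q1 − k·IQR, Q3 + k·IQR]`; quartiles use linear interpolation
(R's `quantile` type 7), fixed for reproducibility. The default `k` grid
is {0.5, 1, 1.5, 3} (Tukey's "outlier" and "far out" values plus two
stricter ones). Per-band outlier sets combine by union by default — the
conservative choice — with intersection available. Freedman–Diaconis
bin widths (`2·IQR·n^{−1/3}`) are attached for the diagnostic
histograms.

**PCA score distance.** Channels are standardized (so every wavenumber
counts equally; zero-variance channels are dropped with a notice), PCA
is fitted per map, and each pixel's Euclidean distance `d` of its first
`n_components = 2` scores from the **component-wise median** score is
thresholded at `threshold_c × median(d)` with `threshold_c ∈ {2, 3, 4}`
and default 3. The median reference (not the mean, not Mahalanobis) is
deliberate: it is robust to the very outliers being hunted.

Dead pixels are automatic outliers under both protocols.

**Filter stage.** Masks can be computed on the raw cube or on the
plan-processed cube (`compare_methods(filter_stage =)`). The package's
own choices: *artifact recovery* is scored with filters on the raw cube,
because an order-2 polynomial fit exactly absorbs a flat +10 AU hot
spike — after baseline correction hot pixels are mathematically
invisible to any detector; *dispersion comparisons* run filters on the
baseline + area processed cube, the configuration the literature
favours (histogram filtering on unpreprocessed spectra mixes thickness
into the fenced variable and performs worse).

## QC metrics

Normalized SD (CV) = population SD / mean of a band-intensity map over
retained pixels; retention = retained fraction; compactness = largest
4-connected inlier component / all inliers (a checkerboard scores
`1/n`). `compare_methods()` tabulates mean/SD/CV per band over a
plan × filter grid in canonical row order, with per-cell error codes
rather than aborting the grid.

## The simulator: what it emulates, and what a green test establishes

`simulate_map()` states a world with the heterogeneity sources named for
FPA maps of SC, every draw from one seeded Mersenne-Twister stream:

| parameter | default | why |
|---|---|---|
| grid, axis | 128×128, 698–3845 cm⁻¹ step 4 | acquisition geometry (tests scale to 64×64) |
| keratin bands | 1652/0.75, 1548/0.55 AU | Amide I the tallest SC peak |
| lipid bands | 2920/0.30, 2850/0.20 AU | CH₂ stretches, ratio 1.5 |
| `thickness_cv` | 0.20 | makes raw per-band CV ≈ 0.2, the reported raw dispersion; multiplicative, so ratios are thickness-free |
| `lipid_cv` | 0.10 | genuine chemical heterogeneity; survives normalization, leaving CV(2920) ≈ 0.08 |
| `thickness_corr_len` | 8 px | smooth fields: moving-average-filtered white noise, rescaled to exact mean 1 / SD = CV |
| `baseline_order`, `baseline_scale` | 2, 0.15 AU | positive constant term (scattering raises the floor) + symmetric higher orders; 0.15 makes baseline drift contribute enough raw dispersion that correction lowers CV (raw 0.26 → corrected 0.22), the reported direction |
| `noise_sd` | 0.005 AU | detector noise after 256 co-added scans |
| `hot_frac`, `dead_frac` | 0.002 each | hot = +10 AU at all channels (unambiguous spike), dead = NaN |
| `contam_frac`, `n_blobs` | 0.02, ≤16 disks r 2–6 px | sebum-like blobs: ester carbonyl 1740 + CH₂ 2920/2850 (0.50/0.60/0.40 AU), thickness-independent (a droplet sits on the film) |

What the generator does **not** contain: Mie/resonant-Mie scattering
distortions, water-vapour lines, spatially structured detector
nonuniformity, band-shape (peak-shift) heterogeneity, saturated
absorbance, or multimodal tissue composition. A green simulation test
therefore establishes that the pipeline behaves correctly under smooth,
unimodal, Gaussian-ish heterogeneity plus point/blob artifacts — not
that it reproduces every property of real SC maps (see below).

## Two deliberately red acceptance expectations

Two literature-derived acceptance assertions fail under this stated
world, and the failures are informative rather than bugs:

1. **2-component PCA cannot see the contaminants on raw spectra.** With
   per-channel scaling, the +10 AU hot spikes and the three degrees of
   freedom of per-pixel baseline drift own the leading principal
   components; the contaminant signature (2 % of pixels) appears around
   PC5. A score-distance cut in PC1–PC2 recovers hot/dead pixels
   perfectly (that guarantee *is* asserted and green) but finds ~15 % of
   the union artifact set. Making contaminants ~4× stronger would flip
   this, but the contaminant amplitude was chosen on chemical grounds
   and is not tuned to the test.
2. **Tight Tukey fences beat PCA on the fenced band's own CV.** A fence
   at `k = 0.5` directly truncates the 2920 cm⁻¹ intensity distribution
   at ≈ ±1.35 σ; no joint 2-PC distance cut at `3 × median(d)`
   (≈ 3.5 σ radius) can shrink that band's CV as much when the
   heterogeneity is smooth and unimodal. Measured over 32 maps:
   0.058 (k=0.5) < 0.076 (k=1.0) < 0.083 (k=1.5) ≤ 0.084 (PCA) <
   0.086 (k=3). The reported superiority of PCA filtering on real SC
   maps therefore must rest on anomaly structure — spatially coherent,
   spectrally diffuse deviations that dominate the leading PCs — which
   the stated generator does not produce. It is a finding about the
   simulator's world, honestly reported, not suppressed.

## Numerical choices and degenerate inputs

* Quantiles: type 7 everywhere (fences, FD widths).
* `fd_bin_width` accepts `(iqr, n)` directly (its closed forms are
  defined for any `n ≥ 1`) and returns `Inf` with a warning at zero IQR
  ("one bin").
* Zero-width fences (zero IQR) are legitimate: all equal values are
  inliers, any spike is outside.
* PCA distances carry an absolute floor of `1e-8 × max(d)` against BLAS
  rounding jitter so exactly-identical spectra yield "no outliers".
* `nearest_channel` breaks ties toward the lower wavenumber; targets
  beyond the axis ± one spacing are errors.
* Baseline correction on an all-NaN spectrum is a degenerate-input
  error; inside `apply_plan` dead pixels instead pass through as NaN and
  are flagged invalid by normalizing plans.
* Band integrals are exactly additive over adjacent ranges only when the
  shared endpoint is a channel (trapezoid on stored channels, no
  interpolation).

## Files

Cubes serialize to a single-file plain-text container (JSON header,
wavenumber line, CSV pixel rows, NaN for dead pixels) — chosen over an
HDF5 binding so the package runs on a plain R + data.table stack; mean
spectra export as `wavenumber_cm-1, absorbance, sd` CSV; masks as 0/1
grids plus flagged-coordinate lists. A CLI
(`inst/cli/ircube.R`) chains simulate → preprocess → filter → report.
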