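# ircube

Processing and quality control of FTIR hyperspectral maps of stratum
corneum.

## The problem

Transmission FTIR microspectroscopy with a focal-plane-array (FPA)
detector records one mid-infrared absorbance spectrum per pixel — a
128 × 128 map at 2.7 µm pixel pitch yields 16,384 spectra over a
345.6 × 345.6 µm field, sampled from 698 to 3845 cm⁻¹. For stratum
corneum (SC), the outermost skin layer, the chemistry of interest is read
from a handful of bands: the protein Amide I (1652 cm⁻¹) and Amide II
(1548 cm⁻¹) peaks, and the lipid CH₂ asymmetric (2920 cm⁻¹) and
symmetric (2850 cm⁻¹) stretches, whose ratio tracks alkyl-chain
conformational order.

A single "representative" mean spectrum of such a map is distorted by
local thickness variation, per-pixel baseline drift, hot/dead detector
pixels and contaminants. `ircube` implements the processing chain needed
before any mean spectrum is trusted:

* **baseline correction** — iterative polynomial ("modified polyfit")
  subtraction per spectrum;
* **normalization** — by the spectrum's mean over the full range
  (*area*) or by the Amide II peak intensity, i.e. the six standard
  scenarios {baseline on/off} × {none, Amide II, area};
* **band chemometrics** — peak intensities (window maximum), trapezoidal
  band integrals, band ratios, and 2-D chemical maps;
* **outlier-pixel removal** — (a) Tukey fences
  `[Q1 − k·IQR, Q3 + k·IQR]` on band-intensity histograms
  (Freedman–Diaconis binning, union/intersection over bands), and
  (b) PCA score distance: per-channel standardization, Euclidean
  distance of each pixel's first *q* PC scores from the component-wise
  median, cut at `c × median(d)`;
* **QC metrics** — normalized SD (CV = population SD / mean) per band,
  retention fraction, and compactness (largest 4-connected inlier
  component / all inliers), tabulated across plan × filter grids by
  `compare_methods()`.

A seeded simulator (`simulate_map()`) generates SC-like cubes with
ground-truth artifact masks — multiplicative thickness field, smooth
lipid-fraction field, positive polynomial baselines, additive noise,
hot (+10 AU) and dead (NaN) pixels, and sebum-like contaminant blobs
(ester carbonyl 1740 cm⁻¹ + CH₂ stretches) — so every filter can be
scored for sensitivity/specificity against known truth.

## Worked example

```r
library(ircube)

## simulate one SC-like map (64 x 64 pixels to keep the example quick)
sm  <- simulate_map(default_sc_config(rows = 64, cols = 64, seed = 1))

## pre-process: iterative polynomial baseline (order 2) + area normalization
pp  <- apply_plan(sm$cube, preprocess_plan("poly", "area"))

## remove outlier pixels with Tukey fences on the three screening bands
mask <- histogram_outliers(pp$cube, fence_bands(), k = 1.5)

qc_report(pp$cube, mask)
#> <qc_report> plan=poly2+area filter=histogram k=1.5 combine=union bands=amide2,amide1,ch2_asym
#>   retention 0.9421, compactness 0.9995
#>       band center   mean     sd      cv    n
#> 1   amide2   1548 14.518 0.3146 0.02167 3859
#> 2   amide1   1652 19.750 0.4304 0.02179 3859
#> 3  ch2_sym   2850  5.447 0.4540 0.08334 3859
#> 4 ch2_asym   2920  8.073 0.6719 0.08322 3859
#>   Amide I/II ratio 1.3622, CH2 asym/sym ratio 1.4771

## how well did the filter recover the injected artifacts?
truth <- sm$truth$artifact_mask | sm$truth$contam_mask
str(outlier_recovery(histogram_outliers(sm$cube, k = 1.5), truth))
#> List of 2
#>  $ sensitivity: num 0.96
#>  $ specificity: num 0.989
```

Reading the report: after baseline + area normalization the intensities
are in "mean-normalized" units (spectrum mean = 1), the Amide I band is
the tallest SC feature, and the residual CV of the 2920 cm⁻¹ band
(~0.08, versus ~0.26 for the raw map) reflects genuine lipid-fraction
heterogeneity rather than thickness or baseline artifacts.

## Command line

```sh
CLI=$(Rscript -e 'cat(system.file("cli/ircube.R", package="ircube"))')
Rscript $CLI simulate   --seed 42 --out map.txt --truth truth.json
Rscript $CLI preprocess --in map.txt --baseline poly:2 --norm area --out map_pp.txt
Rscript $CLI filter     --in map.txt --method pca --components 2 --threshold 3 --out mask.csv
Rscript $CLI report     --in map_pp.txt --mask mask.csv --out report/
```

Cubes travel as a self-describing plain-text container (JSON header +
wavenumber line + one CSV row per pixel); masks and reports are CSV.

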