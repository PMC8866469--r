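# icspectra

Quantification of the **intercapillary space spectrum** on en face optical
coherence tomography angiography (OCTA) images of the superficial retinal
capillary plexus, for researchers studying microcirculatory impairment in
diabetic retinopathy (DR).

On a binarized en face angiogram, the capillary network encloses dark,
flow-free polygons. Healthy maculae carry hundreds of small *intercapillary
areas*; capillary obstruction in DR merges them into enlarged *nonperfusion
areas*. Because the two form a morphological continuum rather than distinct
classes, every vessel-enclosed dark region is treated as one *intercapillary
space* and the per-eye spectrum is summarized by:

- the total space count inside the central 2 mm circle (FAZ excluded),
- mean area, perimeter, and minimum/maximum Feret diameters,
- counts of spaces larger than 0.01–0.05 mm²,
- the count of spaces with area/perimeter ratio A/P > 0.025 (large, smooth,
  remodeled spaces).

The measurement chain mirrors the canonical four-step pipeline: Gaussian
blur (σ = 2 px) → Phansalkar adaptive local thresholding,
t = m·(1 + p·e^(−q·m) + k·(s/r − 1)) over a circular 15 px window
(k = 0.25, r = 0.5, p = 2, q = 10) → central 2 mm ROI → signal inversion and
connected-component morphometry, with the space containing the image center
identified as the foveal avascular zone and excluded. The statistical layer
implements Kruskal–Wallis with Bonferroni-corrected pairwise Mann–Whitney
comparisons, Fisher's exact test (two-sided, minimum-likelihood convention),
Spearman rank correlation, and empirical ROC/AUC with Hanley–McNeil
confidence intervals.

Because no patient images accompany the study this pipeline replicates, the
package includes a **synthetic OCTA generator**: a blue-noise Delaunay
capillary mesh with a protected FAZ ring and trunk vessels, permanent
capillary dropout, per-frame transient flow-signal loss, and speckle-like
noise — with exact planar-face ground truth for validation.

## Worked example

Simulate a moderate-NPDR-like eye (25% capillary dropout), run the full
measurement pipeline, and read its spectrum:

```r
library(icspectra)

cfg <- scene_config(dropout_rate = 0.25, rng_seed = 42)
eye <- simulate_eye(cfg)                      # graph + ground truth + frames
an  <- analyze_eye(eye$stack, run_config(),
                   eye_id = "demo", grade = "moderate_npdr")
t(an$spectrum)
#> total_count        "316"
#> mean_area_mm2      "0.005629325"
#> mean_perimeter_mm  "0.3096315"
#> mean_min_diam_mm   "0.0634857"
#> mean_max_diam_mm   "0.1162885"
#> faz_area_mm2       "0.2708387"
#> count_area_gt_0.03 "7"
#> count_ap_gt_0.025  "29"
```

316 spaces (a healthy synthetic eye carries ≈ 540, so a quarter of the
capillaries being obstructed roughly halves the count), a mean space area of
5.6 × 10⁻³ mm², and 29 spaces above the 0.025 A/P remodeling threshold.
Contingency analysis of the published criterion counts — 30 of 34 severe
NPDR/PDR eyes vs 19 of 41 milder eyes carrying at least one such space:

```r
fisher_exact_2x2(matrix(c(30, 4, 19, 22), 2, 2, byrow = TRUE))
#> row pct: 88.2 46.3   p: 0.000194   OR: 8.68
```

The analysis workflow lives in `analysis/`:
`01_simulate_eyes.R` (exemplar eyes per grade, frames + ground truth to
disk), `02_quantify_spaces.R` (file-based measurement, space tables and eye
spectra), `03_cohort_statistics.R` (97-eye synthetic cohort, severity
report, dropout sweep). Outputs land under `results/`.

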