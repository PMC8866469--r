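---
title: "Quantifying the intercapillary space spectrum on en face OCTA"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying the intercapillary space spectrum on en face OCTA}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

On en face optical coherence tomography angiography (OCTA) of the
superficial vascular plexus, the retinal capillary network encloses dark,
flow-signal-free polygons. In a healthy macula these *intercapillary areas*
are small and numerous; in diabetic retinopathy (DR), capillary obstruction
merges them into progressively larger *nonperfusion areas* (NPAs). Because
no threshold cleanly separates a large intercapillary area from a small NPA,
this package treats every vessel-enclosed dark region as a member of a single
*intercapillary space spectrum* and quantifies the spectrum per eye: the
total number of spaces inside the central 2 mm circle, their mean area,
perimeter, and minimum/maximum Feret diameters, the counts above fixed area
thresholds (0.01-0.05 mm²), and the count of spaces with an area/perimeter
ratio above 0.025 (a marker of large, smooth, remodeled spaces). These
per-eye parameters are then related to DR severity grades with nonparametric
statistics and ROC analysis.

`icspectra` provides the full measurement pipeline, the statistical layer,
and a synthetic OCTA generator with exact ground truth, organized as an
analysis workflow (`analysis/01...03`) over package functions.

## The measurement pipeline

`analyze_eye()` chains the four canonical steps on a 1024 x 1024 en face
image covering a nominal 3 x 3 mm field (pixel pitch 3/1024 ≈ 2.93 µm):

1. **Normalization and denoising.** Intensities are min-max rescaled to
   [0, 1] (`normalize_intensity()`), then smoothed with a Gaussian of sigma
   `blur_radius_px` = 2 px (`gaussian_blur()`). The blur parameter follows
   the "radius" convention of the common image-analysis tools, whose
   Gaussian dialog takes the sigma; the kernel is truncated at 3 sigma and
   border windows are renormalized so constants are preserved.
2. **Binarization.** Phansalkar adaptive local thresholding
   (`phansalkar_threshold()`): a pixel is vessel when its intensity exceeds
   $t = m\,(1 + p\,e^{-q m} + k\,(s/r - 1))$, with $m$ and $s$ the mean and
   population standard deviation over a circular window of radius 15 px.
   The constants default to $k = 0.25$, $r = 0.5$, $p = 2$, $q = 10$ — the
   reference defaults of the method, designed for low-contrast vascular
   images. All are exposed in `threshold_params()` because published
   descriptions of this pipeline do not state them. The threshold is
   computed on the full rectangular image before the ROI is applied, so the
   circle boundary introduces no local-statistics artifacts.
3. **ROI restriction.** The central 2 mm circle (`make_circular_roi()`),
   pixel membership by the center-of-pixel rule.
4. **Detection and morphometry.** Non-vessel pixels inside the ROI are
   connected-component labeled (`label_spaces()`, 4-connectivity by
   default so that 8-connected vessel lines separate spaces; 8 is
   available) and each region is measured (`measure_spaces()`):
   * area = pixel count x pitch²;
   * perimeter from the (1, √2)-weighted 8-directional boundary chain code
     (Moore tracing of the outer boundary); single-pixel regions use the
     pixel-outline value 4 px;
   * minimum/maximum Feret diameters from the convex hull of pixel-corner
     points (an s-pixel square yields side s), exact rotating-calipers
     width and hull diameter (`feret_diameters()`);
   * area/perimeter ratio (units mm, conventionally reported as A.U.).

   The space containing the image-center pixel is the foveal avascular zone
   (`identify_faz()`; if the center pixel is vessel, the region of the
   nearest non-vessel pixel is used). The FAZ is excluded from every
   downstream summary (`summarize_eye()`). Regions touching the ROI rim are
   included and flagged; no minimum-size filter is applied by default —
   both switches exist in `run_config()` because the original analysis does
   not document either choice.

Repeat frames of the same eye can be averaged (`average_frames()`);
comparing the averaged and single-frame binarizations flags capillaries
with transient flow-signal loss (`transient_loss_map()`). Measurement always
uses a single raw frame, because transient and permanent signal loss are
both of interest. Frames are assumed co-registered; an optional
integer-shift alignment (`align_frames()`) exists but is off by default.

## The synthetic generator and what it emulates

No OCTA images accompany the study this pipeline replicates, so validation
rests on `simulate_eye()`:

* **Mesh.** Blue-noise (Poisson-disc) nodes at `seed_point_density` = 125
  points/mm², Bowyer-Watson Delaunay triangulation, and random removal of
  `mesh_prune` = 15% of edges so faces become lobular polygons rather than
  triangles. This density yields ≈ 540 faces inside the 2 mm ROI of a
  healthy eye — the clinical scale of healthy control counts.
* **FAZ.** Nodes are cleared from a central disk of radius 0.30 mm and a
  protected vessel ring (a polygon circumscribing the disk) guarantees one
  face containing the image center with area ≥ πr².
* **Trunk vessels.** Two wider (x 2.2), protected arcade paths threaded
  through the mesh above and below the macula.
* **Pathology.** `apply_dropout()` permanently removes each unprotected
  edge with probability `dropout_rate` (capillary obstruction; faces merge
  and the ground truth is recomputed from the surviving planar graph).
  `render_frames()` additionally blanks each surviving edge per frame with
  probability `transient_rate` (transient plugging), rasterizes edges as
  hard 12 µm strokes (capillary ≈ 8 µm plus flow-signal widening; no
  anti-aliasing, so binarization tests stay sharp), and adds clipped
  Gaussian noise (`noise_sd`, default 0.05). Defaults describe a healthy
  control eye: `dropout_rate` 0, `transient_rate` 0.02.
* **Ground truth.** Faces of the planar embedding are extracted by
  half-edge traversal; `true_face_metrics()` reports the exact shoelace
  area and perimeter of each face polygon and, given a pixel pitch, the
  face's *open area* — the polygon minus the rendered vessel strokes,
  evaluated at the render-grid pixel centers. The open area, not the
  polygon area, is what a perfect binarizer can recover: at any realistic
  stroke width the half-stroke band is 15-40% of a 0.005 mm² face, so
  recovery checks compare against open areas while the 0.1 mm-square
  worked example (area 0.01 mm², perimeter 0.4 mm, ratio exactly 0.025)
  uses the polygon values.

What the generator does **not** emulate: OCT speckle statistics (noise is
white Gaussian), projection artifacts, hemodynamics, the 3-D structure of
the deep plexus, vessel-caliber heterogeneity beyond the two trunk classes,
and eye-to-eye variation in FAZ size. Passing recovery tests therefore
demonstrate correctness of the measurement chain on geometry of the right
scale, not performance on real OCTA noise.

## Validation protocol and numerical choices

* **Recovery runs use `blur_radius_px = 0`.** Blur exists solely to
  suppress speckle; noise-free scenes have none. On such scenes the
  binarization at blur 0 is pixel-exact (binary strokes are either above
  or below the local threshold), so detected per-face areas equal the
  ground-truth open areas and the comparison isolates the morphometry. With
  the default blur, the Phansalkar threshold sits below the blurred stroke
  edge midpoint and the detection boundary moves ≈ 0.7 px outward per side
  — space counts are unaffected (the standard pipeline recovers the
  ground-truth face count within ±1% on the reference eye) but per-face
  areas of small spaces shrink by 10-15%. This dilation is a property of
  local adaptive thresholding on soft edges, affects real images equally,
  and cancels in group comparisons; it is the reason the per-face area
  check is run at blur 0.
* **Chain-code perimeter bias.** The pixel-center chain code underestimates
  the pixel outline: a digital disk of radius 100 px measures ≈ 5% below
  2πr, and a 3 x 3 px square has area 9 but chain perimeter 8, so the
  isoperimetric bound ap_ratio ≤ perimeter/(4π) can only hold for regions
  more than ~8 px across. The estimator is kept because it is the closest
  documented analogue of the particle-analysis tools this pipeline mirrors,
  and the area/perimeter threshold (0.025) is calibrated on the same
  estimator.
* **Ties and degenerate inputs.** ROC ties are credited 0.5 (the AUC equals
  the normalized Mann-Whitney U exactly); AUC confidence intervals use the
  Hanley-McNeil distribution-free formula. The two-sided Fisher p sums all
  margin-fixed tables no more likely than the observed one (the
  minimum-likelihood convention; alternatives such as doubling differ).
  Bonferroni factors equal the number of pairwise comparisons actually
  performed per parameter. Constant input to the Spearman routine yields a
  flagged missing coefficient. A cohort grouping with an empty class skips
  its ROC with a warning. An all-vessel ROI is an explicit error.
* **Orientation.** Total space counts fall with disease and are negated
  before ROC analysis; every other spectrum parameter rises with disease
  and enters as-is.

## Cohort simulation: the study conditions

`simulate_cohort()` mirrors the clinical study design: 22 nondiabetic, 14
no-apparent-retinopathy, 10 mild, 17 moderate, 16 severe NPDR, and 18 PDR
eyes. Grade effect sizes increase monotonically — mean dropout rates
(0, 0.03, 0.08, 0.18, 0.28, 0.38) and mean transient rates (0.02, 0.06,
0.08, 0.10, 0.12, 0.15) — with a uniform ±50% per-eye jitter, so early
disease is dominated by transient signal loss and late disease by permanent
dropout. These values were fixed once, on the reasoning that the healthy
median count (~540) and the diabetic overall median (~300) should bracket
the clinically reported scale; they are not fitted quantities.

The controlled experiment behind the directional claims is
`dropout_sweep()`: 20 eyes at each dropout rate in {0, 0.1, 0.2, 0.3, 0.4}
(the uniform grid spanning the cohort's range), all other parameters at
their defaults. Expected behavior, computed by the test suite and the
acceptance script: Spearman rho ≤ -0.8 for dropout vs total count, ≥ 0.8
for dropout vs mean area and vs the high-ratio count, and AUC ≥ 0.9 for
total count discriminating synthetic diabetic from nondiabetic eyes. The
high-ratio count saturates above dropout ≈ 0.25 (merging consumes
high-ratio spaces as fast as it creates them), which keeps its sweep
correlation near the 0.8 bound.

Problem sizes throughout (1024 px rasters; 100-eye sweeps; a 97-eye cohort)
were chosen so a full validation run completes in a few minutes on one CPU
while preserving the study's native image scale.

## Known limitations

* Absolute patient-level quantities (median counts, clinical AUCs of
  0.9-ish magnitude) depend on the true retinal geometry and scanner noise;
  the synthetic cohort reproduces their direction and approximate scale,
  not their values. Reproducing the published per-eye numbers would require
  the original images, which were never deposited.
* The blur-then-threshold dilation described above means absolute vessel
  masks from the default pipeline are systematically generous; dice against
  the true stroke mask is ≈ 0.84 at 4 px stroke width (sensitivity 1.00).
* Perimeters of spaces containing vessel islands count only the outer
  boundary.
* The deep vascular plexus is out of scope: its three-dimensional network
  does not admit well-defined enclosed spaces on a 2-D projection.
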