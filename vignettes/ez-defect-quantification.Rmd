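---
title: "Quantifying ellipsoid zone defects in the central subfield"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying ellipsoid zone defects in the central subfield}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ezquant)
```

## The measurement problem

The ellipsoid zone (EZ) is a hyperreflective band on spectral-domain OCT
whose local disappearance marks photoreceptor disruption. In macular disease
the area of EZ loss inside the 1-mm central subfield (CSF) is a structural
outcome measure, but outlining the defect by hand on every visit is slow and
grader-dependent. `ezquant` implements a semi-automated alternative: segment
the EZ and RPE boundaries once per B-scan (done upstream by the device or a
segmentation tool), collapse them into an en face thickness map, and let a
trainable pixel classifier delineate the defect, with the human contribution
reduced to a few corrective scribbles on a small training subset.

The pipeline has four stages, each usable on its own:

1. **En face mapping** (`build_enface`): per-B-scan EZ/RPE boundary heights
   become a 2-D map of EZ-to-RPE distance in micrometres.
2. **Pixel classification** (`train_classifier`, `predict_classmap`): a
   random forest over a multiscale texture feature stack labels each map
   pixel *intact* or *absent*.
3. **Area measurement** (`measure_defect`): defect pixels inside the CSF
   disc are grouped into 8-connected components, filtered by a minimum-area
   rule, summed, and capped at the analytic disc area.
4. **Method agreement** (`agreement_stats`): automated and manual area
   series are compared with ICC(A,1), Bland-Altman limits of agreement, and
   the Wilcoxon signed-rank test.

## En face thickness maps

A `LayerVolume` stores, for every B-scan, the axial pixel row of the EZ and
RPE boundaries at each A-scan, plus the device geometry (scan width and
depth in mm, axial scale in µm per pixel). Thickness is
`(rpe - ez) * axial_scale_um_per_px`; segmentation failures appear as `NaN`
and propagate as missing pixels.

Missing values are filled by linear interpolation along each B-scan
(`fill_missing_linear`), with endpoint extension at the edges; interpolation
never overshoots the observed envelope. Whole missing B-scans are filled by
interpolating down the slow axis. A map whose input is more than 50% missing
is rejected as ungradable rather than silently invented.

Because the slow axis is much coarser than the fast axis (128 B-scans
versus 512 A-scans on the 6 × 6 mm cube protocol), the map is resampled to a
square grid with a pixel-centre convention: output row `i` samples input
position `(i - 0.5) * n_bscans / out_rows + 0.5`, so resampling 128 rows to
128 rows is the identity. For classification the map is rendered to 8-bit
grayscale with a fixed display window of 0–64 µm: healthy EZ-to-RPE distance
sits mid-window and complete loss maps to black, so a single window serves
every eye and keeps the classifier's input scale stable across the cohort.

```{r enface, eval = FALSE}
vol <- read_layer_xml("E001.xml")
map <- build_enface(vol, out_rows = 512)
gray <- render_grayscale(map, window_um = c(0, 64))
```

## The feature stack and classifier

Defect boundaries in en face maps are textural: a sharp dark blob with a
soft penumbra. Mirroring the trainable-segmentation approach popularised by
ImageJ/Fiji, each grayscale map is expanded into 64 feature channels
(`feature_stack`):

* the raw image;
* Gaussian blurs at σ ∈ {1, 2, 4, 8, 16, 32} px;
* Sobel gradient magnitude of each blur;
* Hessian eigenvalues, trace, and determinant at each σ;
* differences of Gaussians for all 15 ordered σ pairs;
* membrane projections (a 19 × 19 line kernel rotated through 30
  orientations, reduced by sum/mean/std/median/max/min);
* local variance in a disc neighbourhood.

The σ ladder up to 32 px spans structure from single-pixel noise to blobs a
third of the map across, matching the range of defect sizes the 1-mm CSF
can contain. Convolutions use reflection padding so features are unbiased at
the map edge, and kernel FFTs are cached per map shape so a 512 × 512 stack
costs a few seconds after the first map.

The classifier (`train_classifier`) is a random forest — 200 trees, 2
features tried per split, unlimited depth — the standard configuration for
interactive pixel classification, where label noise is low and training
sets are small. Training examples are *scribbles*: sparse pixels labelled
intact or absent on roughly 10% of the cohort, emulating the interactive
workflow in which a grader corrects a live preview rather than tracing
boundaries. Prediction (`predict_classmap`) returns per-class probabilities
and an argmax label map; ties resolve to *intact* so the automated reading
is conservative.

## Area rules

`measure_defect` intersects the defect mask with the CSF disc mask
(pixel-centre inclusion rule, `csf_mask`), labels 8-connected components,
and applies two rules from reading-centre practice:

* **Minimum area.** Components with area ≤ 0.004 mm² are considered absent
  and dropped — below the smallest gradeable lesion in standard grading
  protocols. On a 6 mm / 512 px grid this is the difference between a
  29-pixel (0.00398 mm², dropped) and a 30-pixel (0.00412 mm², kept)
  component.
* **Maximum area.** The total is capped at the analytic disc area
  π(d/2)² (`csf_analytic_area`; 0.7854 mm² for the 1-mm disc). The ceiling
  quoted in exported tables, `csf_reported_bound`, is that value truncated
  to two decimals: 0.78 mm².

## Agreement statistics

`agreement_stats` compares paired automated and manual area series:

* **ICC(A,1)** — a two-way mixed-effects, absolute-agreement, single-rater
  intraclass correlation computed from the ANOVA mean squares, so a
  systematic offset between methods lowers the coefficient.
* **Bland-Altman** — mean difference (bias) and 95% limits of agreement
  bias ± 1.96 · SD of the differences.
* **Wilcoxon signed-rank** — exact p-value for n ≤ 25 without ties (zeros
  dropped, mid-ranks), otherwise a normal approximation with tie and
  continuity corrections.

## Synthetic validation

Real cohorts ship without pixel-level ground truth, so the package includes
a generator (`synthetic_spec`, `generate_eye`, `generate_cohort`) that
builds layer volumes with *analytic* truth: elliptical defects with known
area, a partial-volume edge ramp centred on the true boundary, sinusoidal
surface wobble, boundary noise, and missing segmentations. An independent
10× fine-grid oracle (`true_area_oracle`) recomputes each defect's area
inside the CSF. `run_synthetic_benchmark` runs the whole pipeline on such a
cohort — train on ~10%, predict the rest — and reports per-eye Dice overlap,
area errors, and agreement statistics against both truth and a simulated
manual grader.

```{r benchmark, eval = FALSE}
bm <- run_synthetic_benchmark(seed = 1, n_eyes = 30)
summary(bm$per_eye$dice)
bm$icc_vs_truth
bm$stats_auto_vs_manual
```

The synthetic cohort validates the machinery, not the biology: defects are
elliptical, noise is Gaussian, and the simulated grader is unbiased. Results
on clinical data depend on segmentation quality and the representativeness
of the scribbled training subset, and ungradable scans (decentred discs,
heavy signal loss) must still be excluded by a human, as they would be in
any reading-centre workflow.

## Key parameters

| Parameter | Default | Rationale |
|---|---|---|
| Display window | 0–64 µm | brackets healthy EZ-to-RPE distance; fixed across eyes |
| Feature scales σ | 1–32 px | noise grain up to CSF-sized blobs |
| Trees / mtry | 200 / 2 | standard interactive-segmentation forest |
| CSF diameter | 1.0 mm | ETDRS central subfield |
| Minimum defect area | 0.004 mm² | smallest gradeable lesion |
| Area ceiling | π/4 ≈ 0.785 mm² (reported 0.78) | analytic disc area |
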