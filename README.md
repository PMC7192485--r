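# ezquant

Semi-automated quantification of ellipsoid zone (EZ) defect area in the
1-mm central subfield (CSF) of the macula, from spectral-domain OCT layer
segmentations.

## The problem

The EZ is the hyperreflective OCT band formed by photoreceptor inner-segment
ellipsoids; where photoreceptors are disrupted, the band disappears. The
area of EZ loss inside the ETDRS central subfield is a structural outcome
measure in macular disease, but tracing defect boundaries by hand on every
B-scan of every visit is slow and grader-dependent.

`ezquant` takes the per-B-scan EZ and RPE boundary heights that device or
third-party segmentation software already produces, and:

1. collapses them into an **en face EZ-to-RPE thickness map** (missing
   segmentations filled by linear interpolation, slow axis resampled to a
   square grid with a pixel-centre convention);
2. classifies each map pixel as **intact or absent EZ** with a random
   forest (200 trees, 2 features per split) over a 64-channel multiscale
   texture feature stack (Gaussian blurs σ = 1–32 px, Sobel magnitudes,
   Hessian eigenvalues, differences of Gaussians, membrane projections,
   local variance), trained from sparse scribbles on roughly 10% of the
   cohort;
3. measures the **defect area inside the 1-mm CSF disc**: 8-connected
   components, components ≤ 0.004 mm² dropped as below the smallest
   gradeable lesion, total capped at the analytic disc area π/4 ≈ 0.785 mm²
   (reported ceiling 0.78 mm²);
4. compares automated against manual area series with **ICC(A,1)**,
   **Bland-Altman bias and limits of agreement**, and the **Wilcoxon
   signed-rank test** (exact for n ≤ 25 without ties).

A synthetic layer-volume generator with analytic ground truth (elliptical
defects of known area, partial-volume edge ramps, surface wobble, boundary
noise, missing data) supports end-to-end validation without patient data.

## Worked example

Train on one synthetic eye's scribbles, measure a second eye, and compare
with the analytic truth:

```r
library(ezquant)

spec <- synthetic_spec(n_eyes = 3, seed = 42,
                       defect_area_range_mm2 = c(0.1, 0.5))

# en face map for the training eye
eye <- generate_eye(spec, 1)
map <- build_enface(eye$volume)
map
#> ThicknessMap E001/V01: 512 x 512 px (0.0117 x 0.0117 mm/px)
#>   thickness range 0.0-42.5 um; clamped 351; missing B-scans 0

# train from scribbles on the 0-64 um grayscale rendering
gray <- render_grayscale(map, window_um = c(0, 64))
model <- train_classifier(
  list(list(stack = feature_stack(gray), labels = generate_labels(eye))),
  seed = 7)
model
#> RFModel: 200 trees, mtry 2, seed 7; OOB accuracy 1.0000
#>   64 feature channels, classes: intact, absent

# classify and measure an unseen eye
eye2 <- generate_eye(spec, 2)
map2 <- build_enface(eye2$volume)
cm <- predict_classmap(model, feature_stack(render_grayscale(map2)))
csf <- csf_mask(eye2$csf_record, map2)
m <- measure_defect(defect_mask_from_classmap(cm), csf,
                    map2$pixel_dx_mm * map2$pixel_dy_mm,
                    eye_id = eye2$volume$eye_id, method = "automated")
m
#> DefectMeasurement E002/visit (automated): 0.4399 mm^2 in 1 component(s), 0 dropped
eye2$true_csf_area_mm2
#> [1] 0.4410
```

The automated measurement recovers the analytic defect area to about
0.001 mm² on this eye.

For file-based batch work the same stages are available as `run_map`,
`run_train`, `run_measure`, and `run_compare`, with a thin command-line
front end in `inst/cli/ezquant.R`:

```sh
Rscript inst/cli/ezquant.R simulate --out cohort --n-eyes 30 --seed 1
Rscript inst/cli/ezquant.R map --in cohort --csf cohort/csf.csv --out maps
```

## Tests

```sh
Rscript -e 'testthat::test_dir("tests/testthat", package = "ezquant", load_package = "installed")'
```

The suite includes property-based checks against independent oracles:
brute-force flood fill for component labeling, exhaustive sign enumeration
for the exact Wilcoxon p-value, ANOVA mean squares for ICC(A,1), fine-grid
rasterization for defect areas, and byte-identical reruns for
reproducibility.

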