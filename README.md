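# roastspec

Near-infrared hyperspectral chemometrics for classifying the roasting
degree of coffee beans — for spectroscopists and food-quality engineers
who want a tested, reproducible reference implementation of the standard
NIR-HSI classification workflow, and for method developers who need its
individual pieces (Kennard–Stone partitioning, SPA, random frog, LS-SVM)
as reusable, oracle-checked components.

## What it does

Roasting changes a bean's moisture, fat and phenolic chemistry, and those
changes imprint on its 874–1734 nm reflectance spectrum: a fat-linked
absorption valley near 1210 nm, a –CH₂ feature near 1350 nm, the water
band at 1450 nm, and broad reflectance differences across 930–1350 nm
that track roast degree. `roastspec` implements the full pipeline from
raw sensor counts to a seven-class decision:

1. **Reflectance calibration** — R = (I_raw − I_dark) / (I_white − I_dark),
   elementwise against dark/white reference frames (full-cube or
   line-scan references).
2. **ROI mean-spectrum extraction** and trimming to the 930–1700 nm
   working range.
3. **Kennard–Stone** max–min partitioning into calibration and
   prediction sets (2:1 by default; 525 samples → 350/175).
4. **Effective-wavelength selection** by PCA X-loading extrema, the
   successive projections algorithm (SPA), or random frog (RF) — a
   Monte-Carlo subset search with an inner cross-validated PLS1 model
   whose per-band selection probability, averaged over 50 runs, ranks
   the wavelengths.
5. **Multiclass LS-SVM** (RBF kernel, one-vs-one, direct KKT solve),
   with γ tuned pointwise over [1, 1000] and σ² set by the median
   heuristic.
6. **Evaluation** — confusion matrix, overall accuracy, misclassified
   count, stratified 10-fold cross-validation.

Because no raw bean cubes are publicly deposited, the package ships a
first-class synthetic-scene generator (`generate_scene()`,
`generate_spectra_matrix()`) that emulates the line-scan acquisition —
256 bands over 874–1734 nm, noisy detector edges, class-dependent
absorption depths at 1210 nm, 75 samples per class — plus ENVI BIL cube
I/O for user-supplied data. See `vignette("roastspec-methods")` for the
model details and design choices.

## Worked example

```r
library(roastspec)

sig <- make_class_signatures()                       # 7 roast signatures
cfg <- run_config(profile = "test",
                  scene = scene_config(samples_per_class = 25, seed = 7),
                  selector = "rf",
                  rf = rf_params(T = 1000, n_runs = 5, seed = 7),
                  seed = 7, out_dir = "run")
res <- run_pipeline(cfg)

res$selection
#> <selection_result> method=rf, 8 bands: 1198, 1161, 1245, 1319, 1201, 1211, 1151, 1080 nm
res$confusion
#> <confusion_matrix> 58 samples, accuracy 100.00%
#>         RD-U RD-L RD-ML RD-LM RD-M RD-MD RD-D
#>   RD-U     6    0     0     0    0     0    0
#>   RD-L     0   11     0     0    0     0    0
#>   RD-ML    0    0     7     0    0     0    0
#>   RD-LM    0    0     0     6    0     0    0
#>   RD-M     0    0     0     0   13     0    0
#>   RD-MD    0    0     0     0    0     8    0
#>   RD-D     0    0     0     0    0     0    7
```

The selector has concentrated on the 1080–1320 nm region — exactly where
the synthetic classes differ (the class-dependent 1210 nm fat feature
and the surrounding separation window) — and the tuned LS-SVM then
classifies the 58 held-out samples perfectly. Synthetic classes are
cleanly separated by construction; on real beans adjacent roast degrees
overlap and published accuracies for this workflow are near 90%. Every
run writes its artifacts (spectra, split, selection, predictions,
confusion matrix, metrics) and a manifest with checksums into `out_dir`;
identical config and seed reproduce the manifest bit for bit.

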