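---
title: "Methods: hyperspectral chemometrics for roasting-degree classification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: hyperspectral chemometrics for roasting-degree classification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(roastspec)
```

## The problem and the pipeline

Roasting transforms the chemistry of coffee beans — moisture, crude fat,
trigonelline, chlorogenic acid and caffeine all shift with roast degree —
and those shifts leave fingerprints in near-infrared (NIR) reflectance.
`roastspec` implements a complete NIR hyperspectral-imaging workflow for
classifying beans into seven ordinal roasting degrees (RD-U unroasted
through RD-D dark):

1. **Reflectance calibration.** A raw digital-number cube is converted to
   relative reflectance with the white–dark correction
   \(R = (I_\mathrm{raw} - I_\mathrm{dark}) / (I_\mathrm{white} -
   I_\mathrm{dark})\), applied elementwise.
2. **ROI extraction.** Each sample's spectrum is the arithmetic mean over
   all pixels of its region of interest at every band.
3. **Band trimming.** Detector edges are noisy; analysis keeps the closed
   interval 930–1700 nm.
4. **Kennard–Stone partitioning** into calibration and prediction sets at
   ratio 2:1.
5. **Effective-wavelength (EW) selection** by one of three methods:
   X-loading extrema, the successive projections algorithm (SPA), or
   random frog (RF).
6. **Multiclass LS-SVM** with an RBF kernel, with the regularization
   parameter \(\gamma\) tuned by pointwise search over \([1, 1000]\).
7. **Evaluation** by confusion matrix and overall accuracy, plus
   stratified 10-fold cross-validation within the calibration set.

Because no public hyperspectral cubes of roasted beans exist at the scale
this workflow assumes, the package includes a first-class synthetic-scene
generator; every stage is exercised end to end on generated data.

## The synthetic scene model

The generator emulates a line-scan acquisition of 525 samples (75 per
class, 7 classes; all counts configurable), each sample a dish of ~30
elliptical beans sharing one ROI. Its reflectance model is a smooth
baseline with negative-Gaussian absorption features at the canonical NIR
overtone positions for plant material — ~940 nm (third C–H overtone),
~1210 nm (second C–H overtone, tracking crude fat), ~1350 nm (–CH\(_2\)
stretch), ~1450 nm (first O–H overtone, water) and ~1660 nm (first C–H
overtone). Two ingredients separate the classes, both confined to the
930–1350 nm window where real roast series differ most:

* the 1210 nm feature depth increases monotonically with roast degree
  (default step 0.012 reflectance units per class), and
* a broad offset bump centred at 1140 nm lowers overall reflectance for
  darker roasts (default step 0.025 per class).

The raw cube is produced by inverting the calibration identity:
`raw = dark + R * (white − dark) + noise`, with white ≈ 4000 and dark ≈
100 counts (arbitrary but fixed sensor levels). Pixel noise is
independent Gaussian in digital-number space with SD 0.01 reflectance
units inside 930–1700 nm and 10× that outside — edge bands of real
InGaAs line-scan systems are low-signal and littered, and the 10× ratio
is our choice of magnitude. Sample-level variability is a multiplicative
scatter factor `N(1, 0.01)` plus an additive offset `N(0, 0.003)` per
sample, a minimal stand-in for dish-to-dish packing and illumination
differences. A fast path (`generate_spectra_matrix()`) produces ROI-mean
spectra directly, scaling band noise by \(1/\sqrt{n_\text{pixels}}\);
both paths draw the sample-level effects in the same RNG order, so they
coincide exactly in the noiseless limit (a tested invariant, max
absolute difference below 1e−10).

**What the generator does not emulate:** optical scattering and
illumination geometry, spatial within-bean heterogeneity, wavelength-
correlated noise, instrument drift, and the true (unpublished) per-class
reflectance magnitudes. Passing tests therefore demonstrate that the
algorithms are implemented correctly and behave sensibly under a
realistic signal structure — not that real beans of adjacent roast
degrees are as separable as the synthetic classes. On the default
synthetic conditions the classifier is essentially perfect; the
published experiment on real beans reached ~90%, and that gap is
expected.

## Partitioning, responses and the inner regression engines

**Kennard–Stone** is the classic max–min procedure on Euclidean
distances of the trimmed, unpreprocessed reflectance rows: seed with the
most distant pair, then repeatedly admit the sample farthest from the
current set, until `round(cal_fraction * n)` samples are selected
(350 = round(2/3 · 525)). Ties break to the lowest row index. The split
is global by default; a `per_class` option exists because sources often
leave this unstated.

**Class responses.** The selectors' inner regressions need a numeric
response; classes are encoded as ordinal dummy numbers 1…7 in roasting
order, which respects the ordinal structure of roast degree.

**PCA** is computed by SVD of the column-centred matrix; each
component's sign is fixed so its largest-magnitude loading element is
positive, making loading plots reproducible. **PLS1** is the NIPALS
recursion (compiled, since subset-search selectors refit it thousands of
times); with the full latent dimension it reproduces ordinary least
squares, which the tests assert against an independent OLS fit.

## The three wavelength selectors

**X-loading extrema.** "Large absolute loading" is operationalised as
the interior local maxima of the absolute loading curves of the first
two components, pooled (keeping each band's largest score) and truncated
to the top `n_select` (default 7). If fewer extrema exist than
requested, all are returned and the result is flagged.

**SPA.** For every candidate starting band a projection chain of length
`n_select` (default 5) is grown: each step projects all remaining band
columns onto the orthogonal complement of the chosen set and takes the
column of maximal residual norm (Gram–Schmidt, with a from-scratch
projection oracle in the tests). Chains are scored by the hold-out RMSE
of a multiple linear regression predicting the class response on a
deterministic 2:1 Kennard–Stone split of the provided rows; the best
chain is returned in selection order. Chains that hit rank deficiency
(residual norm below 1e−10) stop early and are flagged.

**Random frog.** A Monte-Carlo subset search in the reversible-jump
spirit with an inner PLS1 model. Defaults follow the standard published
settings: `T` = 10000 iterations, initial size `Q` = 50, proposal SD
`theta` = 0.3 × current size, pool coefficient `omega` = 3, acceptance
bound `eta` = 1, 50 runs averaged. Where the framework leaves internals
open we fixed, and document here:

* the inner PLS latent count is `min(10, subset size, fold-train size − 1)`,
  and candidate RMSEs come from 5-fold cross-validation on folds fixed
  per run (so RMSEs of successive subsets are comparable);
* growth samples an `omega`-fold pool of outside bands, fits PLS on the
  union and keeps the top bands by coefficient magnitude; shrink keeps
  the top bands of the current subset;
* acceptance probability is `min(eta, RMSE_current / RMSE_candidate)`;
  a non-finite candidate RMSE means rejection;
* the inner model operates on **autoscaled** (unit-variance) columns.
  This matters: PLS coefficients on raw reflectance scale inversely with
  band variance, so low-variance noise bands would otherwise dominate
  the importance ranking. Autoscaling is the standard convention in the
  subset-search PLS literature.

A band's selection probability (SP) is the fraction of iterations whose
retained subset contains it, averaged over runs; run *r* uses seed
`seed + r − 1`. Bands are ranked by mean SP and the top `k` (default 8)
are reported; the number kept is an exposed parameter, not an automatic
threshold, because no principled cutoff for SP rankings is established.

Whether selection should see all rows or calibration rows only is often
left unstated in applications; the pipeline uses calibration rows only,
avoiding leakage into the prediction set.

## LS-SVM

Training a binary least-squares SVM reduces to one linear system: with
\(A = K + I/\gamma\), the KKT conditions
\(\begin{bmatrix}0 & \mathbf{1}^\top\\ \mathbf{1} & A\end{bmatrix}
\begin{bmatrix}b\\ \alpha\end{bmatrix} =
\begin{bmatrix}0\\ y\end{bmatrix}\)
are solved by Cholesky block elimination
(\(b = \mathbf{1}^\top A^{-1}y / \mathbf{1}^\top A^{-1}\mathbf{1}\),
\(\alpha = A^{-1}(y - b)\)); the tests verify the residual of the full
KKT system below 1e−8 and agreement with a generic dense solve.
Multiclass wrapping is one-vs-one with majority vote, ties broken by
summed decision values (one-vs-rest would be a drop-in alternative; the
pairwise scheme keeps each subproblem small and balanced). The RBF width
\(\sigma^2\) defaults to the median pairwise squared distance of the
training rows (median heuristic) — tuning it is supported but optional,
since conventionally only \(\gamma\) is searched, over 100 log-spaced
points in \([1, 1000]\) (20 points in the test profile). Grid ties
resolve to the smallest \(\gamma\), then the smallest \(\sigma^2\).
Cross-validation is stratified by class and seeded; accuracy is pooled
over folds.

## Numerical choices and degenerate inputs

* Calibration errors out (naming line, pixel and band) wherever
  `white <= dark` — reference frames are controlled inputs, so silent
  masking would hide acquisition faults.
* Band trimming uses the closed interval `[930, 1700]`. On the default
  uniform 256-band grid over 874–1734 nm this keeps **228** bands; the
  count depends on the instrument's band-center table, and published
  tables for the same nominal range can give 229. The window is the
  specification; the count is derived.
* Zero-variance responses, empty masks, undersized scenes, `Q > p`,
  out-of-range latent counts and singular kernel systems are all hard
  errors with informative messages rather than silent repairs.
* Determinism: every stochastic routine takes an explicit seed;
  identical configuration and seed reproduce scenes, selections and the
  pipeline manifest bit for bit.

## Problem sizes used by the test-suite and examples

The shipped tests run the full 525-sample generator, Kennard–Stone at
525 rows, selector recovery experiments on 525 × 100 planted-signal
matrices (RF at `T` = 1000, 5 runs, 10 repetitions; SPA over all
starts), classifier checks over 20 seeds at 175 samples, and brute-force
oracle comparisons at ≤ 12 samples. These sizes were chosen as the
smallest at which the statistical claims are meaningful; the full-scale
RF profile (`T` = 10000, 50 runs) is the documented default for real
analyses.

## Known limitations

* ROI masks come from the generator (or integer-label images supplied by
  the user); no automatic bean segmentation is provided beyond what a
  simple reflectance threshold would give on external cubes.
* Only BIL-interleaved ENVI cubes are read; BSQ/BIP are not.
* The LS-SVM stores all training rows (dense kernel); fine for hundreds
  of samples, not tens of thousands.
* No spectral preprocessing (smoothing, SNV, derivatives) is applied
  anywhere — matching the workflow this package implements, which used
  none.
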