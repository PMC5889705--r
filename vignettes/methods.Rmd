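---
title: "Methods: forest-cover mapping, poststratified area estimation, and presence modelling"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: forest-cover mapping, poststratified area estimation, and presence modelling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

This vignette is the package's own account of its models and the design
choices behind them. It states no empirical result that the test suite or
`scripts/acceptance.R` does not itself compute.

## 1. The workflow

`pinyon` chains five stages, each usable on its own:

1. a seeded **synthetic landscape generator** (DEM, coarse climate grids,
   cover truth, reflectance bands, stratified reference samples);
2. **spectral bookkeeping** — resampling coarse bands to the fine grid,
   NDVI, and a fixed-order 11-feature stack;
3. **terrain derivatives** — Horn slope/aspect, the terrain ruggedness
   index (TRI), and the vector ruggedness measure (VRM);
4. a **backpropagation neural-network classifier** producing a class map
   and a winning-probability map;
5. **design-based accuracy and area estimation** from an error matrix,
   and an **association stage** linking pine presence to terrain/climate
   covariates.

## 2. Design-based accuracy and area estimation

This is the statistical core. The error matrix holds sample counts
$n_{ij}$ with map classes $i$ in rows and reference classes $j$ in
columns (the row/column convention is fixed and validated), mapped areas
$A_i$, total area $A$, and weights $W_i = A_i / A$. The poststratified
estimators are

$$\hat p_{ij} = W_i \frac{n_{ij}}{n_{i\cdot}}, \qquad
  \hat p_{\cdot j} = \sum_i \hat p_{ij}, \qquad
  \hat A_j = A\,\hat p_{\cdot j},$$

with the stratified standard error

$$S(\hat p_{\cdot j}) = \sqrt{\sum_i W_i^2\,
  \frac{r_{ij}(1 - r_{ij})}{n_{i\cdot} - 1}}, \qquad
  r_{ij} = \frac{n_{ij}}{n_{i\cdot}}, \qquad
  S(\hat A_j) = A\,S(\hat p_{\cdot j}).$$

Overall accuracy is $\hat O = \sum_j \hat p_{jj}$; user's accuracy
$\hat U_i = \hat p_{ii}/\hat p_{i\cdot}$; producer's accuracy
$\hat P_j = \hat p_{jj}/\hat p_{\cdot j}$. These assume the reference
sample is stratified by the *map* class (which is exactly how the
pipeline draws its assessment sample) and that reference labels are
error-free.

Numerical and reporting choices:

* All proportions are carried in full precision; rounding to the 3–4
  decimals of a printed table happens only in `print.area_report()`.
* The area interval is reported both as $1.96 \cdot SE$ (the conventional
  approximate 95% multiplier, the `ci_multiplier` default) and as
  $2 \cdot SE$, because published area margins are often the latter
  rounding of the same interval; both columns are labelled.
* Kappa is computed on the raw counts by default, with an
  area-proportion basis as an option — published reports rarely say which
  basis produced their value, and the two differ.
* Degenerate inputs: a map stratum with zero samples is an error naming
  the stratum; a single-sample stratum with off-diagonal counts leaves
  the variance undefined and errors; an all-zero reference column yields
  `NA` producer's accuracy rather than an exception; a class with zero
  mapped area but sampled rows is a consistency error.
* The variance formula is validated in the suite against the empirical
  standard deviation of 2,000 Monte-Carlo stratified resamples of a fixed
  generating map (10% relative tolerance).

## 3. The classifier

A single-hidden-layer perceptron with logistic activations in both
layers, trained by gradient descent on squared error and monitored by the
root-mean-square (RMS) error over all output units. Defaults: 8 hidden
units, learning rate 0.20, stop at RMS ≤ 0.04 or 500 passes, weights
initialized uniform(−0.5, 0.5) from the seed. Features are min–max scaled
to [0, 1] with constants computed from the training rows only (a constant
feature is rejected by name); targets are one-hot; the predicted class is
the argmax of the four output activations with ties broken by the lowest
class index, and the probability map reports the winner's share of the
activation total.

**Update regime.** The default performs one weight update per training
sample in a seeded, reshuffled order ("pattern" mode), counting one pass
over the data as one iteration. The alternative single full-batch update
per iteration is available (`train_config(update = "batch")`) but at the
same learning rate descends far too slowly to reach the 0.04 stopping
level in any realistic number of passes — a training rate of 0.20
combined with convergence in a few tens of iterations is only coherent
under per-pattern updates, which is why pattern mode is the default.
Momentum is not used. The forward pass is unit-tested against
hand-evaluated two-layer arithmetic at $10^{-12}$, and the trained
network is cross-checked against an independent reference implementation
(`nnet`) on a separable two-blob problem.

Hidden-layer width, initialization range and update regime are recorded
on the model object, since none of them is externally fixed.

## 4. Terrain metrics

* **Slope/aspect**: Horn's 3×3 finite differences; slope in degrees;
  aspect in degrees clockwise from north of the downslope direction,
  `NA` on zero-gradient cells (a flat cell has no aspect). Border cells
  use edge replication by default; a `border = "nodata"` flag blanks the
  outer ring instead.
* **TRI**: per-cell elevation change against the eight neighbours.
  The default is the square root of the summed squared differences; the
  summed and mean absolute difference variants (the latter being the
  GDAL/QGIS convention) are switches, because the field's prose
  definitions are ambiguous among them. Nodata neighbours are excluded
  with count adjustment. TRI is shift-invariant and scales linearly with
  the DEM — both asserted as properties.
* **VRM**: unit surface normals $(\sin s \sin a, \sin s \cos a, \cos s)$
  (flat cells contribute $(0,0,1)$), resultant length $|R|$ over an odd
  $w \times w$ window (default 3), $\mathrm{VRM} = 1 - |R|/n \in [0,1]$.
  Zero on any plane regardless of tilt — asserted directly, since VRM is
  *not* invariant under vertical scaling on curved terrain.

All three kernels are verified to $10^{-10}$ against naive double-loop
oracles on random 12×12 DEMs.

## 5. The synthetic generator: what it emulates, and what it does not

The generator reproduces the *statistical structure* the downstream
stages assume, not geographic realism:

* **DEM**: a superposition of seeded Gaussian bumps (default 8, widths
  0.20–0.45 of the short grid side) plus low-amplitude smooth noise,
  rescaled affinely to exactly 280–1,662 m. Gaussian bumps were chosen
  over fractal noise because they are seedable, smooth enough for
  meaningful slope/aspect, and have controllable width.
* **Climate**: the warm-month mean temperature (MTWM) grid is a
  lapse-rate transform of block-mean elevation (higher blocks cooler)
  plus block-level noise, constant within 8×8-cell blocks and clipped to
  23.5–25.2 °C. Block-constancy deliberately reproduces the resolution
  mismatch of draping an ~800 m climate surface over a 10 m scene. Two
  pure-noise covariates ship alongside for screening tests.
* **Cover truth**: cells at or above the pine floor (default 1,010 m, a
  published lower elevation limit for these stands; configurable) are
  pine with probability
  $\mathrm{logit}^{-1}(\beta_0 + \beta_T\,\mathrm{TRI} +
  \beta_M\,\mathrm{MTWM} + \beta_V\,\mathrm{VRM})$; the rest grade
  desert floor → scrub → chaparral by elevation bands (500 m, 900 m)
  after ~60 m of seeded dither, mimicking interdigitated ecotones.
* **Truth-model defaults**: slopes keep published field magnitudes and
  signs (TRI +0.178, MTWM −1.159, VRM +28.476). The intercept default is
  22.0 rather than a published value: the synthetic DEM compresses a
  whole sierra's relief into a small grid, so its cell-to-cell TRI runs
  above the 15-m-DTM field scale, and the published intercept would
  saturate the eligible zone at pine probabilities near 1. The intercept
  was calibrated once, against the generator's own statistics, to centre
  the eligible-zone linear predictor near zero.
* **Spectra**: per-class mean reflectance per band plus Gaussian noise
  (default sd 0.006), clipped to [0, 1]. B4/B8 means put each class's
  noise-free NDVI at the centre of its target interval (pine 0.30–0.41,
  chaparral 0.24–0.28, scrub 0.10–0.15). Reflectance clipping, not
  12-bit digital-number scaling, is used; NDVI is scale-invariant anyway.
  Six bands can be aggregated 2× and resampled back to emulate the mixed
  10/20 m acquisition.
* **Reference sampling**: stratified, without replacement (the
  replacement policy is not externally fixed; without replacement matches
  how ground campaigns revisit distinct plots), exactly the requested
  count per class. The default allocation (536/764/405/438, totalling
  2,143) mirrors a published survey's class allocation, which is exposed
  as a free parameter since only the "at least 400 per class" rule is
  documented.

Passing tests on this generator show the *estimators and the pipeline
plumbing* behave as designed under a known truth; they do not show that
real imagery is this separable. Real scenes add atmospheric residuals,
mixed pixels, spatially correlated noise, label error in the reference
data and co-registration error, none of which is simulated. The spectral
noise dial exists precisely to degrade separability, and a suite property
checks that hold-out accuracy decreases (non-strictly) as the dial rises.

## 6. Association stage

Kruskal–Wallis two-group screening uses the rank statistic with tie
correction and a $\chi^2_1$ p-value; an all-tied sample returns
$H = 0, p = 1$ by convention. The Bonferroni level is taken as
α = 0.0005 verbatim (it is treated as a given of the protocol, not
re-derived from the covariate count). Collinearity pruning walks the
stage-1 survivors in ascending-p order and drops the larger-p member of
any pair with $|r_s| > 0.7$ — the ordering makes the keep/drop outcome
deterministic, and every decision is logged in the report. Nothing
surviving stage 1 is flagged, not an error.

The logistic model is fitted by IRLS via `stats::glm(binomial)` — the
standard tool, not re-implemented — and the suite checks it against a
direct BFGS maximization of the binomial log-likelihood at $10^{-6}$.
Perfect separation is detected (separation warning plus vanishing
deviance or exploding standard errors) and reported as an error naming
the covariate with the largest standardized estimate. The package fits
the screened set in one final model; backward elimination is not
performed because "stepwise" protocols are under-specified and the
screened set is already small.

Cross-validated random forest: stratified seeded folds (every fold must
contain both classes), `randomForest` as the learner, and in-package
metrics per fold — AUC by the tie-corrected Mann–Whitney rank
formulation, sensitivity/specificity at a fixed 0.5 threshold (no
threshold is externally specified, and 0.5 matches the logistic
decision point), TSS = sensitivity + specificity − 1 (an exact identity,
asserted per fold), and binary kappa.

## 7. Pipeline and reproducibility

Stages hand off through files (ESRI ASCII grids, CSV tables, JSON
reports) so each stage is independently rerunnable and inspectable; a
manifest records per-stage wall time, file lists and an MD5 hash of the
serialized configuration, and every stage logs start/finish. ESRI ASCII
was chosen as the grid format because it is a plain-text standard
readable by GDAL/QGIS and diffs cleanly under version control. All
randomness derives from one root seed split into fixed per-stage
streams, so a rerun with the same configuration byte-matches its
reports, and individual stages can be reproduced in isolation.

The accuracy-assessment sample is drawn stratified by the *predicted*
map (as the estimators require), with truth labels read from the
generator's cover grid; mapped areas come from the predicted map's class
cell counts.

## 8. Problem sizes used by the suite

The suite exercises scenes of 24–100 cells a side. The end-to-end
property uses twenty 100×100 scenes at spectral noise 0.02 (enough noise
that assessment strata contain observable error), 150 training points
per class and 100 assessment points per predicted class, checking that
hold-out overall accuracy stays ≥ 0.85 and that the 1.96·SE pine-area
interval covers the generator's true pine area in at least 17 of 20
seeded runs (the binomial-slack version of nominal 95% coverage).
Parameter-recovery uses twenty 100×100 scenes with 800-point samples,
requiring each truth-model coefficient inside ±2 reported standard
errors in at least 90% of replicates. These sizes were chosen as the
smallest that keep the stratified estimators and the classifier in their
intended operating regime.

## 9. Known limitations

* No spatial autocorrelation in spectra or noise; per-cell independence
  makes classification easier than on real imagery.
* No atmospheric simulation, cloud masking, mixed pixels, or reference
  label error.
* The classifier is deliberately minimal (no momentum, no early-stopping
  validation split, no alternative learners for the mapping stage).
* Climate grids are block-constant stand-ins; no downscaling.
* Kappa is reported for completeness despite its known redundancy with
  overall accuracy.
* The placeholder georeferencing (synthetic affine origin, no CRS) means
  outputs are not drop-in GIS layers for a real site.
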