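---
title: "Methods: tiling, DAG-SVM subtype calls, and morphometric survival stratification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: tiling, DAG-SVM subtype calls, and morphometric survival stratification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

`rccpath` implements a complete histopathology analysis pipeline for renal
cell carcinoma (RCC) at desk scale: whole-slide tiling with background
removal, patch classification through a pluggable scorer, multiclass subtype
calls by a decision-DAG support vector machine (DAG-SVM) over learned
embeddings, tumor-probability heatmaps reduced to cleaned binary masks,
region and nuclei morphometry aggregated to patients, and survival risk
stratification by a two-level cross-validated lasso-Cox model. This
vignette explains each model, its assumptions, the tunable parameters, and
the numerical and design choices, in the order data flows through the
pipeline.

## Tiling and background removal

Slides are cut into square tiles of side $T$ (default 512 px) on a regular
grid with 50% overlap, i.e. stride $s = T(1-\mathrm{overlap})$; patch
origins are 0-based with half-open pixel bounds, enumerated row-major so
patch identities are reproducible. Partial tiles at the right/bottom edges
are dropped rather than padded: with 50% overlap the coverage loss is at
most one stride, and padding would fabricate pixels that the background
filter and the scorer would then see. The patch count is
$(\lfloor (W-T)/s \rfloor + 1)(\lfloor (H-T)/s \rfloor + 1)$.

A patch is discarded as background when at least a fraction $f$ (default
0.5) of its pixels have mean-RGB intensity strictly above a threshold
(default 210 of 255). The rule has a second reading — "the mean of the
brightest 50% of pixels exceeds 210" — which is close to equivalent in
practice and is available via `method = "brightest_mean"`; the
fraction-above reading is the default because it is monotone in the white
fraction and trivially auditable pixel by pixel. The threshold applies to
the per-pixel mean over the three channels, not per channel; for near-white
scanner background the two coincide.

## The patch scorer contract

Everything downstream needs only two operations from a scorer: `score()`
(a probability vector over classes per patch) and `embed()` (a fixed-length
penultimate-layer representation per patch). The bundled reference scorer
is deliberately small so the entire pipeline trains on a CPU in seconds: a
20-dimensional summary representation per patch (channel means and
standard deviations, an 8-bin intensity histogram, horizontal and vertical
gradient energy, dark/bright pixel fractions, and two channel-difference
terms) feeds a single-hidden-layer softmax network (`nnet`). Features are
standardized by training-set mean and standard deviation — the analog of
channel normalization in convolutional training. Training proceeds in
epochs of 25 optimizer iterations with warm restarts; the epoch with the
best validation accuracy is retained and training stops early after 5
epochs without improvement (at most 40 epochs). The hidden activations
(default dimension 16, always read from the scorer rather than hard-coded)
are the embeddings; a convolutional backbone exposing a 512-dimensional
penultimate layer plugs in behind the same contract without any change
downstream.

Data are split at the *slide* level (70/15/15 by largest-remainder
rounding): with 50% overlap, adjacent patches share half their pixels, so a
patch-level split would leak near-duplicates between folds. Two
class-imbalance remedies are provided: minority augmentation (vertical
flip, rotation in [-25°, +25°], and additive Gaussian pixel noise, each
applied independently with probability 0.5 to patches resampled with
replacement) and inverse-class-frequency sampling weights, under which each
class is drawn with equal expected frequency. The noise standard deviation
is 10 intensity units (clipped to [0, 255]); rotation fills exposed corners
by mirror reflection, so augmented patches never acquire background-colored
corners that would trip the filter.

## DAG-SVM subtype classification

The $N$-class problem is decomposed into all $N(N-1)/2$ pairwise linear
soft-margin SVMs, each fit only on the embeddings of its two classes
(libsvm backend; regularization constant default 1, exposed in the
configuration since no canonical value exists). Prediction walks a decision
DAG: keep an ordered candidate list, evaluate the classifier of the current
(first, last) pair, remove the loser, and repeat — exactly $N-1$
evaluations, asserted at every call. The node order is a fixed, configured
class order (default lexicographic): DAG predictions are known to be only
weakly sensitive to the ordering, and fixing it makes runs reproducible. A
margin of exactly zero eliminates the class later in the order — an
arbitrary but deterministic tie-break for a measure-zero event.

A DAG emits only a label, but ROC analysis needs a continuous score, so
per-class scores are the summed signed margins over all pairwise
classifiers involving that class (one-vs-one margin voting), the standard
continuous surrogate. The metric panel reports accuracy, per-class and
macro precision/recall, Cohen's kappa
($\kappa = (p_o - p_e)/(1 - p_e)$), and micro-/macro-averaged one-vs-rest
AUC computed by the rank-based (Mann-Whitney) estimator with ties counted
one half.

## Heatmaps, masks, and the one-third rule

Per-slide heatmaps assign each pixel the *mean* tumor probability of all
kept patches covering it. Averaging is the combination rule because it is
order-independent, idempotent under patch duplication, and agrees with the
single-patch value where there is no overlap; pixels covered by no kept
patch are absent (never zero — absence of evidence is not a low
probability). Heatmaps can be materialized at a configurable downsample
factor for gigapixel inputs; at package fixture scale the default is full
resolution, and all areas are reported consistently in the working scale's
pixel units, which leaves morphometric ratios and the survival
stratification unchanged.

The binary mask keeps pixels with probability strictly greater than 0.95.
Components are labeled with 8-connectivity (diagonal touches merge, which
matches the visual continuity of tumor regions); the largest component is
the main region, and every component smaller than one third of it is
removed. Both thresholds are strict inequalities. The slide-level score for
slide-wise ROC analysis is the fraction of kept patches with probability
strictly above 0.5.

## Morphometry

Each retained component yields area (pixel count), filled area (after hole
filling), convex area (pixels inside the convex hull of the component's
pixel centers), perimeter, major/minor axis lengths and eccentricity of
the ellipse with matching second central moments, solidity, and the ratios
perimeter/area and perimeter²/area.

Two numerical choices deserve note. *Perimeter*: counting boundary steps
with diagonal weight $\sqrt2$ systematically overestimates smooth contours
by about 5.5% (a digitization bias, not noise), so the boundary length is
measured on the half-level marching-squares contour of the zero-padded
mask and multiplied by Kulpa's staircase correction 0.948; on rasterized
disks and ellipses of radius ≥ 20 px this lands within ~0.5% of the
analytic circumference. The estimator is mildly biased *low* for
axis-aligned polygons, which is irrelevant to the blob-like regions the
pipeline measures. *Moments*: the per-pixel variance term 1/12 is added to
the eigenvalues of the pixel-coordinate covariance (the regionprops
convention), which keeps single-pixel and thin components well-defined.

The tumor feature set has a "total" block (each quantity summed over all
retained components, ratio features recomputed from the summed numerator
and denominator) and a "main region" block (the largest component alone).
The canonical 15-feature roster used for survival screening is the six
summed quantities plus perimeter-by-area in both blocks, plus main-region
eccentricity; solidity and perimeter²/area are also emitted but flagged
non-canonical, and the roster is selectable because the historical feature
list admits more than one reading.

Nuclei are segmented from high-probability patches by hierarchical Otsu
thresholding on mean-RGB intensity. The depth of the hierarchy is adaptive:
the darker stratum is re-thresholded while its intensity spread still
exceeds one third of the whole image's spread (at most three levels), so a
bimodal image stops after one cut while an image with background,
cytoplasm and nuclei takes a second. A final guard requires the accepted
stratum's mean intensity to be nucleus-dark (≤ 150), so blank bright
patches yield no nuclei; components under 15 px are discarded. The
segmenter sits behind a function contract, so a different method can be
swapped in without touching the survival stage. The seven nuclei features
are the totals over all nuclei of all analyzed patches of: area, convex
area, filled area, perimeter, major axis, minor axis, and eccentricity.
Per-slide features are averaged (unweighted) over each patient's slides.

## Survival stratification

The log-rank statistic, the Kaplan-Meier product-limit estimator, and risk
indexing are implemented in the package and tested against independent
enumeration oracles; the penalized and unpenalized Cox fits are delegated
to `glmnet` and `survival::coxph`, which are exactly the vetted optimizers
a practitioner would use.

The core procedure is a two-level cross-validation. In the outer loop each
patient is held out in turn; on the remaining $n-1$ patients a lasso-Cox
model is fit with the penalty chosen by inner 10-fold cross-validated
partial-likelihood deviance (the deviance-minimizing penalty); the held-out
patient is assigned to the high-risk group iff their linear predictor
exceeds the *median training* risk index, ties going to low risk. The
held-out outcome therefore never influences its own assignment, which is
asserted inside the loop. The assembled groups are compared with the
log-rank test, Kaplan-Meier curves, and a group-contrast hazard ratio. For
a univariate screen the same procedure runs per feature (for one feature
the lasso reduces to soft-thresholded univariate Cox; the design matrix is
padded with a zero column to satisfy the solver's two-column minimum, and
the pad provably receives a zero coefficient). Features with raw p < 0.05
enter the integrative model — raw, because the historical analysis did not
correct for multiplicity; a Benjamini-Hochberg flag is available. The
multivariate model fits the continuous leave-one-out (pre-validated) risk
index together with age, gender, stage, and grade, and reports Wald hazard
ratios with 95% intervals; because the risk index is pre-validated, its
hazard ratio is not inflated by in-sample fitting.

Degenerate cases are explicit: if every leave-one-out model is null the
risk indices are all zero, everyone falls to low risk, and the result is
flagged degenerate with no test. Under pure-noise features the
deviance-minimizing penalty yields the exactly-null model in roughly
three-fifths of fits; we call a fitted model "near-zero" when every
|coefficient| < 0.15, i.e. under 15% of the unit log-hazard used as a
realistic signal size throughout the package.

## The synthetic-data module

The generators define the package's study conditions and are first-class,
tested code. Slides are rendered as a near-white background (intensity
245 ± 3, floored at 212 so background always trips the 210 filter), a
rectangular tissue region textured as normal parenchyma, and a tumor
sub-rectangle covering a requested fraction of the tissue with a
class-specific texture (base color with Gaussian grain plus dark
chromatin-like blobs; all tissue base colors average strictly below 210 so
the filter separates tissue from background by construction). Region
corners sit on a 16-px lattice, giving ground-truth masks crisp,
reproducible boundaries. Nuclei scenes place non-overlapping dark ellipses
by rejection sampling and record analytic geometry ($\pi ab$, axes $2a$,
$2b$, orientation) for every rendered nucleus. Embedding clusters are
spherical unit-variance Gaussians at mutually equidistant centers, with
separation expressed in within-class standard deviations. Survival cohorts
draw event times from an exponential with hazard
$\lambda_0 \exp(x^\top\beta)$ and independent exponential censoring whose
rate is calibrated (by root finding) to the requested expected censored
fraction. Every generator is deterministic in its seed.

What the generators do *not* emulate — and hence what passing tests do not
establish about real slides: H&E stain variation and artifacts, irregular
tissue boundaries (regions are lattice-aligned rectangles), overlapping or
textured nuclei, non-proportional hazards, and informative censoring. The
tests demonstrate that the *procedures* are implemented correctly, not
that the reference scorer would classify real histology.

## Problem sizes and reproducibility

The demonstration configuration uses 192-px slides with 32-px subtype
tiles and 16-px heatmap tiles (both 50% overlap) — the two tile sizes
mirror using different magnifications for the subtype and survival tasks —
with 8 slides per subtype, 8 normal slides, and a 40-patient cohort whose
tumor fraction is $0.35 + 0.18z$ (clamped to [0.08, 0.95]) for a latent
driver $z$ with log-hazard 1 per unit and ~30% censoring. Simulation
checks use: 500 patients for univariate coefficient recovery, 1000 for
multivariate recovery of a stage log-hazard of 0.55, 200 patients x 20
replicates for stratification power, and 60 patients x 5 noise features
for size calibration. One seed determines every stochastic choice (slide
rendering, splits, network initialization, fold assignment, augmentation),
and rerunning any stage with the same seed reproduces its output exactly.

A caveat on calibration: because every patient's group assignment depends
on models trained on the *other* patients' outcomes, the assembled groups
are not fixed in the sense the log-rank test assumes. This is the known
anticonservativeness of pre-validated predictors (Tibshirani & Efron 2002;
Höfling & Tibshirani 2008): on pure-noise features the package's own
calibration check (`scripts/acceptance.R`, `twolevel_cv_type1_alpha05`)
measures a rejection rate above the nominal 5% — on the order of one and a
half to three times nominal at the simulated cohort sizes — rather than
exact size. The
stratification p-values should therefore be read as descriptive of the
historical procedure; a permutation recalibration would restore exact size
and is deliberately out of scope here because the goal is the procedure as
practiced.

## Known limitations

The reference scorer is a texture-summary model: adequate for the
synthetic fixtures and for exercising every downstream contract, but not a
substitute for a trained convolutional backbone on real slides. The
convex-hull area uses pixel centers, which underestimates hull area by a
boundary band of order the perimeter for very small components. The
one-third cleanup compares raw component areas with no morphological
closing beforehand. Leave-one-out outer folds make the stratification
$O(n)$ penalized fits per feature set, which is the main cost driver for
cohorts beyond a few hundred patients.
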