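# rccpath

Tools for a complete renal-cell-carcinoma (RCC) histopathology analysis
pipeline, built to run and be tested entirely at desk scale:

1. **Tiling & background removal** — slides are cut into overlapping square
   patches (default 512 px, 50% overlap) and a patch is discarded when at
   least half of its pixels have mean-RGB intensity above 210.
2. **Patch scoring & embeddings** — a pluggable scorer contract
   (`score()` → class probabilities, `embed()` → penultimate-layer
   representation) with a small CPU-trainable reference implementation,
   slide-level 70/15/15 splits, minority-class augmentation and
   inverse-frequency resampling weights.
3. **DAG-SVM subtype classification** — the N-class problem becomes
   N(N−1)/2 pairwise linear soft-margin SVMs over embeddings; prediction
   walks a decision DAG (exactly N−1 evaluations), and the metric panel
   reports accuracy, precision/recall, Cohen's κ = (p₀ − pₑ)/(1 − pₑ), and
   micro-/macro-averaged rank-based AUC.
4. **Heatmaps & tumor masks** — per-pixel mean tumor probability over
   covering patches; strict 0.95 masking; 8-connected components with the
   one-third-of-main-region cleanup.
5. **Morphometry** — region area, convex/filled area, perimeter
   (marching-squares boundary with staircase correction), second-moment
   axes and eccentricity, solidity, perimeter–area ratios; hierarchical
   adaptive Otsu nuclei segmentation; patient-level averaging.
6. **Survival stratification** — per-feature and integrative lasso-Cox
   risk indices inside a two-level cross-validation (outer leave-one-out
   assignment against the training median, inner 10-fold penalty
   selection), with in-repo log-rank and Kaplan–Meier estimators and a
   multivariate Cox model (risk index + age, gender, stage, grade).

A synthetic-data module generates tissue-like slides with ground-truth
tumor masks, nuclei scenes with analytic geometry, separable embedding
clusters, and survival cohorts with known hazard structure, so every stage
is testable offline. The intended audience is computational-pathology
researchers who want an auditable, fully seeded reference implementation of
this pipeline's statistical machinery.

## Worked example

```r
library(rccpath)
res <- run_all(demo_config(seed = 1))

res$classification$metrics$accuracy
#> [1] 1
res$mask_iou
#> [1] 1
res$survival$stratification
#> <risk_stratification: 22 low / 18 high; log-rank chi2 8.454, p 0.00364; HR 2.995 (1.385-6.477)>
head(res$survival$multivariate, 2)
#>     variable       hr ci_lower ci_upper     p_value
#> 1 risk_index 1.391391 1.126488 1.718586 0.002174637
#> 2        age 1.025372 0.988633 1.063477 0.178338130
```

Reading the output: the 3-subtype DAG-SVM classifies every held-out test
patch correctly on the demonstration textures; the cleaned high-probability
masks coincide with the ground-truth tumor masks (intersection-over-union
1.0); and the two-level cross-validated risk groups separate survival
(log-rank p ≈ 0.004, high-vs-low hazard ratio ≈ 3.0). In the multivariate
model the pre-validated risk index stays prognostic (HR per unit ≈ 1.39)
after adjusting for clinical covariates. The univariate screen table
(`res$survival$screen`) lists the per-feature log-rank p-values; the
tumor-burden features (total/main area, perimeter, axes) carry the planted
image–hazard association.

A thin command-line front end is included:

```sh
Rscript inst/cli/rccpath.R fixtures --out demo_data --seed 1
Rscript inst/cli/rccpath.R run-all  --out demo_run  --seed 1
```

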