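---
title: "Individual KLS structural covariance networks: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Individual KLS structural covariance networks: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(klsnet)
```

This vignette is the package's own account of the science it implements:
the model and its assumptions, the tunable parameters and their defaults,
what the synthetic generator does and does not emulate, the numerical
choices, and the design decisions that were genuinely open.

## 1. The model

### Regional distributions and KLS

A subject's brain is parcellated into regions of interest (ROIs):
116 AAL regions for voxel-based gray matter volume (GMV), 68
Desikan–Killiany cortical regions for the surface metrics (cortical
thickness CT, sulcal depth SD, fractal dimension FD, gyrification index
GI). Within each ROI the voxel- or vertex-wise values form an empirical
distribution. We estimate it with a Gaussian-kernel KDE, evaluate all of
a subject's ROI densities on one *common grid* spanning the subject-wide
minimum to maximum (so regions are directly comparable), convert to
probability masses, and compare region pairs with the symmetric
Kullback–Leibler divergence

$$D(P,Q) = \sum_i \Big[ P(i)\,\log\frac{P(i)}{Q(i)} +
  Q(i)\,\log\frac{Q(i)}{P(i)} \Big],$$

mapped through $\mathrm{KLS}(P,Q) = e^{-D(P,Q)} \in (0,1]$. The
similarity matrix with unit diagonal is the subject's individual
structural covariance network. The assumptions worth stating:

- *Distributional similarity is meaningful connectivity.* Two regions
  with similar value distributions are treated as "covarying" even
  though no temporal or tractographic information enters.
- *The common grid is subject-specific.* Absolute value scales cancel
  within subject; between subjects only the derived network topology and
  KLS weights are compared, never raw grids.
- *KDE smoothing is adequate at a few hundred samples per ROI.* Below
  ~10 samples density estimation is refused (`min_samples = 10`).

### Graph topology

Weighted KLS matrices are binarized by *sparsity*: at sparsity $s$, the
$k = \mathrm{round}(s\,N(N-1)/2)$ strongest edges are kept, so every
network has the same edge count at a given threshold. The grid is
0.05–0.30 in 0.01 steps (26 values) for 116-node networks and starts at
0.07 (24 values) for 68-node networks, which keeps the smaller graphs
connected. Per threshold we compute clustering `Cp`, characteristic path
length `Lp`, global and local efficiency, and nodal
degree/betweenness/efficiency/local-efficiency; `gamma = Cp/⟨Cp_rand⟩`,
`lambda = Lp/⟨Lp_rand⟩` and `sigma = gamma/lambda` are normalized against
degree-preserving Maslov–Sneppen rewired null networks (study-scale
default 1000 per threshold). Each metric is summarized across the grid
by its trapezoidal AUC, so no single threshold drives inference.

### Group statistics

Outcomes (regional means, nodal AUCs, edges) are compared across CN /
EMCI / LMCI by ANCOVA controlling age, sex, education and APOE ε4 —
plus total intracranial volume for GMV-derived outcomes. We report the
Type III F for the group block, partial $\eta^2 =
SS_{group}/(SS_{group}+SS_{error})$, adjusted means at covariate grand
means, and Bonferroni-corrected pairwise contrasts with Cohen's d from
the covariate-adjusted values and the full-model residual SD. Families
of tests (nodes per metric; all edges) are corrected with
Benjamini–Hochberg FDR.

### Subtype classification

Pairwise logistic regression on a 13-feature panel of local imaging
markers, under nested stratified cross-validation (10 outer / 5 inner
folds). Inside each outer training fold — and only there — features are
residualized on the covariates, min–max scaled, and filtered by
L1-penalized logistic regression (LASSO; penalty chosen by inner-CV mean
AUC); an L2-penalized logistic model is then refit on the selected
features with its own inner-CV-tuned penalty. Held-out probabilities are
pooled into one ROC; we report trapezoidal AUC and accuracy /
sensitivity / specificity at the Youden-optimal threshold, with
significance from a label-permutation test that reruns the *entire*
nested pipeline per permutation.

## 2. Tunable parameters

| Parameter | Default | Units / rationale |
|---|---|---|
| `m` (grid points) | 256 | power of two, matches common KDE toolboxes |
| bandwidth rule | `"botev"` | diffusion plug-in, automatic, scale-equivariant; `"silverman"` fallback for tiny/pathological samples |
| epsilon floor | 2.2e-16 | added to normalized masses, then renormalized (see §4) |
| sparsity grid | 0.05–0.30 / 0.07–0.30 | per atlas, step 0.01 |
| null networks | 1000 study-scale, 20 pipeline default | degree-preserving rewires, 10 swap attempts per edge |
| FDR alpha | 0.05 | BH step-up |
| penalty grid | 20 log-spaced values, 1e-3–1e3 | shared by LASSO selection and ridge refit |
| outer/inner folds | 10 / 5 | stratified, ±1 subject class balance |
| permutations | 5000 study-scale, 200 desk-scale | p ≥ 1/(B+1) |

## 3. The synthetic world

`generate_cohort()` draws, per diagnostic group, variables calibrated to
the study cohort's printed summaries: age, MoCA, ADAS-Cog-13, education
and CSF Aβ1-42 as (truncated) normals matched on mean/SD; MMSE as a
small discrete distribution whose 25/50/75% quantiles equal the printed
median and IQR; p-tau as a lognormal matched on the median and IQR ratio
(a lognormal cannot also match both printed quartiles exactly, because
the printed quartiles are not log-symmetric about the median); sex and
APOE ε4 at the printed frequencies. Three variables have no printed
summaries and are *invented, plausible* stand-ins: t-tau (lognormal,
group medians 70/95/115 pg/mL), TIV (normal, 1450 ± 140 mL) and the
Logical Memory II scores (drawn inside the group-consistent band of the
subject's education stratum).

Two calibration subtleties:

- **Truncation with mean matching.** CN requires amyloid negativity, so
  CN Aβ1-42 must lie at/above 192 pg/mL; EMCI/LMCI below. We solve (by
  `uniroot`) for the normal location whose *truncated* mean equals the
  printed group mean, so self-consistent labels and calibrated means
  coexist.
- **Cognition coupling.** `generate_roi_samples()` regenerates
  ADAS-Cog-13 as the group baseline plus a slope times the subject's
  *deviation* of mean affected-ROI value from its group expectation,
  plus noise. Using the raw regional mean instead would drag group ADAS
  means away from their calibrated values; the deviation form preserves
  calibration and the required sign (more atrophy ↔ worse cognition)
  both within and between groups.

Atrophy defaults (package choices, not reported quantities): GMV —
bilateral hippocampus + left thalamus at −0.3 SD (EMCI) and −0.8 SD
(LMCI) of the between-subject SD; CT — left entorhinal,
isthmus-cingulate and supramarginal at 0 (EMCI) and −0.6 SD (LMCI).
Sample counts per ROI are Poisson around 500 (GMV voxels) / 300
(surface vertices) with a floor of 10.

**What a green test establishes — and what it does not.** The generator
reproduces group means/frequencies, the labeling logic, localized mean
shifts, and an atrophy–cognition coupling. It does *not* emulate spatial
autocorrelation between neighboring ROIs, covariate–covariate
correlations (beyond APOE's association with group), scanner or
segmentation artifacts, within-ROI non-Gaussian shape, or longitudinal
structure. Green acceptance tests therefore establish that the
*machinery* is correct and well-calibrated under the stated statistical
world — they do not reproduce, and are not compared against, the gated
cohort's empirical effect sizes or classification AUCs.

## 4. Numerical choices

- **Bandwidth.** The diffusion plug-in rule solves its fixed point on a
  1024-bin dyadic histogram of the data standardized to [0, 1], making
  the selected bandwidth exactly affine-equivariant; Silverman's rule is
  the documented fallback when the fixed point cannot be bracketed.
- **Epsilon floor on the mass scale.** The floor that protects KL terms
  from zeros is added to the *normalized masses* (then renormalized),
  not to raw densities: densities carry units 1/x, so a constant density
  floor would break scale coherence (an affine rescaling of all samples
  must leave the network unchanged). With the mass-scale floor, rescaled
  inputs reproduce the matrix to ~1e-12.
- **Canonical summation.** Symmetric KL sums in ascending grid order and
  uses elementwise-commutative operations, so `D(P,Q)` and `D(Q,P)` are
  bit-identical.
- **Tie-breaking.** Binarization sorts by descending weight, then
  ascending lexicographic node-pair order — deterministic under tied
  weights.
- **Path length on disconnected graphs.** `Lp` averages over *connected*
  pairs only (with a connectedness flag); efficiency terms assign
  disconnected pairs a zero contribution.
- **BH arithmetic.** Adjusted p-values are computed as
  `p * (n/rank)`; since `n/rank >= 1`, the floating-point result is
  provably never below the raw p.
- **Matrix I/O.** 17 significant digits — lossless double round-trip —
  with symmetry/diagonal/range re-validated on read.
- **Seeds.** A single config seed is expanded into per-stage substreams
  (`derive_seed`), so toggling one pipeline stage cannot shift another
  stage's randomness; all derived seeds stay below 2^31.

## 5. Open design decisions, and how they were resolved

- *CN/EMCI Logical Memory II bands overlap* (e.g. scores 9–11 in the
  16+ education stratum satisfy both). Amyloid status disambiguates:
  A− → CN, A+ → EMCI, as the group definitions require.
- *Selection vs refit.* After LASSO selection the final per-fold model
  is an inner-CV-tuned L2-logistic refit on the selected features,
  reading "only features with non-zero coefficients were retained for
  the final model" as selection → refit. A single-feature selection
  falls back to an unpenalized logistic fit.
- *Scaled test values are not clipped* to [0, 1]: clipping would destroy
  monotone ordering of out-of-range test values.
- *Network density under sparsity thresholding* is fixed by
  construction, so the density comparison is implemented on the weighted
  matrix with absolute KLS cutoffs (`density_curve`) — a documented
  interpretation.
- *Config format is JSON*, not YAML: no YAML parser is available in the
  supported dependency set, and jsonlite round-trips the config hash
  deterministically.
- *Edgewise models are fit as one multi-response linear model* per
  design (QR once, all 6,670 edges simultaneously) — numerically
  identical to per-edge ANCOVA, verified in the tests against the scalar
  route.

## 6. Known limitations

- KLS is the only similarity implemented (no Jensen–Shannon variant);
  weighted-network metrics, modularity/rich-club analyses and multiclass
  classification are out of scope.
- The diffusion bandwidth uses a fixed 1024-bin histogram; for samples
  far larger than a few thousand values per ROI a larger dyadic size may
  be preferable (exposed via `bw_botev(n_hist=)`).
- The permutation test is embarrassingly parallel but runs serially;
  5000 study-scale iterations are compute-heavy on one core (~expect
  tens of minutes), which is why the pipeline default is 0/200.
- Statistical behavior tests are Monte-Carlo with pre-registered
  binomial bounds; they are calibrated to the stated synthetic world,
  not to any empirical dataset.
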