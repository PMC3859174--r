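---
title: "Methods: quantitative structure-bitter-taste modelling of peptides"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantitative structure-bitter-taste modelling of peptides}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bitterQSBR)
```

## The problem

Bitterness is an undesirable side property of peptides produced by
enzymatic protein hydrolysis and fermentation. Its potency is measured as
log(1/T), where T is the human sensory bitter-threshold concentration in
mol/L; higher values mean more bitter. A quantitative
structure-bitter-taste relationship (QSBR) model predicts log(1/T) from
computed molecular descriptors so that less bitter peptides can be
designed before any sensory panel is run.

This package implements a complete QSBR workflow around a curated set of
227 peptides and amino acids (2-14 residues, log(1/T) between 1.00 and
5.70) split 181/36/10 into training, test and validation partitions, with
the reference MLR/SVM/ANN predictions for every record. The workflow has
four layers: data handling and partitioning, descriptor computation and
selection, model building, and validation statistics.

## The reference model

The core predictor is a six-descriptor linear equation on the log(1/T)
scale:

log(1/T) = 5.45 + 0.10 SPAN + 0.32 Mor11v − 7.88 MSD − 1.55 HATS8u
− 5.39 G3p + 0.92 E3s

The descriptors and their roles:

* **SPAN** (Å) — radius of the smallest centroid-centered sphere
  enclosing all atoms; a molecular size measure. Bitterness grows with
  size, so its coefficient is positive.
* **MSD** — Balaban's mean-square topological distance,
  sqrt(Σ d²ᵢⱼ / (A(A−1))) over ordered atom pairs; decreases with
  branching and atom count.
* **E3s** — third-axis directional WHIM accessibility under
  electrotopological-state weights.
* **G3p** — third-axis directional WHIM symmetry under polarizability
  weights, in (0, 1].
* **HATS8u** — GETAWAY leverage autocorrelation at topological lag 8,
  unweighted: Σ over atom pairs at graph distance 8 of hᵢhⱼ, with h the
  diagonal of the molecular influence matrix H = M(MᵀM)⁻¹Mᵀ of the
  centered coordinates.
* **Mor11v** — 3D-MoRSE scattering sum Σᵢ<ⱼ wᵢwⱼ sin(s rᵢⱼ)/(s rᵢⱼ) at
  s = 10 Å⁻¹ with van-der-Waals-volume weights. The family is named
  one-based in s — Mor01 is s = 0 — so Mor11 is s = 10 Å⁻¹. This
  off-by-one is the easiest way to silently corrupt every value, which
  is why `morse()` takes the physical s, and `mor11v()` encodes the
  mapping once.

## Descriptor implementation choices

Descriptors are computed from their open literature definitions
(Todeschini & Consonni's handbook forms). Bit-compatibility with the
commercial descriptor engine used to build the original dataset is *not*
promised — its exact weight tables and normalizations are proprietary —
so all descriptor-level tests are property-based: closed-form values on
2-3 atom systems, brute-force oracles (direct enumeration for SPAN,
hand-built distance matrices for MSD, explicit influence-matrix algebra
for HATS), invariance under rigid motion and atom relabeling, and
exhaustive enumeration over all labelled trees on up to 7 nodes for the
claim that the path graph maximizes MSD.

Atomic property weights (van der Waals volume from Bondi radii,
atomic polarizability, and an electrotopological-state table built from
Kier-Hall terminal-atom intrinsic states) are carbon-scaled and shipped
as a CSV in `inst/extdata/`. Hydrogens are used only when explicitly
present in a conformer; none are ever added implicitly.

Degenerate geometry is a real concern for small peptides: a planar or
collinear conformer has no defined third principal axis. The WHIM
third-axis indices are then reported as 0 with a `degenerate` flag rather
than as an error, so batch runs survive glycine-like edge cases. The WHIM
symmetry index uses the information-content form
G = 1/(1 − (nₛ/n)log₂(nₛ/n) − (nₐ/n)log₂(1/n)), where an atom counts as
symmetric along an axis when another atom mirrors its score or it lies on
the axis plane, within a tolerance of 5% of the score spread; G is 1 for
a centrosymmetric score distribution and falls toward 1/(1+log₂ n) for a
fully asymmetric one. The accessibility index is the inverse weighted
kurtosis of the axis scores, Eₘ = λₘ²·Σw / Σwᵢtᵢₘ⁴.

## The synthetic generator

Real descriptor values for the 227 peptides cannot be recomputed without
the original conformers and descriptor engine, so every downstream stage
is exercised on synthetic data whose statistical structure mirrors the
study conditions:

* `gen_joint()` draws from a multivariate normal over (response, SPAN,
  Mor11v, MSD, HATS8u, G3p, E3s) with the published 7×7 correlation
  matrix. Marginal moments for E3s (0.21 ± 0.10), HATS8u (0.33 ± 0.13)
  and Mor11v (0.10 ± 0.40) are the published training statistics; SPAN,
  MSD and G3p moments are published nowhere, so the defaults (25 ± 9,
  0.35 ± 0.10, 0.15 ± 0.05) are placeholders chosen once to keep the
  equation's output inside the observed 1.0-5.7 activity range — they
  are config-exposed and clearly documented as not literature values.
  A printed correlation matrix rounded to two decimals can be slightly
  indefinite; it is repaired by clipping eigenvalues at 1e-8 and
  renormalizing the diagonal, and a matrix needing a shift larger than
  0.05 is rejected instead of silently repaired.
* `gen_equation_response()` applies the published equation and adds
  N(0, σ²) noise. The default σ = 0.43 is the training RMSE of the
  reference model. The equation block also prints "S.E.P. = 0.08",
  which is inconsistent with that RMSE; both numbers are kept in the
  package records and neither is silently reconciled — the RMSE scale is
  the one a regression noise model can actually use.
* `gen_wide_matrix()` builds the wide screening scenario: a few hundred
  columns with a small planted informative set, optional exact/near
  duplicates (for the intercorrelation rule) and near-constant columns
  (for the repeated-value rule), with truth labels returned.
* The response marginal (2.87 ± 1.00) matches the packaged activities.

What the generator does **not** emulate: non-Gaussian marginals, the
discreteness and length-clustering of real peptides, and any
nonlinearity in the true descriptor-activity relation. Passing
recovery tests therefore demonstrates that the pipeline machinery is
correct and well-calibrated at the study's size and noise scale, not
that the biological conclusions transfer.

## Selection cascade

Stage 1, `correlation_filter()`: drops constant columns, columns whose
modal value covers more than 90% of cases, and from every pair with
|r| > 0.99 the member less correlated with the response. The
repeated-value rule is stated ambiguously in the method source
("frequency of repeated values ... lower than 10% of cases"); it is
implemented as the >90%-identical rule and flagged as such. The filter is
idempotent by construction.

Stage 2, `iterative_gapls()`: variables are chunked into blocks of at
most 200; each block is scored by a genetic algorithm over binary
inclusion chromosomes whose fitness is the cross-validated percentage of
explained variance of a PLS regression (components chosen internally up
to 10); the top 50% of a block is carried forward, merged with the next
100 variables, and the process repeats until the pool is exhausted,
keeping the top 20% of the final round. GA internals follow Leardi's
published defaults where the method source is silent: population 30,
single-point crossover rate 0.5, per-bit mutation 0.01, 100 fitness
evaluations per run, 5-fold CV, sparse initialization at ~5 variables
per chromosome. Scores are run-to-run variable by nature; the per-variable
score is the selection frequency weighted by fitness, averaged over
independent runs, and the 50%-carry scheme (rather than a hard short
list) is what makes the iteration robust to that variability. Ties in
the carry sort are broken by score descending, then column position
ascending. The PLS1 core is a NIPALS implementation validated in the
test suite against an independent PLS implementation to machine
precision and against OLS in the full-component limit.

Stage 3, `stepwise_select()`: classical F-test forward selection with
removal (defaults 0.05 enter / 0.10 remove, the common statistical-
package convention), followed by a bivariate check that removes the
later entrant of any kept pair with |r| ≥ 0.9.

One design point deserves emphasis: inside the full cascade
(`select_descriptors()`) the stepwise entry level defaults to a
Bonferroni-adjusted 0.05/m, m the number of GA survivors. At every
forward step the *minimum* p-value over dozens of null candidates is
compared against the cutoff, so a flat 0.05 admits at least one spurious
variable in most runs regardless of signal strength; the adjusted level
makes a clean planted-truth recovery achievable while the standalone
`stepwise_select()` keeps its classical defaults for users who want the
textbook behaviour.

Problem sizes used in the recovery studies: n = 181, p = 244 with 6
planted informative columns and noise SD 0.43 (the study's training
scale); the GA budget is 20 independent runs per scored block in the
shipped analyses, which recovers the planted six exactly in ~85% of 20
seeded repeats. The method default of 100 runs per block is available
through `gapls_config()` when runtime is no concern.

## Models

* `fit_mlr()` — ordinary least squares on the raw descriptor scale, so
  coefficients are directly comparable with the published equation;
  reports SEs, R², adjusted R², F and SEP, and refuses rank-deficient
  designs naming the collinear columns.
* `fit_svr()` — ε-insensitive support vector regression with an RBF
  kernel; defaults C = 91, ε = 0.07, γ = 0.06 (the published tuned
  optimum). Features are z-scored on training statistics; whether the
  original study standardized inputs is unstated, but a γ of 0.06 is
  only plausible on a standardized scale, and standardization is the
  package's choice. `tune_svr()` grid-searches by cross-validated RMSE
  with a fold assignment fixed per seed (paired comparisons across
  cells); ties prefer smaller C then larger ε, the more regularized
  model.
* `fit_ann()` — one hidden layer of bounded-sigmoid (tanh) units with a
  linear output, trained by Levenberg-Marquardt damped least squares on
  z-scored inputs and response, with an internal random 70/15/15
  train/validation/test split and early stopping on the validation part.
  The method source's phrase "the number of hidden layers was three" is
  read as three hidden *neurons* in one hidden layer, consistent with
  the default single-hidden-layer architecture of the network tool it
  names; `ann_config()` exposes the count. Training runs in bursts of 10
  LM iterations between validation checks, keeps the best-validation
  weights, and stops after 6 checks without improvement or at 1000
  iterations. Columns are sorted into a canonical order before weight
  initialization so that column permutation cannot change the fitted
  network; with the split and initialization drawn from the config seed
  the fit is fully reproducible.

## Validation statistics

Error statistics are percentage-deviation based: IPD = 100|ŷ−y|/y per
point, MPD the mean (± SD) of the IPD series, and ILRSD the
corresponding inter-laboratory replicate statistic
(100/N)Σ|Y−Ȳ|/Ȳ. IPD frequencies are binned as [0,15), [15,30], (30,∞);
both boundary points belong to the middle bin.

Goodness of fit uses R² = squared Pearson correlation of observed and
predicted — the whole-set and per-partition tables report both R and R²
consistently under that reading — with RMSE, adjusted R² and F in their
standard OLS forms. Cross-validated q² = 1 − PRESS/SS_total with
held-out predictions and SS_total against the overall mean; the
leave-many-out scheme uses 10 folds by default. Y-randomization refits
on shuffled responses and reports the per-shuffle training R².

External validation implements the standard criteria suite: R² > 0.6;
the through-origin slope/ratio condition in both orientations,
((R²−R₀²)/R² < 0.1 with 0.85 ≤ K ≤ 1.15) *or* the primed counterpart,
so the K/K′ orientation ambiguity cannot flip an overall pass; the gap
condition |R₀² − R₀′²| < 0.3; and Roy's Rm² = R²(1 − √(R²−R₀²)) > 0.5.
The source prints the Rm² formula garbled ("R2(1-R2-R02)"); the
canonical Roy form is used, which is the only reading internally
consistent with the printed test-set values (R² 0.723, ratio 0.001,
Rm² 0.704 require R₀² ≈ 0.722). R₀² is the through-origin coefficient
with predicted values as the regressor (observed fit by K·predicted) —
the orientation that reproduces those printed numbers — and R₀′² is the
reverse; both are always reported. Statistics recomputed from the
packaged 2-decimal predictions inherit rounding at the ±0.02 level, and
MPD at roughly ±0.3 of a percent point.

## Partitioning, outliers and degenerate inputs

Training/test/validation splitting clusters the standardized feature
block with k-means (k-means++ seeding, Euclidean distance, 10 clusters
by default) and allocates each cluster's members to the partitions in
the requested proportions (79/16/5 by default) by largest-remainder
rounding, most-typical members (nearest the centroid) going to training
first. The method source does not state its per-cluster allocation rule;
this proportional rule is the package's choice, and realized fractions
deviate from the request by at most one record per cluster. Outlier
screening is the two-view convention: standard scores in response space
(cutoff 3, at which the packaged activities flag nothing) and a PCA
score map in descriptor space with component signs fixed by the
largest-magnitude loading.

Degenerate inputs are rejected loudly rather than patched: zero-variance
responses, disconnected bond graphs for topological descriptors,
rank-exceeding PCA requests and non-PSD-beyond-repair correlation
matrices all raise errors naming the problem.

## Known limitations

* Descriptor values are not bit-compatible with the commercial engine
  behind the original dataset, so the published descriptor-selection
  membership and the LOO q² of the original descriptor matrix cannot be
  and are not reproduced; their substitutes are the planted-truth
  recovery studies.
* The ANN is a small fixed architecture; it demonstrates the nonlinear
  headroom of the dataset, not an optimized predictor.
* SPAN/MSD/G3p synthetic marginals are placeholders (see above).
* The GA is a stochastic search: kept sets differ across seeds by
  design, and all shipped analyses fix and report their seeds.
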