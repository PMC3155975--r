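---
title: "Consistent expression indices across analogous cohorts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Consistent expression indices across analogous cohorts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ceindex)
```

## Motivation and model

Expression cohorts profiling the same disease entity can be viewed as
samples from a common "expression space": a modest number of latent
biological programs (proliferation, immune infiltration, stromal content,
...) drive most between-tumor variation, while each cohort adds its own
technical and population idiosyncrasies. A principal component estimated
in one cohort mixes both. The premise of this package is that the
*reproducible* part can be isolated by requiring components to recur
across several cohorts, without ever looking at outcome labels — an
unsupervised route to transferable metagenes.

Formally, each cohort's log2 expression matrix is modeled as
`X = baseline + L·A + E`, with shared loadings `L` for programs common to
all cohorts, per-cohort activities `A`, and cohort-specific structure
folded into `E`. The pipeline estimates the column space of `L` piecewise
(per-cohort PCA), identifies which estimated axes agree across cohorts
(CPC clustering), and compresses the agreement into sign-weight metagenes
(CEIs).

## The pipeline and its tunable parameters

**CV filter** (`cv_filter`, bounds 1 and 1000, dimensionless). The
coefficient of variation is computed on the anti-logarithm of the log2
values — CV = sd(2^x)/mean(2^x), sample sd — because fold-change
variability, not additive log-scale variance, is what distinguishes a
regulated transcript from a flat one. For a log-normally distributed
anti-log value the CV depends only on the log-scale spread
(CV = sqrt(exp(σ_ln²) − 1)), so a feature needs a log2 sd of roughly 1.2
to clear the lower bound of 1; the upper bound of 1000 guards against
pathological rows. A log2 *shift* multiplies the anti-log row and leaves
the CV unchanged — the filter is insensitive to probe-level baseline
offsets by construction.

**PCA** (`fit_pca`). SVD of the row-centered matrix, no variance scaling:
the CV filter has already equalized dynamic range, and scaling would
discard the very differences in spread the method exploits. Each
component's sign is fixed by making its largest-magnitude weight positive,
so results do not depend on the linear-algebra backend. `ω_j` is the
explained standard deviation (square root of the j-th eigenvalue), and
total variance is conserved: Σ_j ω_j² = Σ_i σ_i².

**BIC component count** (`select_k_bic`, `k_max` default min(n−1, 20)).
The unexplained variance at k components is the residual sum of squares
ν_k = Σ_i σ_i² − Σ_{j≤k} ω_j², and the criterion is the Gaussian-residual
form `BIC(k) = n·ln(ν_k/n) + k·ln(n)`. This uses exactly the ingredients
the method calls for (n, k, ν) and, on cohorts in the realistic regime
simulated here, selects the 3–6 leading components one expects from bulk
tumor profiles. The functional form is an argument (`form`) so
alternatives can be slotted in; a perfect fit (ν_k ≤ 0) is capped at
−∞ and returned with a warning. Note that for very small cohorts
(n − 1 ≤ p and n − 1 ≤ k_max) the rank limit itself is a "perfect fit"
and the cap triggers trivially; k_max should be kept below n − 1 in that
regime.

**Distillation** (`distill_pc`, `alpha` default 0.01). Each selected PC is
reduced to the features whose Pearson correlation with its scores is
significant by a two-sided Student's t-test (t = r√(n−2)/√(1−r²), n−2 df).
Two-sided is the conservative choice given that component orientation is
arbitrary; the correlation sign is retained separately. At alpha = 0.01 a
cohort of independent noise features is included at ~1%, which the test
suite verifies by simulation.

**Jaccard–cosine dissimilarity** (`pc_dissimilarity`). Two distilled PCs
are compared through J (Jaccard index of representative sets) and C
(cosine of the PC weight vectors restricted to the common features). The
default combination is `d = 1 − J·|C|`: zero iff the sets coincide and
the common weights are collinear, one for disjoint sets, bounded in
[0, 1], and invariant to either component's sign. The product form is
deliberately strict — a pair must agree both in membership and in weight
geometry — and an additive alternative (`1 − (J+|C|)/2`) is available
behind the `method` argument. Cosine uses the PC *weights* (loadings),
not correlations, on the intersection.

**CPC clustering** (`cluster_pcs`, `cut_height` default 0.9). Average
linkage on the pooled dissimilarity matrix, tree cut at 0.9, clusters
with at least two members kept. The generous cut reflects the strictness
of the product dissimilarity: same-program PCs from different cohorts
typically sit at d ≈ 0.1–0.3, while unrelated PCs sit near 1, so the cut
mostly separates "related at all" from "unrelated". A cluster's gene set
is the features representative in at least two of its members — single-PC
evidence is never enough. Whether members span ≥ 2 cohorts is recorded
but not enforced; within-cohort duplicate PCs would make consistency
vacuous, and the report makes that visible.

**CEI derivation** (`derive_ceis`, `n_factors`, `threshold` default 0.1).
CPC-gene z-scores are computed per cohort (removing cohort location and
scale — the only batch correction the method needs) and merged. Factor
analysis with varimax rotation is the classical tool here: maximum
likelihood is the default extraction, with iterated principal-axis
factoring as the alternative and as the automatic fallback when genes
outnumber samples (the ML discrepancy requires a full-rank sample
correlation). Factor scores are Thomson regression scores computed
through the model-implied correlation (Woodbury identity), which remains
well-defined for p > n. Per-factor gene coefficients are the least-squares
regression of each gene's z-scores on the factor scores; coefficients
below 0.1 in magnitude are zeroed and the surviving signs are the CEI
weights. Whether the "least-squares coefficients" are regression
coefficients or rotated loadings is isolated behind `coef_type`; the two
differ only in scaling under an orthogonal factor model, and the
downstream statistics (AUC, median split) are invariant to positive
scaling. Factors are ordered by post-rotation variance explained and
sign-fixed (largest coefficient positive), giving stable CEI1..CEIn
identities. The default factor count in `cei_fit` is the number of CPC
clusters found — the factor analysis is asked to re-express exactly the
consistent structure the clustering identified — and is exposed as a
parameter because different tumor types warrant different counts.

**Scoring** (`score_cei`). A cohort is scored by the *sum* of sign-
weighted within-cohort z-scores. Sum versus mean is cosmetic (positive
scaling), and per-cohort z-scoring makes scores invariant to per-gene
affine transformations of the target cohort, verified in the tests.
Missing genes are dropped, never imputed; coverage is reported and a
warning is raised below 50%.

**Clinical evaluation** (`roc_auc`, `km_cox_median_split`,
`evaluate_ceis`). The ROC is traversed over distinct thresholds (ties
cross simultaneously) and integrated by the trapezoidal rule; computed on
the integer TP/FP lattice this equals the Mann–Whitney U statistic (half
credit per tie) over n⁺·n⁻ *exactly*, and the test suite asserts bitwise
equality against a brute-force pair count. Significance is the two-sided
Wilcoxon rank-sum normal approximation with tie correction. Survival uses
administrative censoring at the horizon (5 or 10 years), a median split
(score ≤ median goes to the low group, so odd cohorts put the median
sample low), a Cox fit on the group indicator (Efron ties, survival
package) and the log-rank P. P values across CEIs are reported raw, with
an optional Benjamini–Hochberg column.

**Subtyping** (`assign_subtype`). Cohorts are stratified by PAM
(k-medoids) on the two marker features ESR1 and ERBB2 (configurable, so
the tool is not tied to one array platform). The qualitative rule —
the double-negative subtype shows consistently low expression of both
genes — is operationalized as: the
double-negative cluster is the one whose medoid has the smallest sum of
the two marker values. The cluster count is not dictated by the method;
the default k = 4 matches the natural marker geometry (double-negative,
ER+, HER2+, double-positive) and k = 2 or 3 work for cohorts lacking one
arm.

## What the synthetic generator emulates — and what it does not

`simulate_cohort_family` plants: shared factors with identical loadings
in every cohort on disjoint gene blocks; one private factor per cohort on
its own block; Gaussian noise; per-cohort per-gene offsets (batch);
log-normal-style dynamic range (`signal_scale`, log2 units) so that
signal genes pass the anti-log CV filter at its default bounds while flat
genes fail it; a logistic response link and an exponential survival link
on the shared-factor activities, with uniform censoring tuned to ~30% at
the default hazard (10-year-follow-up regime).

Two generator decisions matter for identifiability and are deliberate
design, not incidental defaults:

* **Distinct factor strengths.** Shared blocks default to 120/60/30 genes
  and the private factor is smaller and weaker (20 genes, loading 0.6
  versus 0.8). PCA can only align components with factors whose
  eigenvalues are separated by more than the sampling fluctuation
  (~λ√(2/n)); near-equal strengths would make the leading components an
  arbitrary rotation of the factor space and the cross-cohort consistency
  question ill-posed. Real expression programs likewise differ strongly
  in variance share.
* **In-sample orthogonal activities.** Factor activities are decorrelated
  (QR) within each cohort. Independent draws correlate at ~1/√n with
  tails beyond 0.3 at n = 60–80, which tilts sample PCs across gene
  blocks and makes "the planted factor" ill-defined as a PCA target. With
  exact in-sample orthogonality, the planted truth is what PCA estimates.

What the generator does **not** emulate: probe-level microarray physics
and normalization artifacts, heavy-tailed or count noise, correlated gene
blocks (co-expression within a block beyond the single factor),
overlapping programs sharing genes, missing values, and outcome links
that involve private factors or nonlinearities. Passing the test suite
therefore demonstrates that the implementation recovers planted linear
factor structure under realistic sizes and noise — not that the method
will isolate biology in any particular real data set.

Default sizes (5 cohorts, 1000 genes, 40–80 samples per cohort, 60 by
default) mirror the regime of multi-cohort subtype studies; tests and the
acceptance script use 40–80 samples and up to 6 cohorts so the full suite
runs in well under a minute.

## Numerical choices and degenerate inputs

* PCA keeps min(p, n−1) components (a centered matrix has rank ≤ n−1);
  component signs are fixed deterministically.
* Probe collapse keeps the probe with the largest sample sd per gene;
  ties break by file order, making the collapse deterministic.
* Zero-variance features: CV 0 (filtered out); correlation with a PC is
  undefined and treated as 0 (never representative); zero-variance genes
  are dropped from the z-score merge with a warning.
* An empty representative set is an error at the `distill_pc` level
  (with advice to relax alpha), but `cei_fit` skips such late,
  noise-dominated components with a message rather than aborting a whole
  derivation.
* Median ties in the survival split all go to the low group, keeping the
  groups as nearly equal as possible and the rule deterministic.
* Cox fitting uses Efron tie handling and a 1e−9 Newton tolerance.
* `factanal`'s default starting uniquenesses need an invertible sample
  correlation; when that fails (p close to n) a flat deterministic start
  is used, and for p ≥ n the extraction falls back to principal-axis
  factoring with a message.
* All simulation randomness flows from one seed; generators save and
  restore the caller's RNG state.

## Known limitations

* The cut height (0.9) and the dissimilarity form were chosen on
  simulated cohorts; real multi-cohort panels may need the exposed knobs
  (`cut_height`, `method`, `alpha`) adjusted, and the dendrogram plot
  (`plot(fit)`) is the diagnostic to look at first.
* With few samples per cohort (n ≲ 25) the BIC's rank limit interacts
  with `k_max` (see above) and ML factor analysis gives way to
  principal-axis extraction; results are then more sensitive to the
  coefficient threshold.
* The least-squares coefficient threshold (0.1) is an absolute value on
  z-scored data; its false-inclusion rate grows as 1/√n_samples shrinks
  relative to 0.1, so very large merged panels will include more marginal
  genes per CEI, and very small ones fewer.
* Multivariate Cox adjustment (clinical covariates) is out of scope; the
  evaluation reports one model per CEI.
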