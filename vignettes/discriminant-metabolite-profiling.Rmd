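---
title: "Discriminant metabolite profiling with wheatms"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Discriminant metabolite profiling with wheatms}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wheatms)
```

## The problem

Untargeted UPLC-TOF-MS profiling of plant extracts yields a peak table:
hundreds of samples by thousands of features, each feature a (retention
time, m/z) pair with a peak-area intensity, and absence encoded as 0.
`wheatms` implements the chemometric workflow used to ask whether such
profiles discriminate genetically distinct groups — in the motivating
application, United States wheat market classes: tetraploid durum (DW)
versus hexaploid hard (HBW) and soft (SBW) bread wheat, with bread-wheat
subclasses defined by kernel colour and growth habit. The same machinery
applies to any feature table with a class structure.

The pipeline is: replicate averaging, two high-quality-ion filters,
Pareto scaling, PCA for unsupervised inspection, OPLS-DA for supervised
discrimination, single-linkage dendrograms of predictive scores,
S-plot + jack-knifed confidence intervals for biomarker ion selection,
and adduct-mass annotation of the selected ions.

## Filtering and scaling

Technical replicates of each biological line are averaged first
(`average_replicates()`); both filters then operate on the line-level
table:

* **Presence filter** (`filter_presence()`, default 0.8): a feature is
  kept iff in at least one class the fraction of lines with intensity
  strictly greater than 0 is ≥ 80%. "Present" means non-zero because the
  upstream peak-alignment software encodes a missing peak as 0. Because
  averaging precedes filtering, a line counts as "present" if any of its
  replicates showed the peak.
* **Mean-intensity filter** (`filter_mean_intensity()`, default 1.0): a
  feature is kept iff its mean intensity across *all* lines, pooled
  regardless of class, is ≥ 1.0.

Both bounds are inclusive, as stated by the cut-off criteria ("≥ 80%",
"≥ 1.0"). The filters are order-dependent and each stage emits a
`filter_report` whose counts chain (`n_before` of stage two equals
`n_retained` of stage one).

**Pareto scaling** (`pareto_scale()`) centers each feature and divides by
the square root of its sample standard deviation (n − 1 denominator —
the chemometrics convention, and the same denominator used for S-plot
covariances, so the two are mutually consistent). Columns with zero
variance become all-zero rather than NaN. The scaling parameters are
returned so held-out or new observations can be projected with
`pareto_apply()` using the training parameters only.

## PCA and OPLS-DA

`fit_pca()` is an ordinary eigendecomposition (via SVD of the centered
matrix). Auto component selection adds a component while a 7-fold
cross-validated Q2 improves by more than 0.01; held-out rows are scored
by projection onto the training loadings. That projection scheme is known
to be optimistic compared with element-wise deletion schemes; it is used
only as a stopping rule, never as a reported statistic.
`hotelling_ellipse()` supplies the 95% score-plot ellipse with semi-axes
`s_i * sqrt(2 (n^2-1) / (n (n-2)) * F(0.95; 2, n-2))` and flags
observations whose T² exceeds the critical value.

`fit_oplsda()` dummy-codes the K classes as indicator columns (centered
before fitting; PRESS is likewise computed on the indicator scale).
Orthogonal components are extracted and deflated *first*: each iteration
takes the leading NIPALS PLS component of the current matrix, removes
from its X-loading the part lying in the span of the class-predictive
weight directions (the singular subspace of X'Y), and deflates the
resulting orthogonal score/loading pair. Predictive components are then
fitted on the filtered matrix by standard NIPALS PLS2. Consequences that
the tests exploit:

* with `n_orth = 0` the model *is* NIPALS PLS2, verified against an
  independent eigendecomposition-based PLS oracle;
* predictive and orthogonal scores are orthogonal by construction;
* the explained-variation split is exact: R2Xp + R2Xo = R2X(cum).

At most K − 1 predictive components are allowed for K classes (two for
the three-class wheat model, one for two-class models). Component signs
are fixed so each component's largest-magnitude loading is positive,
removing the eigenvector sign ambiguity.

**Cross-validation** (`cross_validate()`): folds are stratified by class
and assigned by a seeded within-class shuffle, so every class appears in
every training split; the seed is a required, logged parameter.
`Q2Y(cum) = 1 − PRESS/SS` with PRESS accumulated over held-out dummy
predictions and SS the centered total sum of squares of the dummy
matrix. Per-component Q2 values use the first `a` predictive components
with the orthogonal filter fixed. Stratification requires
`k ≤ min(class size)`; the default 7 folds therefore drop to 6 whenever
the six durum lines are in the model. `k = n` is accepted as
leave-one-out. The matrix is scaled once on the full data before CV
(as the original software does); the scaling is not refitted per fold.

**Classification**: the predicted indicator vector is mapped through a
softmax to per-class scores and the argmax is taken. The softmax is a
monotone surrogate for a modeled class-membership probability — any
monotone choice yields the same argmax, hence the same
misclassification tables. Exact ties are broken by class order with a
warning. `fisher_exact_probability()` attaches to a confusion table the
generalized hypergeometric *point* probability of the observed table
given its margins, computed via `lgamma`; the point-probability
convention (not a tail sum) is the one that reproduces the published
table probabilities.

## Biomarker selection

`splot()` computes, per feature, the covariance and correlation of the
scaled feature with the first predictive score (sample n − 1 forms
throughout; the covariance scaling is documented here because published
S-plots do not state the denominator). `jackknife_cov_ci()` refits the
model with each CV segment deleted (grouped, delete-a-fold jackknife —
mirroring the CV-segment jackknife of the original software, not
delete-one), sign-aligns each refit's first score to the full model by
correlation, and forms
`cov ± t(0.975, k−1) * SE_jack`. A feature is significant when the
interval excludes zero. `select_discriminatory()` replaces the
publication's manual tail-picking with a reproducible rule: both
`|cov|` and `|pcorr|` must clear a threshold (defaults: their 95th
percentiles) *and* the interval must exclude zero; results are sorted
ascending by covariance so ions elevated in the positive-scoring class
appear last.

## Dendrograms

`single_linkage()` wraps single-linkage agglomeration on Euclidean
distances over the first one or two predictive score columns.
*Compactness* of a cluster is its merge height — read as "the distance
of the cluster node from 0" on the dendrogram axis, the only
interpretation consistent with how published node heights are used.
*Distinctness* is the gap from the node to its parent's height; the root
has no parent and gets distinctness 0 by convention. A known identity
ties the tree to an independent oracle: the root height equals the
bottleneck (maximum edge) of the Euclidean minimum spanning tree.
Display ordering sorts subtrees by leaf count ("by size"); this has no
numeric consequence.

## Annotation

`annotate()` matches an observed m/z against an offline compound table
under the 14 ESI+ adduct scan modes (M+H; M+Na; M+H−2H2O; M+H−H2O; M+K;
M+2Na−H; M+2H; M+3H; M+H+Na; M+2H+Na; M+2Na; M+2Na+H; M+Li; M+CH3OH+H)
with a default 10 ppm tolerance. Ion m/z is computed
electron-corrected: `(M + Σ carriers − z·m_e)/z`, so e.g. the proton
contributes 1.00727646 Da; this convention reproduces the printed mass
errors of the sodiated reference rows, which the uncorrected convention
does not. Neutral losses subtract neutral water; the methanol adduct
adds neutral methanol before protonation. Charges follow the adduct
names: +1 except M+2H, M+H+Na, M+2Na (2+) and M+3H, M+2H+Na, M+2Na+H
(3+). Hits are ranked by absolute mass error, ties on the integer AME
are all reported, and an empty result yields an NC row. Lipid Maps
categories map to broad polarity classes FA, ST → NP; GL, GP, PR, PK,
SP, SL → PL; ON, OS, NC → NC (overridable). A transcription of the
published discriminatory-ion table and a compound database derived from
it ship in `inst/extdata/` and load with `wheat_discriminatory_ions()`
and `wheat_compound_db()`. A handful of the printed integer mass errors
are not reproducible under either electron convention (they reflect the
search engine's internal masses); the neutral masses, which all
reproduce to 4 decimals, are the contract.

## The synthetic-data generator

Because the original wheat dataset was not deposited, every end-to-end
claim is exercised on `simulate_feature_table()`, whose defaults *are*
the study conditions: 45 lines (DW 6; HBW 27 split HRS 9 / HRW 8 /
HWW 6 / HWS 4; SBW 12 split SWW 6 / SRW 4 / SWS 2), 9 technical
replicates (405 rows), 3727 features, retention times 0–35 min, m/z
50–1500 Da. Feature roles:

* **markers** (10 by default): a 3× multiplicative shift planted at the
  line level in their elevated class group, alternating between durum
  and the pooled bread-wheat classes — the study's primary contrast.
  Planting at the line level (not per replicate) means replicate
  averaging helps recovery, mirroring the average-then-filter order.
* **noise features** (2420): absent in each *line* with probability 0.6.
  The dropout draw is shared by a line's replicates — the compound is
  absent in that line — because a per-replicate draw would almost never
  survive averaging over 9 replicates and the presence filter would have
  nothing to remove. `expected_filter_survivors()` gives the exact
  binomial survival probability of the ≥80%-in-a-class event for these
  features, used to bound the filter tests.
* **low-mean features** (437): means drawn uniformly below the 1.0
  cutoff, so the intensity filter removes them.
* the remainder are clean log-normal features
  (`meanlog = 3, sdlog = 1` — LC-MS peak areas are right-skewed), with
  line-level biological variation `sdlog = 0.3` and technical replicate
  noise CV 0.2. A weaker 1.5× subclass effect on 5 features per
  multi-subclass class exercises the within-class models.

The default role counts were chosen once, from the binomial analysis,
so the two filters remove approximately the published 2355 and 437 of
3727 features; at seed 0 the realized counts are 2335 and 439, leaving
953 high-quality ions. What the generator does *not* emulate: retention
drift, batch effects, correlated co-eluting features, heteroscedastic
detector noise, isotope envelopes. Passing the end-to-end tests
therefore shows the pipeline recovers planted multiplicative class
structure under realistic sparsity and skew — not that it would rank
identically on the original instrument data.

## Numerical choices and degenerate inputs

* NIPALS convergence: relative score change ≤ 1e−14, at most 1000
  iterations.
* Zero-variance columns: scaled to all-zero; S-plot correlation set to 0
  with a flag; a constant score vector or all-constant matrix is an
  error.
* The predictive-weight subspace used for orthogonalization keeps
  singular directions with singular value > 1e−10 relative to the
  largest; if nothing orthogonal remains, adding further orthogonal
  components is an error rather than returning numerical dust.
* Jackknife sign alignment fails loudly (rather than silently flipping)
  if a refit score is numerically orthogonal to the full-model score.
* Classification ties are broken by class order with a warning.
* Dendrogram cut ties follow merge order, as in `stats::cutree`.

## Problem sizes used by the test-suite

The suite runs the full 405 × 3727 study design once for the end-to-end
checks (about two seconds) and uses 12–45 observation, 6–600 feature
fixtures elsewhere, with seeds fixed in the test code. The auto
component rule (add a component while cross-validated Q2Y gains more
than 0.01) substitutes for the proprietary significance rule of the
original software; the published component counts (2 predictive / 4
orthogonal for the 3-class model) cannot be confirmed without the
original data, so the tests assert behaviour, not those counts.

## Known limitations

* This is not a numerical clone of SIMCA-P+: deflation details,
  PCA cross-validation scheme, and its class-membership probability
  formula are proprietary; the package matches the published algorithmic
  definitions and reproduces the published desk-scale quantities
  (diagonal-table Fisher probabilities, adduct-mass arithmetic, ion
  counting contracts).
* The stratified-CV requirement `k ≤ min(class size)` means models
  containing the 6-line durum class run 6-fold, not 7-fold, CV.
* Annotation is m/z-only: no isotope-pattern scoring, MS/MS matching,
  negative-mode adducts, or retention-time prediction.
* Missing values are not imputed; absence must be encoded as 0.
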