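---
title: "Rank-based gene-pair prognostic signatures: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Rank-based gene-pair prognostic signatures: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pairhazard)
```

## The problem and the model

Prognostic gene-expression signatures built on absolute expression levels
travel poorly between cohorts: different platforms, library preparations and
normalization pipelines shift and stretch each sample's measurement scale.
`pairhazard` implements the rank-pair alternative. For an ordered pair of
genes $(a, b)$ and a patient $s$, the pair score is the binary indicator

$$ x_{ab}(s) \;=\; \mathbf{1}\{E(a, s) > E(b, s)\}, $$

a comparison made entirely *within* the patient. Any strictly increasing
transform of one sample's expression vector — affine platform scaling,
log transformation, rank replacement — leaves every score unchanged, so the
method needs no cross-sample normalization at all. This invariance is the
central claim of the approach and is enforced by tests at three levels
(pair matrix, risk score, group assignment).

A prognostic signature is a sparse set of pairs with Cox coefficients
$\beta_k$; the risk score of a patient is the linear predictor

$$ \eta(s) \;=\; \sum_k \beta_k\, x_k(s), $$

and a threshold $c$ (the "cutoff") splits patients into high-risk
($\eta > c$) and low-risk groups. The external-validation rule is strict:
the cutoff learned in the discovery cohort is applied *frozen* to the
validation cohort, never re-calibrated.

## The pipeline

1. **Gene filtering** (`filter_genes`). Candidate genes must be present in
   both cohorts and show unscaled median absolute deviation
   $\mathrm{mad}(x) = \mathrm{median}\,|x - \mathrm{median}(x)|$ of at least
   0.5 in *each* cohort separately. We use the unscaled MAD (no 1.4826
   consistency factor) because the threshold is a bare spread in expression
   units with no distributional framing; the constant is exposed as an
   argument for users who want the robust-sigma reading. The comparison is
   "keep when $\ge$ threshold", i.e. the removal rule is MAD $< 0.5$.
2. **Pair construction** (`build_pair_matrix`). All $k(k-1)/2$ unordered
   combinations, enumerated once in gene-list order; the reversed pair is
   redundant because on tie-free data $x_{ab} + x_{ba} = 1$. Ties score 0:
   "higher" is read strictly, ties are measure-zero on continuous data, and
   a deterministic rule keeps scoring reproducible.
3. **Candidate selection** (`select_candidate_pairs`). Pairs whose score-1
   frequency falls outside $[0.2, 0.8]$ in either cohort are dropped: a
   near-constant indicator carries no usable contrast and inflates the
   multiple-testing burden. The 20–80% band is the convention of the
   relative-ordering literature; both endpoints are inclusive and
   configurable.
4. **Univariate screen** (`univariate_screen`). One Cox fit per pair on the
   binary score, keeping Wald $p < \alpha$ (default 0.05). For a binary
   covariate the Cox score test coincides with the log-rank test — a unit
   test verifies the identity numerically — so this is equivalent to a
   Kaplan–Meier/log-rank screen while also yielding a hazard ratio per pair.
5. **LASSO-Cox selection** (`lasso_cox`). $L_1$-penalized Cox over the
   screened pairs (via `glmnet`), with $\lambda$ chosen by 10-fold
   cross-validated partial-likelihood deviance at its minimum. We prefer
   `lambda.min` to the 1-SE rule because the goal is the most representative
   model rather than maximal parsimony; `lambda.1se` is available. Fold
   assignment derives deterministically from the seed, making training
   byte-reproducible.
6. **Cutoff calibration** (`calibrate_cutoff`). The risk score's
   time-dependent ROC at the evaluation horizon (default 1 year) gives the
   Youden-optimal threshold $\arg\max (\mathrm{TPR} - \mathrm{FPR})$; exact
   ties break toward the threshold nearest the marker median, which also
   stabilizes the degenerate symmetric-null case.
7. **Validation** (`validate_signature`), subgroup Kaplan–Meier analyses
   (`subgroup_km`) and clinical adjustment (`clinical_cox`) follow the
   frozen-cutoff rule described above.

## Survival estimators

Kaplan–Meier, log-rank and Cox fits are delegated to the `survival` package
(Efron tie handling by default, matching the de-facto standard; Breslow for
cross-checks — the two agree exactly on tie-free data). Confidence
intervals are Wald ($\hat\beta \pm 1.96\,\mathrm{SE}$, exponentiated), the
form used in forest-plot reporting. Degenerate fits — no events, collinear
covariates, monotone likelihood — are *flagged* (`converged = FALSE`) rather
than thrown, because a screening loop over hundreds of pairs must survive
individual pathologies.

The time-dependent ROC is the cumulative/dynamic variant with
inverse-probability-of-censoring weighting (IPCW), implemented in the
package: at horizon $t$, cases are subjects with an observed event by $t$
(weight $1/\hat G(T_i^-)$, where $\hat G$ is the Kaplan–Meier estimate of
the censoring survival), controls are subjects followed beyond $t$ (weight
$1/\hat G(t)$). The cumulative/dynamic definition matches the "survival at
1 year" reading of the horizon; the variant is recorded in the result's
metadata. When no censoring occurs before the horizon, the AUC reduces
exactly to the Mann–Whitney concordance of the marker, which the tests
exploit as a brute-force oracle. Thresholds are midpoints between adjacent
distinct marker values, so a perfectly separating marker yields a cutoff in
the interior of the class gap.

## Immune deconvolution

`deconvolve` estimates per-sample cell-type fractions by non-negative least
squares of the bulk profile on a reference matrix (genes matched by symbol),
rescaled to the unit simplex. NNLS is the simplest well-posed estimator for
the constrained-regression deconvolution contract; the $\nu$-SVR used by
some reference-based tools is a plug-point, not a requirement. Significance
per sample is a Monte-Carlo permutation test on the reconstruction
correlation: permute the bulk vector's gene labels, refit, and report the
add-one fraction of permutations reaching the observed correlation (so
$p > 0$ always). Group comparisons are Welch t-tests without multiplicity
correction in the headline column — mirroring starred-p presentation — with
a Benjamini–Hochberg column alongside for honest reading. The packaged
reference (`inst/extdata/synthetic_reference.tsv`, regenerable with
`simulate_reference()`) is a synthetic 60-gene × 6-cell-type matrix with
disjoint marker blocks; curated signature matrices such as LM22 are not
redistributed, and any user-supplied reference in the same layout works.

## What the synthetic generator emulates — and what it does not

`simulate_cohort_pair` plants the prognostic signal *in the pair order*:
for each planted pair a latent per-sample indicator $z \sim
\mathrm{Bern}(1/2)$ decides which gene of the pair receives the larger of
two draws from a shared per-gene log-normal law, so the pair score equals
$z$ exactly and expression *magnitude* carries no survival information.
Survival follows the standard Cox-exponential construction
$T \sim \mathrm{Exp}(\lambda_0 e^{\sum_k \beta_k z_k})$ with independent
exponential censoring; an exponential baseline (rather than Weibull) is the
simplest law satisfying proportional hazards, and no pipeline stage models
the baseline shape. Cohort 2 receives a per-sample strictly increasing
distortion (affine with positive slope, monotone cubic, or rank-preserving
random regeneration), emulating platform effects.

Reference study conditions (the generator defaults, fixed once): 40 genes,
300 samples per cohort, 3 planted pairs with log-hazard $\beta = 1.5$,
baseline hazard 0.1/year, censoring rate 0.3/year, affine distortion, times
in years. The censoring rate was chosen analytically: under the
$2^3$-point planted-hazard mixture the expected censored fraction
$\mathbb{E}[c/(c + \lambda_0 e^{\beta'z})]$ is ≈30% at $c = 0.3$, matching
a realistic overall-survival cohort.

The generator does **not** imitate real tumor-expression covariance,
batch structure, correlated clinical covariates (stage and grade are drawn
independently of risk), or non-proportional hazards. Passing the recovery
experiments therefore demonstrates that the pipeline's machinery is correct
under its own assumptions — not that any particular clinical signature is
reproducible on real cohorts.

## Numerical and design choices

- **Ties**: pair ties score 0 (strict comparison); at-cutoff samples go to
  the low-risk group (`>` is strict). Both choices are documented and the
  group rule is deliberately asymmetric so the cutoff itself is assigned
  deterministically.
- **Duplicate gene rows** collapse to the maximum-MAD row (first occurrence
  on ties): the most informative measurement wins.
- **Time units** are metadata, never converted; the ROC horizon must be
  supplied in the clinical table's unit. A declared horizon unit that
  contradicts the declared time unit is a configuration error caught before
  any computation.
- **Determinism**: every stochastic step (simulation, CV folds,
  permutations) consumes an explicit integer seed; the pipeline manifest
  records md5 checksums of all artifacts, and identical config + seed
  reproduces identical checksums.
- **Problem sizes in the test suite** were chosen as the smallest that
  leave the Monte-Carlo bands comfortably wide: 200 null cohorts of 100
  samples for the screen-size check, 50 seeds of the full 300-per-cohort
  recovery experiment, 200-permutation deconvolution nulls.

## Known limitations

- No frailty, stratified, time-varying or competing-risks survival models.
- The screen tests each pair marginally; correlated pairs sharing a gene
  are screened independently and left to the LASSO to disentangle.
- NNLS deconvolution assumes the bulk is approximately a non-negative
  mixture of the reference profiles on a shared linear scale; it is not a
  batch-correction method.
- The Youden cutoff targets one horizon; signatures meant for several
  horizons should be calibrated per use.
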