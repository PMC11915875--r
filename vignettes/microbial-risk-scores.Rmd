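---
title: "Microbial risk scores for two-cohort tumor-microbiome survival analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Microbial risk scores for two-cohort tumor-microbiome survival analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mrsurv)
```

## Overview

`mrsurv` estimates associations between species-level microbiome
composition and censored survival outcomes across two cohorts, stabilizes
the species selection by repeated subsampling, attaches a
permutation-defined p-value to each selection frequency, and condenses the
selected panel into a per-sample Microbial Risk Score (MRS). This vignette
documents the model, the conventions and tunable parameters, what the
synthetic generator does and does not emulate, and the numerical choices a
user auditing results should know about.

## The estimation path

### Compositional normalization

Microbiome counts carry information only about relative abundance, so all
modelling operates on centered log-ratio (clr) coordinates:
$\mathrm{clr}_i = \log(x_i + c) - \frac{1}{T}\sum_j \log(x_j + c)$.

* **Pseudocount `c`** (default 1, added to raw counts). Only the presence
  of *some* pseudocount is essential; 1 is the simplest convention and
  keeps integer interpretability. It is a parameter of `clr_transform()`
  because the choice shifts clr values of rare taxa and thus, mildly,
  their fitted effects.
* **Filtering** (before clr): a taxon is retained when the fraction of
  samples with at least `min_count = 2` reads is at least
  `min_prevalence = 0.10` *and* its mean relative abundance is at least
  `min_mean_relab = 1e-5`. Thresholds are inclusive: the removal rule is
  stated as "less than", so boundary taxa stay. Filtering is computed on
  the pooled cohorts (one shared species panel for the meta-analysis); a
  per-cohort mode is available by filtering subsets yourself.
* **Batch centering** (`batch_center()`): per-taxon cohort means are
  equalized to the grand mean. This is a deliberately simple location-only
  adjustment — distributional batch effects (variance or quantile shifts)
  are out of scope. Because it shifts each cohort by a constant per taxon,
  it leaves the *within-cohort* Cox fits invariant; its effect is on
  cross-cohort comparability of the final score.

### Per-species survival models and pooling

Each species' clr abundance enters a Cox proportional-hazards model per
cohort with the standard adjustment set: age (years, continuous), sex,
tumor stage (I/IIA vs IIB), and cigarette smoking. Smoking is coded with
three indicators (current, former, not-reported) against never; the
not-reported category is kept explicit rather than dropped so that
missingness does not silently shrink cohorts. Ties use the Efron
approximation — the default of modern survival software and more accurate
than Breslow when event times are coarsely recorded.

Cohort estimates are pooled with the DerSimonian–Laird moment estimator
(`meta_random_effects()`): Cochran's $Q$ on fixed-effect weights, between-
cohort variance $\tau^2 = \max\{0, (Q - df)/(\sum w - \sum w^2/\sum w)\}$,
and pooling weights $1/(se^2 + \tau^2)$. With one usable cohort the pool
degenerates to that cohort's estimate. `p_het` tests $Q$ against
$\chi^2_{df}$.

A calibration note: with two studies, the $\max(0,\cdot)$ truncation in
$\tau^2$ makes the pooled p-value slightly conservative in its mid-range
even under the null (the tail behavior at the usual 0.05 level is
accurate, which is what the test suite asserts). This is a property of DL
pooling with $k = 2$, not of this implementation; uniformity holds exactly
for the per-cohort Wald p-values.

### Stability selection

`stability_select()` repeats, `n_iter = 100` times: draw `frac = 90%` of
each cohort without replacement (stratified, so both cohorts always
contribute to the pool), refit every species, pool, and mark species with
`p_meta < alpha = 0.05`. The selection frequency $O_j$ is the marked
fraction; species with $O_j \ge 0.60$ are selected. The 60% threshold
follows the standard stability-selection recommendation. Two degenerate
cases are handled conservatively and loudly rather than silently:

* a subsample leaving a cohort with fewer than two events, or a fit that
  does not converge, contributes "not significant" for the affected fits
  and increments a per-iteration failure counter kept on the result;
* monotone-likelihood fits (e.g. every high-exposure sample failing
  first) are detected by an effect-size guard (|log HR| > 10 or a
  non-positive-definite information matrix) and flagged `converged =
  FALSE`, excluding them from the pool.

### Permutation p-values

`permutation_test()` rebuilds the *entire* selection-frequency computation
`n_perm = 500` times on data where the outcome pairs (time, event) are
jointly permuted against the exposure/covariate rows, within cohort. The
p-value is $p_j = (\sum_i I(P_{ij} \ge O_j) + 1)/(n_\mathrm{perm}+1)$,
floored at $1/(n_\mathrm{perm}+1)$, with BH q-values across species. Design
choices here were genuinely open and are worth stating:

* **What is permuted**: outcomes, not abundances. Permuting outcome pairs
  within cohort preserves the covariate–microbiome correlation structure
  and the censoring distribution while breaking every outcome link, which
  is the null the selection frequency is meant to be judged against.
  (Permuting abundances instead would also break covariate–microbiome
  structure and test a different, less relevant null.)
* **Full re-run**: each permutation repeats all `n_iter` subsample
  iterations, so $P_{ij}$ is distributed exactly like $O_j$ under the
  null. This is the expensive but honest option; the cost is
  `n_perm x n_iter` fits per species and the reason these two knobs are
  exposed everywhere.
* A species with $O_j = 0$ has $p_j = 1$ by construction, since every
  permuted frequency trivially reaches 0.

### The risk score

`build_mrs()` computes $s = \sum_k \hat\beta_k \, \mathrm{clr}_{\cdot k}$
over the selected species and z-scores across the combined cohorts.
Weights are the pooled **log**-HRs from the full-data meta-analysis — the
polygenic-score convention, additive on the linear predictor scale — not
the HRs, and not averages over subsample iterations (the subsampling
serves selection; the effect size is best estimated on the full data).
Z-scoring makes the score invariant to rescaling all weights by a positive
constant, so the Cox HR "per SD" is the stable quantity; the HR per raw
score unit is also reported since "per unit" is ambiguous between the two
scales. Separate scores are built per outcome (mortality vs relapse),
since the selected panels differ.

`km_logrank()` splits at the median (ties to the low-risk group — a
deterministic, documented rule), estimates product-limit curves, and
reports both the classical log-rank p and the likelihood-ratio p from the
two-group Cox fit (deviance-table style); callers can quote either, and
both are stored. Median survival is the earliest time the curve reaches
0.5 or below, flagged undefined when never reached.

## Diversity module conventions

* Shannon entropy and Jensen–Shannon divergence use natural logs; Simpson
  is the Gini–Simpson form $1 - \sum p^2$. Chao1 is the bias-corrected
  $S_{obs} + F_1(F_1-1)/(2(F_2+1))$.
* β-diversity significance uses a distance-based PERMANOVA
  (McArdle–Anderson partition) with the adjustment covariates fitted
  *before* the variable of interest and permutations that shuffle **only
  the variable's values**, within cohort strata. How to adjust a
  permutational test "on time-to-event data" is not well defined; the
  package's convention is to test the event indicator (optionally at a
  fixed horizon) as the grouping variable and to state that this is a
  convention, not a reconstruction of any particular published analysis.
  Survival-vs-diversity questions are instead answered parametrically by
  Cox models with each α index as the exposure.
* Rarefaction curves are Monte-Carlo (multivariate hypergeometric
  subsampling without replacement, `n_draws` per depth); the exact
  expectation $E[S(d)] = \sum_t 1 - \binom{N-n_t}{d}/\binom{N}{d}$ is used
  as the test oracle.

## The synthetic generator

`simulate_cohorts()` exists so the whole pipeline can be exercised, with
known ground truth, on data shaped like a two-cohort tumor-microbiome
study: default sizes 140 + 63, ~400 taxa, heavy censoring, compositional
counts with cohort batch structure. Its mechanics:

* latent per-taxon log abundances: shared log-normal means (SD 1.5),
  within-sample noise SD 1, plus a per-taxon cohort-2 shift
  ~ N(0, `batch_shift_sd` = 0.5); counts are multinomial at depths drawn
  log-uniformly in [5e3, 5e4];
* survival: linear predictor = true-composition clr of the causal taxa
  times their log-HRs (default ±0.5 per clr unit) plus clinical covariate
  effects; event times by inverse transform from an exponential baseline
  (default 0.045/month, ≈15-month median at the covariate center). The
  predictor is centered within cohort because only λ·exp(η) is
  identified — this pins the time scale to the configured baseline;
* relapse: an additional proportional hazard (default 0.3× the death
  hazard); the RFS event time is min(relapse, death) and one shared
  uniform censoring time per sample applies to both outcomes, so
  `rfs_time <= os_time` holds by construction. The censoring cap is
  solved numerically to hit the target OS censoring fraction (default
  0.41);
* covariates: age ~ N(66, 10), 55% male, 70% stage IIB, smoking
  37/11/38/13% across never/current/former/not-reported — margins chosen
  once for fixture realism;
* immune fractions: 22-column Dirichlet per sample, with designated causal
  taxa multiplying designated cell types' concentrations by
  `exp(link x clr)`.

What it deliberately does **not** emulate: read-level sequencing error,
taxonomic misassignment, host-read contamination, zero-inflation beyond
what multinomial sampling of skewed compositions produces, non-proportional
hazards, informative censoring, or correlated clinical covariates. Passing
tests on this generator therefore validate the *estimation machinery*
(calibration, recovery, invariances) — they are not evidence about any
real cohort.

## Problem sizes in tests and the acceptance script

The package's own verification runs are sized to be thorough yet quick on
one CPU: the null-calibration check uses 100 replicates of pooled n = 200
with 20 taxa; the recovery check uses 20 replicates of pooled n = 400 with
40 taxa, log-HR 0.8 and 50 subsample iterations; `scripts/acceptance.R`
runs the full two-outcome analysis at 140 + 63 samples, 120 taxa, 50
iterations and 50 permutations. These sizes are the package's choices for
routine verification; all knobs scale up by argument.

## Known limitations

* The Wald-based `p_meta` relies on asymptotic normality of per-cohort
  log-HRs; with very few events per cohort, permutation p-values are the
  more trustworthy quantity (and are the ones the selection is judged by).
* DL pooling with two cohorts estimates $\tau^2$ very noisily; `p_het` has
  little power and the pooled CI does not account for uncertainty in
  $\tau^2$.
* The batch-centering step is location-only, as discussed above.
* `predict()` on new samples applies the training clr and weights but no
  batch adjustment for a *new* cohort's shift; cross-cohort transport of
  the score should be validated before use.
* The permutation stage is the computational bottleneck
  (`n_perm x n_iter x species x cohorts` Cox fits); budget accordingly or
  lower `n_perm` for exploration and keep 500 for final inference.
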