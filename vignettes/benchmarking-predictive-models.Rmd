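---
title: "Benchmarking predictive vs prognostic models of checkpoint-inhibitor benefit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Benchmarking predictive vs prognostic models of checkpoint-inhibitor benefit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(icibench)
```

## The problem

A biomarker model for immunotherapy is clinically useful only if it is
*predictive* — informative about the benefit of an immune checkpoint
inhibitor (ICI) relative to chemotherapy — rather than merely
*prognostic*, i.e. informative about outcome regardless of treatment.
In a randomized two-arm trial the distinction is measurable: a
prognostic score discriminates outcomes equally well in both arms, a
predictive score discriminates specifically in the ICI arm.

`icibench` implements an evaluation framework built on that idea. For a
model producing one real-valued score per patient, the per-arm *basal
metric* (BM) is Harrell's concordance index for the survival endpoints
(PFS, OS) or the ROC-AUC for the binary endpoint (best overall response
of progressive disease, PD). The primary metric is the **difference in
squared scaled basal metrics**:

$$\mathrm{scaled}(BM) = 2\,(BM - 0.5), \qquad
  \mathrm{DSS} = \mathrm{scaled}(BM_{\mathrm{ICI}})^2 -
                 \mathrm{scaled}(BM_{\mathrm{CHEMO}})^2 .$$

A model performing equally in both arms has DSS = 0 whatever its
absolute discrimination; squaring credits models that predict well in
the negative direction; models informative only in the control arm go
negative. DSS therefore isolates the treatment-specific (predictive)
component of a model's signal.

## Basal-metric conventions

The concordance index counts pairs (i, j) with $t_i < t_j$ and an event
for patient i; pairs with tied times are comparable only when exactly
one of the two had the event. Tied scores count 1/2. These are the
standard Harrell conventions; they are declared here because different
software makes different choices and the framework's numbers depend on
them. For the PD endpoint, the AUC is oriented by each model's declared
direction (`benefit_high` models are credited for ranking
non-progressors above progressors), which together with the squaring
makes the evaluation direction-agnostic.

Both metrics are pure rank statistics: every downstream quantity is
invariant under strictly monotone transforms of the scores, which is
why rule-based models may use arbitrary rank-preserving constants (the
Aginome group offsets 20/10/0 below).

## Reference models

Five published model families are implemented from their printed rules,
plus the two univariate baselines (raw TMB, raw PD-L1, cohort-median
imputation of missing values):

* **Netphar** — decision tree: TMB is binarized at 243 missense
  mutations and `Y = 10*TMBbin + TMBbin*PDL1`; the TMB-low branch is
  deliberately conservative (all zeros), and missing TMB falls to it.
* **I-MIRACLE** — category 3 when TMB-high (≥ cohort upper tertile;
  proliferation-signature tertile as proxy when TMB is missing) and
  PD-L1-high (≥ 50%; immune/ICR-signature tertile as proxy), 1 when
  both low, 2 otherwise.
* **Aginome-Amoy** — three groups from the cohort medians of PD-L1 and
  TMB, ranked group 3 > group 1 > group 2, with min–max-normalized
  within-group linear scores.
* **FICAN-OSCAR** — the published sparse linear model over a panel
  enrichment score and clinical indicators; all coefficients are
  negative, so the model is scored as `benefit_low`. The published
  description does not state the TMB-high cut point; we use the cohort
  upper tertile for consistency with the other models, and the score's
  direction is recorded explicitly as an assumption in the output.
* **DukeLKB1** — six features: TMB > 67th percentile, PD-L1 > 67th
  percentile, and the means of histology-stratified z-scored expression
  over four signatures. The published description does not state how
  the six features combine into one prediction; the default is a signed
  equal-weight sum (+TMB, +PD-L1, +inflammatory; −LKB1-loss, −NRF2,
  −neuroendocrine, the known resistance associations), exposed as a
  configurable weight vector.

Whether I-MIRACLE's tertiles were computed per arm or pooled is not
stated; we pool across arms (as for all cohort thresholds, computed
with the type-7 linear-interpolation quantile).

### Signature scoring

The published models compute single-sample signature scores with
external tools named only by package. We implement the two primitives
as documented contracts of this package rather than claiming numerical
equivalence with those tools:

* `rank_enrichment_score()` — the standardized Mann–Whitney mean-rank
  statistic of the set genes within each patient's expression ranking
  (mean 0, variance ≈ 1 under exchangeability; antisymmetric under
  expression negation).
* `walk_enrichment_score()` — a weighted Kolmogorov–Smirnov random
  walk over the decreasing-expression ordering, rank weights (exponent
  1 by default), scored as maximum positive minus maximum negative
  deviation (the "difference" convention). Plain ranks deliberately
  replace the kernel-density rank statistic of the better-known GSVA
  implementation; this is a documented deviation, chosen to keep the
  primitive exactly testable against a hand-computed walk.

The actual gene memberships of the published signatures (20-gene ICR,
proliferation, 4-gene inflammatory, LKB1/STK11-loss, NRF2,
neuroendocrine, custom panel) are not reproduced here; they are
user-supplied configuration via GMT files. The synthetic generator
emits its own true signature blocks for testing.

## Ranking procedure

Per-model uncertainty comes from `B` bootstrap resamples (default
1000), stratified within arm with arm sizes fixed — DSS compares arms,
so letting arm sizes fluctuate across resamples would inflate its
variance. Degenerate resamples (an arm left without comparable pairs or
with one outcome class) are redrawn and counted.

Model comparisons use a paired-bootstrap Bayes factor: with
$w$ the number of resamples in which model a's DSS exceeds model b's
(ties split 1/2) out of $B$,

$$K = \frac{w + 0.5}{B - w + 0.5},$$

capped at $2B$. The 0.5 terms are a continuity correction so degenerate
sweeps stay finite; the estimator is exactly reciprocal
($K_{ab} K_{ba} = 1$) below the cap. The exact estimator used by the
original challenge is not public; this package's ranking semantics
follow the published rules with this estimator as its declared stand-in,
and no numerical agreement with the challenge's K values is claimed.

Ranking then proceeds in three published steps: a model is *eligible*
if K versus the TMB baseline exceeds 3; eligible models whose K
relative to the highest-DSS eligible model is below 3 form the *tie
set*; ties are broken on the ICI-arm BM, and tied models within
`tie_tol` of the best tie-break BM are *top performers*. "Close to the
best tie-breaking score" is operationalized as one bootstrap standard
error of the best tie-breaker's ICI-arm BM (configurable). The three
sets are nested by construction.

`km_median()` supports the stratified Kaplan–Meier summaries (median
PFS/OS in the upper-tertile vs middle/lower-tertile score groups, per
arm). It delegates to `survival::survfit()`; when the curve sits
exactly at 0.5 the median is the average of the boundary times, so with
no censoring it equals the plain sample median, and a curve that never
reaches 0.5 reports "not reached" (`NA`).

## The synthetic trial generator

The real evaluation data are restricted clinical trials, so the
generator produces two-arm cohorts with the *structure* the framework
assumes, not a calibration to any trial's summary statistics:

* 1:1 randomization to ICI vs chemotherapy; sex, histology, smoking and
  ECOG sampled at NSCLC-like frequencies (60% male, 25% squamous, 85%
  ever-smokers, 35% ECOG 0).
* Latent standard-normal immune and proliferation factors per patient;
  expression is `loading × factor + N(0,1)` noise within disjoint
  signature blocks (immune, proliferation, panel — the panel loads on
  the immune factor), pure noise elsewhere. Defaults: 200 genes, blocks
  of 20/20/10 at loadings 0.8/0.8/0.7, a desk-scale stand-in for a
  transcriptome.
* TMB: log-normal counts (meanlog log 150, sdlog 0.8 — median 150
  missense mutations, so the Netphar 243 cut selects roughly the top
  quarter), Gaussian-copula correlation 0.6 with the proliferation
  factor. PD-L1: logit-normal percent (intercept −0.5, scale 1.5),
  copula correlation 0.5 with the immune factor.
* PFS from an exponential proportional-hazards model with baseline rate
  0.1/month and log-hazard $-(\theta\,\mathrm{ICI} + \beta_{prog} b +
  \beta_{pred}\, b\,\mathrm{ICI})$ on the standardized biomarker $b$
  (positive coefficients prolong survival). OS = PFS + an independent
  Exp(0.08) residual, guaranteeing OS ≥ PFS with positive correlation.
  Exponential rather than Weibull hazards because the inverse transform
  is closed-form and every metric in the framework is rank-based, hence
  indifferent to the time scale's shape.
* Administrative censoring at 24 months plus Exp(0.02/month) dropout;
  PD labels from a logistic model with matching prognostic/predictive
  terms; 10% completely-at-random missingness in TMB and PD-L1
  (informative missingness is deliberately out of scope; expression is
  never masked so the signature proxies stay available).
* All randomness flows from one master seed through five named
  substreams (covariates, expression, outcomes, censoring,
  missingness), so changing one component's parameters leaves the other
  components' draws untouched.

`effect_scenarios()` fixes four canonical settings: `null` (no
effects), `prognostic_only` ($\beta_{prog} = 1$, $\beta_{pred} = 0$),
`predictive_only` ($\beta_{prog} = 0$, $\beta_{pred} = 1$ on
standardized TMB) and `mixed`; non-null scenarios add a modest overall
ICI benefit ($\theta = 0.2$).

What the generator does **not** emulate: real transcriptome dimension
and correlation structure, informative censoring or missingness,
non-proportional hazards (delayed ICI effects and survival-curve
crossover), or any calibration to published medians and response rates.
Passing tests therefore demonstrate that the framework's machinery and
its separation of predictive from prognostic signal are correct under
the stated generative model — not that any model would reproduce its
published performance on trial data.

## Numerical and design choices

* Cohort thresholds use the type-7 quantile; missing values are dropped
  before quantile computation; min–max normalization of a constant
  variable returns 0.5.
* Missing TMB is conservative everywhere it can be: Netphar's low
  branch, a 0 TMB-high indicator in FICAN-OSCAR and DukeLKB1.
* The per-patient `netphar_score()` refuses missing PD-L1 (the rule
  needs it); the dataset-level `score_model()` wrapper median-imputes
  instead, with a message, so a complete submission can always be
  produced.
* OS evaluation runs on as-recorded outcomes. A crossover-adjusted OS
  analysis is out of scope; users with corrected times can simply
  substitute them into the `os_time`/`os_event` columns.
* Evaluation problem sizes in the test suite (cohorts of 100–2000,
  B of 100–500, 200 replicate trials at n = 500 for the
  predictive-vs-prognostic separation check, with a 50-gene expression
  matrix since the TMB baseline under test ignores expression) were
  chosen as the smallest sizes at which the Monte-Carlo checks are
  stable.

## Known limitations

* Signature gene memberships ship as user configuration, not as
  reconstructions of the published lists.
* The Bayes-factor estimator and bootstrap scheme are declared
  conventions, not reconstructions of the challenge's unpublished code.
* The generator's exponential hazards cannot express time-varying
  treatment effects, which are common in immunotherapy trials.
* C-index computation is O(n²) per arm; fine for trial-sized cohorts
  (thousands), not intended for biobank-scale data.
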