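---
title: "Methods: IHC prognostic-panel scoring, survival analysis and
  cross-platform meta-analysis"
author: "ihcpanel"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: IHC prognostic-panel scoring, survival analysis and cross-platform meta-analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ihcpanel)
```

## The problem

Immunohistochemistry (IHC) panels are a low-cost alternative to
transcriptomic prognostic signatures in breast cancer: a small set of
antibodies is scored on tissue microarray (TMA) cores and combined into
a summary score. `ihcpanel` implements one such workflow end to end for
a three-marker panel — the cell-cycle regulator **ANLN**, the
mitogen-activated kinase **PBK**, and the estrogen-response gene
**PDZK1** — where high ANLN, high PBK and low PDZK1 are the adverse
states. The package covers:

1. core-level scoring and quality control (`ihc_scoring`),
2. the 0–3 panel score with its Signature A/B dichotomisation (`panel`),
3. the association and survival statistics used in such cohorts
   (`stats`),
4. a cross-platform transcriptomic meta-analysis with per-dataset
   median dichotomisation (`meta_analysis`), and
5. seeded simulators of a TMA cohort and of heterogeneous expression
   datasets, so every stage can be exercised and validated without
   patient data (`synthetic_data`).

## Scoring model

Each patient contributes duplicate cores per marker. A core is
**evaluable** when it has at least 30% tissue and at least 100 cells
("less than" is strict, so exactly 30%/100 passes); failing cores are
discarded to avoid manual selection bias. The three markers use three
scales:

* **ANLN** (nuclear): percent of stained nuclei, binned
  0 = ≤1%, 1 = 2–25%, 2 = 26–75%, 3 = >75%.
* **PDZK1** (cytoplasmic): staining intensity 0–3
  (negative/weak/medium/strong).
* **PBK** (cytoplasmic): intensity-distribution (ID) score =
  intensity × percent cells stained, scale 0–300.

Duplicate cores are combined by the **maximum over evaluable cores**
(the consensus rule used with this cohort; a mean rule is available via
`scoring_config(consensus = "mean")`). Patient-level scores are
dichotomised strictly above marker-specific cut-offs: ANLN category
> 1, PDZK1 intensity > 2, PBK ID score > 48. The ANLN threshold is
stated in the source material as an "intensity" cut-off although ANLN
is scored by nuclear-percentage category; the only 0–3 scale ANLN has
is the category, so the threshold is applied there (categories 2–3 =
high). A patient with no evaluable core for a marker is **missing** for
that marker — missingness is an explicit level, propagated and never
imputed.

The **panel score** adds one point per adverse state,

$$s = \mathbf{1}[\text{ANLN high}] + \mathbf{1}[\text{PBK high}]
      + \mathbf{1}[\text{PDZK1 low}] \in \{0,\dots,3\},$$

defined only for patients with all three markers called
(complete-case). Scores 0–1 form the good prognostic **Signature A**,
scores 2–3 the poor **Signature B**.

```{r truth-table}
lv <- expand.grid(anln = c("high", "low"), pbk = c("high", "low"),
                  pdzk1 = c("high", "low"), stringsAsFactors = FALSE)
lv$score <- panel_score(lv$anln, lv$pbk, lv$pdzk1)
lv$signature <- panel_signature(lv$score)
lv
```

## Reporting conventions

All reported percentages are rounded **half away from zero** to one
decimal (`round_half_up`); base R's round-half-to-even does not
reproduce standard clinical-table arithmetic such as 252/512 = 49.2%.
One known consequence: 4/6 is reported as 66.7%, where occasional
published tables print 66.6 (truncation); we standardise on half-up.
Cross-tabulations of the panel score against clinicopathological
variables report within-score-column percentages with "unknown"
categories excluded from the denominator but still counted.

## Statistics

The survival and association statistics are the standard ones for this
design, computed through the `survival` package and base R behind a
validating interface:

* `km_estimate` — Kaplan-Meier product-limit curves (exportable as
  coordinate tables).
* `logrank_test` — Mantel-Cox log-rank with hypergeometric variance,
  df = groups − 1; zero events yield statistic 0, p = 1.
* `cox_fit` — Cox proportional hazards by partial-likelihood
  maximisation (Newton-type, tolerance 1e-9, ≤ 50 iterations), Efron
  tie handling by default (Breslow selectable; the two agree exactly on
  tie-free data), complete-case deletion with the used n reported, and
  95% Wald intervals $\exp(\hat\beta \pm 1.959964\,\mathrm{se})$.
  Categorical covariates are one-hot encoded against a reference level
  (first alphabetical unless configured). Constant covariates and
  non-convergent fits (e.g. perfect separation) raise errors rather
  than returning unstable estimates.
* `chi_square_test` — Pearson chi-square, no continuity correction;
  zero-margin rows/columns are dropped (with a warning) before the
  degrees of freedom are computed.
* `fisher_exact` — exact two-sided 2×2 p by the probability-mass
  criterion (the sum of hypergeometric probabilities not exceeding the
  observed table's); larger tables use a seeded Monte Carlo permutation
  p with at least 1e5 draws. Note that the probability-mass two-sided
  p is conservative relative to the Pearson p for near-null tables;
  the two agree closely only where a real association signal exists.
* `pearson_correlation` — Pearson's r with the t-transform p on n − 2
  degrees of freedom.

The test suite checks these against independent oracles written from
first principles: a hand product-limit estimator, a brute-force
observed-minus-expected/variance log-rank computation from the risk-set
definition, and full hypergeometric enumeration for Fisher 2×2 tables.

## Cross-platform meta-analysis

Expression datasets from different platforms cannot be compared on a
common scale, so the procedure is made rank-based within each dataset:

1. **Gene-centring** (`collapse_probes`): probes mapping to the same
   gene are averaged; unmapped probes are dropped with a logged count.
2. **Median dichotomisation** (`median_dichotomize`): within each
   dataset, a sample is "high" for a gene iff its value strictly
   exceeds the dataset median (midpoint of central order statistics for
   even n). Values **equal to the median are "low"** — the tie rule is
   a deliberate, documented choice; the source material states only
   that the median is the cut-off.
3. **Group assignment** (`assign_groups`): the default `"strict"` mode
   labels a sample poor-prognostic iff ANLN is high AND PBK is high AND
   PDZK1 is low, matching the conjunctive definition of the poor
   signature; the alternative `"score"` mode dichotomises the 0–3 panel
   score at 2. The modes differ exactly on samples with score ≥ 2 that
   do not show all three adverse states.
4. **Pooling** (`pool_datasets`): groups are assigned within-dataset
   *before* pooling; pooling is concatenation and is order-invariant.
5. **Global analysis** (`pooled_survival_analysis`): Kaplan-Meier and
   log-rank on the pooled group label; optionally a Cox model of group
   adjusted for lymph node status, tumour grade and ER status on
   complete-case samples, with the complete-case n reported alongside
   the pooled n.

Because each step after normalisation depends only on within-dataset
ranks, the pipeline is invariant under strictly monotone per-dataset
transformations of the expression values — exactly so when genes have
single probes, and up to probe-averaging for multi-probe genes (the
mean commutes with affine transforms only; a strongly nonlinear
monotone distortion applied at probe level can move near-median
samples across the cut). Raw normalisation (RMA/quantile, loess) is an
upstream responsibility: the package consumes normalised matrices.

## The synthetic-data generators

The source cohort is not public, so the package ships generators whose
**defaults are the study conditions**, chosen once from the published
margins and held fixed:

* `cohort_sim_config()` — 512 patients, duplicate cores, administrative
  follow-up horizon 17 years with independent exponential censoring
  (emulating a median follow-up near 11 years); marker-high targets
  64.5% (ANLN), 36.0% (PBK), 15.4% (PDZK1); per-marker availability
  targets 93.6%/57.0%/54.7% with ~49.2% three-marker completeness.
* Core loss is **block-correlated**: under independent loss the three
  availabilities would imply only ~29% completeness, far below the
  ~49% observed, so losses share a per-patient fragility factor
  $f_i \sim N(0,1)$, with loss probability
  $\Phi(a_m + b f_i)$ per core. The intercepts $a_m$ are calibrated to
  the marginal availabilities and the loading $b$ to the completeness
  target by one-dimensional root-finding over a fixed Gaussian
  quadrature grid, at configuration time.
* Marker dependence: ANLN and PBK load (0.55 each) on a shared latent
  proliferation factor that also drives tumour grade and Ki67, giving
  the positive ANLN–PBK association seen in practice; PDZK1 is
  independent.
* Covariate margins (age, size, grade, nodal, ER, PR, Her2, Ki67,
  histological type, and their unknown-token rates) follow the
  published cross-tabulation margins.
* Survival is proportional-hazards with an exponential baseline
  (0.020/yr RFS, 0.008/yr BCSS — round values giving realistic event
  fractions over the horizon), driven by the *true* marker states. The
  default effect mode ties the hazard to the true Signature-B indicator
  at the published univariate hazard ratios (3.33 for RFS, 16.36 for
  BCSS); a per-marker effect mode is available.
* Observer noise on duplicate cores is **boundary-respecting**: core
  jitter never crosses a marker's dichotomisation cut-off, so an
  evaluable patient's call always equals the latent state. This is a
  simplification — real observers misclassify near thresholds — and it
  is why downstream parameter-recovery tests measure estimator
  behaviour rather than robustness to scoring error.

`expr_sim_config()` emulates a ten-dataset, ~1,300-sample
cross-platform collection: per-dataset location shifts (SD 1.5) and
scale factors (0.6–1.8), one to three probes per gene, probe noise
around the gene signal, survival generated from the strict poor-group
indicator (default log-HR log 1.49, the published adjusted estimate),
and ~19% independent missingness per adjustment covariate so the
complete-case n drops to roughly half the pooled n (echoing published
adjusted analyses). Probe noise can flip near-median samples between
groups, attenuating recovered hazard ratios by a few percent — real
measurement error behaves the same way.

What passing tests on these simulators show: that the pipeline's
arithmetic, consensus/missingness logic and estimators are correct and
calibrated under a proportional-hazards world with the published
margins. What they cannot show: robustness to observer disagreement,
non-proportional hazards, informative censoring or batch effects beyond
location/scale — none of which the generators emulate.

## Numerical choices and degenerate inputs

* All simulator randomness flows from the single config seed; equal
  configs give identical output.
* Quadrature for the loss calibration uses a normalised 601-point grid
  on ±6 SD; calibration fails loudly for infeasible targets
  (completeness above the smallest availability).
* Degenerate statistics are defined, not silent: zero events give
  log-rank statistic 0 and p = 1; a zero table margin gives Fisher
  p = 1; all-identical expression values warn and class every sample
  "low"; crosstab columns with only unknown entries are flagged and
  their percentages set to NA.
* Problem sizes in the test suite (a 512-patient cohort, recovery runs
  at n = 5000 and pooled n = 1200–3000, 2000 null replicates for the
  log-rank size check, 300 for the null-uniformity check) are chosen so
  the whole suite completes in well under a minute while keeping Monte
  Carlo error small relative to the tolerances tested.

## Known limitations

* The panel weights markers equally; no continuous risk score is
  provided.
* No proportional-hazards diagnostics, time-varying covariates or
  competing-risks models.
* The Monte Carlo Fisher p for r×c tables is a permutation estimate;
  its own Monte Carlo error (~`1/sqrt(B)`) should be kept in mind when
  comparing to exact values.
* The simulators are structural emulations, not fits to the original
  cohort; agreement with published counts is by construction of the
  targets, not evidence about the original data.
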