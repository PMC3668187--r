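# ihcpanel

Scoring and survival analysis for an immunohistochemistry (IHC)
prognostic biomarker panel in breast cancer, plus the cross-platform
transcriptomic meta-analysis that validates the same three genes at the
mRNA level.

## What it is for

Tissue-microarray (TMA) studies score candidate protein markers on
hundreds of tumour cores and ask whether a small panel predicts
recurrence-free survival (RFS) or breast-cancer-specific survival
(BCSS). This package implements that workflow for the three-marker
panel of **ANLN** (anillin, nuclear), **PBK** (PDZ-binding kinase,
cytoplasmic) and **PDZK1** (PDZ-domain containing 1, cytoplasmic),
where high ANLN, high PBK and low PDZK1 are the poor-prognostic
states. It is aimed at biostatisticians and translational researchers
who need the full chain — core QC, marker scoring, consensus,
dichotomisation, panel scoring, cohort statistics, and a pooled
expression meta-analysis — as tested, scriptable functions rather than
spreadsheet arithmetic.

## The model in brief

Per core, ANLN is scored by percent stained nuclei binned to
categories 0–3 (≤1%, 2–25%, 26–75%, >75%), PDZK1 by staining intensity
0–3, and PBK by the intensity-distribution (ID) score
`intensity x % cells stained` (0–300). Cores with <30% tissue or <100
cells are discarded; duplicate cores are combined by the maximum over
evaluable cores. Patient-level calls are "high" strictly above the
cut-offs ANLN > 1, PDZK1 > 2, PBK > 48. The panel score is

    s = 1[ANLN high] + 1[PBK high] + 1[PDZK1 low]  in {0,...,3}

computed for complete cases only, and dichotomised into Signature A
(s = 0,1; good) vs Signature B (s = 2,3; poor). Survival comparisons
use Kaplan-Meier curves, the Mantel-Cox log-rank test, and Cox
proportional-hazards regression (Efron ties, 95% Wald intervals);
associations use the chi-square, Fisher's exact and Pearson
correlation tests. The meta-analysis module collapses probes to genes
by averaging, dichotomises each gene at its within-dataset median
(rank-based, so platform location/scale effects cancel), assigns the
conjunctive poor group per dataset, pools datasets, and runs global
log-rank and node/grade/ER-adjusted Cox models on RFS.

Because the original patient data are not public, the package ships
seeded simulators (`simulate_tma_cohort`, `simulate_expression_datasets`)
whose defaults emulate the published study conditions: a 512-patient
cohort with duplicate cores, block-correlated core loss calibrated to
93.6%/57.0%/54.7% marker availability and ~49% three-marker
completeness, covariate margins matching the published
cross-tabulation, and ten heterogeneous expression datasets of ~130
samples each.

## Worked example

```r
library(ihcpanel)

cfg  <- cohort_sim_config(seed = 7)      # published-margin defaults
sim  <- simulate_tma_cohort(cfg)
calls <- score_ihc_cohort(sim$cores)     # QC -> score -> consensus -> call
completeness_summary(calls, cohort_size = 512)
#> Cohort of 512 patients
#>  marker evaluable evaluable_pct high high_pct low low_pct
#>    ANLN       486          94.9  320     65.8 166    34.2
#>     PBK       296          57.8  112     37.8 184    62.2
#>   PDZK1       295          57.6   41     13.9 254    86.1
#> Complete cases (all 3 markers): 262 (51.2%)

panel <- build_panel(calls)
d <- merge(panel, sim$survival, by = "patient_id")
d <- d[!is.na(d$signature), ]            # complete cases
logrank_test(d$bcss_time, d$bcss_event, d$signature)
#> Log-rank test: chi-square = 65.91 on 1 df, p = 4.713e-16 (n = 262)

cox_fit(d$rfs_time, d$rfs_event,
        data.frame(signature = factor(d$signature, levels = c("A", "B"))))
#> Cox PH fit (efron ties), n = 262 of 262 supplied, 113 events
#>        term     coef        se            hr_ci      p_value
#>  signatureB 1.281718 0.2711598 3.60 (2.12-6.13) 2.280843e-06
```

Reading the output: of 512 simulated patients, 262 have all three
markers evaluable (the generator targets the ~49% completeness of a
real TMA with correlated core loss); Signature B carries a hazard ratio
of 3.60 (95% CI 2.12–6.13) for recurrence, consistent with the
generating Signature-B effect (hazard ratio 3.33) the defaults encode.

The same stages are available as pipeline subcommands
(`run_pipeline()` or `Rscript inst/cli/ihcpanel.R`):
`simulate-cohort`, `simulate-expression`, `score-ihc`, `panel`,
`survival`, `assoc`, `meta` — each writes its outputs plus a
`manifest.json` recording the seed and config, so any run is
reproducible from its manifest.

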