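Package: ihcpanel
Title: Prognostic Biomarker Panel Scoring and Survival Analysis for
    Tissue Microarray Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for building and evaluating immunohistochemistry (IHC)
    based prognostic biomarker panels in breast cancer. Implements
    marker-specific scoring of tissue microarray (TMA) cores
    (nuclear-percentage categories, cytoplasmic intensity, and the
    intensity-distribution score), core-level quality control and
    duplicate-core consensus, dichotomisation at marker-specific
    cut-offs, and the three-marker panel score (high ANLN, high PBK, low
    PDZK1) with its Signature A/B dichotomisation. Provides the cohort
    association and survival statistics used with such panels
    (chi-square, Fisher's exact, Pearson correlation, Kaplan-Meier,
    log-rank, and Cox proportional-hazards regression), a cross-platform
    transcriptomic meta-analysis pipeline with probe-to-gene collapsing
    and per-dataset median dichotomisation, and seeded simulators for
    TMA-style cohorts and heterogeneous expression datasets so that
    every stage can be exercised end-to-end without access to patient
    data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    survival,
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
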