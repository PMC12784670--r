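Package: pvsignal
Title: Disproportionality Signal Detection for Spontaneous Adverse Event Reports
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for pharmacovigilance disproportionality analysis of
    individual case safety reports (ICSRs), built around the dual-database
    (FAERS / CVARD) evaluation of venous thromboembolism and bleeding signals
    for glioma systemic therapies. Provides a normalized ICSR data model with
    readers for delimited and FAERS-quarterly-style files and version-aware
    deduplication; free-text glioma cohort construction with broad and strict
    case definitions; drug-name normalization and any-role / primary-suspect
    exposure classification; bevacizumab regimen stratification; composite
    MedDRA preferred-term endpoints counted once per report; the reporting
    odds ratio (ROR), proportional reporting ratio (PRR), Bayesian confidence
    propagation information component (IC/IC025) and empirical-Bayes
    gamma-Poisson shrinkage (EBGM/EB05) with the a >= 3 and ROR lower-bound
    signal rule; a constrained-search oracle that reconstructs 2x2 tables
    from published summary rows to verify printed confidence intervals; and a
    seeded generator of synthetic spontaneous-reporting databases with known
    ground-truth reporting odds ratios for calibration and parameter-recovery
    studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tibble,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
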