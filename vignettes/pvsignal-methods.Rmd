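---
title: "Disproportionality signal detection for glioma therapies: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Disproportionality signal detection for glioma therapies: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pvsignal)
```

## The problem

Patients with malignant glioma carry a high baseline risk of venous
thromboembolism (VTE) and of central nervous system (CNS) and
gastrointestinal (GI) bleeding, and the systemic therapies they receive --
temozolomide, bevacizumab, and the nitrosoureas lomustine and carmustine --
may add to that risk. Spontaneous adverse-event reporting databases (the US
FAERS and the Canadian CVARD) allow a comparative, hypothesis-generating
look at this question through *disproportionality analysis*: within a
disease cohort, is a given event reported disproportionately often among
reports mentioning a given drug?

`pvsignal` implements that workflow end to end -- ICSR ingestion, glioma
cohort construction, exposure and regimen classification, composite
endpoints, four disproportionality statistics with a prespecified signal
rule, regimen and sensitivity analyses -- plus two supporting instruments:
a seeded synthetic reporting-database generator with closed-form ground
truth, and a constrained-search oracle that reconstructs 2x2 tables from
published summary rows so that printed confidence intervals can be verified
without access to the raw extractions.

## Data model

A `report_set` is a relational bundle of four tibbles (reports, drugs,
reactions, indications) keyed by `(report_id, version)`, mirroring how
reporting systems actually deliver data. Spontaneous reports arrive in
versions; `deduplicate()` keeps only the maximal version of each case
(ties keep the last-read record, with a warning), and every analysis
operates on deduplicated sets. Two dialects are read and written: a
normalized TSV schema and a minimal FAERS-quarterly-style `$`-delimited
DEMO/DRUG/REAC/INDI layout. Age and weight are binned to the bands used in
baseline tables of pharmacovigilance studies (12-17, 18-64, 65-85 years;
<50, 50-100, >100 kg); values outside those bands (under 12 or over 85
years) have no band and are recorded as unknown. Occupation codes MD, PH,
OT and HP count as health-care-professional reporters; any other nonblank
code as non-HCP; blank as unknown.

## Cohorts, exposures, endpoints

The glioma cohort is built by case-insensitive *substring* matching of
configured terms against the indication and history text. Substring rather
than word-boundary semantics is a deliberate choice: "ASTROCYTOMA" should
capture "ANAPLASTIC ASTROCYTOMA"; the shipped term lists are closed under
substring containment, so no over-capture arises within them. Two
definitions ship as editable config: a broad, sensitivity-maximizing list
(glioma, malignant glioma, glioblastoma (multiforme), (anaplastic)
astrocytoma, (anaplastic) oligodendroglioma) and a strict list restricted
to higher-certainty malignant wording. The strict term set is a subset of
the broad set, so strict cohorts are provably contained in broad ones.
Abbreviations such as "GBM" are not in the default lists: their
specificity in free text is unverifiable, so including them is left to the
user's config.

Drug names are normalized to uppercase generic tokens through an editable
brand map (Avastin, Temodar/Temodal, Gleostine/CeeNU, BiCNU/Gliadel, and
biosimilar brands). A report is *exposed* if any drug entry carries a
target generic name, in any role (primary suspect, secondary suspect or
concomitant) for the main analysis, or restricted to primary-suspect
entries for the exposure-misclassification sensitivity analysis.

Bevacizumab reports are partitioned into mutually exclusive regimen groups
by co-reported chemotherapy: monotherapy, + temozolomide, + lomustine.
Reports carrying bevacizumab with *both* temozolomide and lomustine fit
none of those; they get the label `BEV_OTHER_COMBO` and contribute only to
the "other bevacizumab-containing regimens" comparator cells, never to a
focal group. Regimen assignment always uses any-role exposure; the PS-only
sensitivity analysis applies to main-analysis exposure, not to regimen
stratification.

Endpoints are configured sets of MedDRA preferred terms compared by exact
string equality after case/whitespace normalization -- no MedDRA hierarchy
or SMQ expansion, the configured list *is* the endpoint. The shipped VTE,
CNS-bleeding and GI-bleeding sets are seeded from the PTs named for these
composite outcomes (deep vein thrombosis, pulmonary embolism and related
venous terms; intracranial/cerebral haemorrhage and haematoma terms; GI
haemorrhage, haematemesis, melaena) and are documented approximations: the
full lists used by any given study are rarely published, so the sets are
user-extensible config. A report counts once per endpoint regardless of
how many of its PTs match, and first occurrences are not distinguished
from recurrences.

## The statistics

For each drug-event pair a 2x2 table of deduplicated report counts is
built within the cohort: `a` target drug + target event, `b` target drug +
other events, `c` other drugs + target event, `d` other drugs + other
events. The comparator is the rest of the *cohort*, not the full database.

- **ROR** (primary): `(a d)/(b c)`, with the log-normal Woolf 95% interval
  `exp(ln ROR ± 1.96 sqrt(1/a + 1/b + 1/c + 1/d))`. The Woolf method is
  the package's single CI convention; its agreement with the published
  intervals is verified post hoc through the recovery oracle rather than
  assumed.
- **PRR**: `[a/(a+b)] / [c/(c+d)]` with the analogous log-normal interval,
  and the Pearson chi-square *without* continuity correction. The
  uncorrected variant is the package's convention (published near-null
  rows with chi-square printed as 0.02 or 0 are consistent with it); the
  recovery oracle nevertheless accepts either variant when inverting
  published rows, because other software may differ.
- **IC/IC025**: the information component in its shrunk observed/expected
  form, `IC = log2((a + 0.5)/(E + 0.5))` with `E = (a+b)(a+c)/N`, and the
  closed-form credibility lower bound
  `IC025 = IC - 3.3 (a+0.5)^(-1/2) - 2 (a+0.5)^(-3/2)`. This form was
  chosen because published IC values in this literature equal
  `log2(EBGM)` to printed precision, indicating a shrunk-O/E formulation;
  the package tests that arithmetic relation on its transcribed reference
  rows.
- **EBGM/EB05**: the empirical-Bayes geometric mean under a two-component
  gamma-Poisson shrinker. The prior
  `w Gamma(alpha1, beta1) + (1-w) Gamma(alpha2, beta2)` is fitted once per
  analysis call on all of the call's `(a, E)` pairs by maximizing the
  negative-binomial marginal likelihood with a bounded quasi-Newton
  optimizer from the conventional start `(0.2, 0.1, 2, 4, 1/3)` -- a
  deterministic fit. The posterior is again a two-component gamma mixture;
  `EBGM = 2^(E[log2 lambda])` via digamma moments and EB05 is the 5th
  posterior percentile by monotone root finding. Both are verified against
  brute-force numerical integration in the test suite. With fewer than 20
  pairs the five-parameter mixture is weakly identified, so the fit is
  flagged low-information rather than refused; no stratification is
  applied.

A pair is a **positive signal** when `a >= 3` and the ROR 95% lower bound
exceeds 1. Pairs with `a < 3` are flagged not analyzable: their counts and
point estimates are still reported (published tables print them too), but
they never signal. Tables with a zero cell receive the Haldane-Anscombe
correction (0.5 added to all four cells) for the ROR/PRR and their
intervals -- the chi-square stays on the raw cells -- and the result is
flagged. Reported values are rounded to 2 decimals only at export;
internal computation is full precision.

Databases are analyzed independently, never pooled; multiple-testing
adjustment is deliberately absent, matching standard practice for
hypothesis-generating disproportionality screens.

## The recovery oracle

Published signal tables print, per row, the count `a` and 2-decimal ROR,
PRR and chi-square -- enough to constrain, but not uniquely determine, the
underlying table. `recover_table()` inverts a printed row by analytic
pruning: for each candidate exposure margin `b`, the printed ROR and PRR
jointly pin the ratio `d/c` (and thereby the admissible range of `b`:
`b ≈ a (PRR - 1)/(ROR - PRR)` up to rounding slack), and the chi-square
then fixes the scale of `(c, d)` through a closed-form quadratic along the
ray `d = rho c`, on which the Pearson statistic rises monotonically to the
asymptote `(a rho - b)^2 / ((a+b) rho)`. Only a thin shell of integer
candidates is ever visited; solutions are returned as runs of consecutive
`d` values.

Two numerical points deserve note. First, when the printed ROR and PRR
coincide (rare-event rows), the admissible `b` is unbounded above and the
solutions form a one-parameter family along `b`; the search then probes
the feasible range log-uniformly (`b` is a scale parameter of unknown
magnitude) so the returned set spans the family, and
`verify_printed_ci()` reports the *modal* recomputed CI bound with its
vote share rather than pretending uniqueness. Second, the two CI bounds
are not equally determined: the lower bound is stable across the family
(its spread is a few thousandths for published rows with chi-square >= 4,
and its modal rounded value reproduces the printed bound), while the upper
bound inherits the `1/c` variance of small event-margin cells and can
spread by a few hundredths. The signal rule depends only on the lower
bound, which is exactly the bound the oracle certifies. Rows with
chi-square below about 1 are near-null and ill-conditioned under 2-decimal
rounding; they are excluded from CI verification. Rounding of printed
values is assumed to be within half a printed unit in either direction,
which covers both half-up and half-even conventions.

## The synthetic generator

`generate_reports()` draws a reporting database whose statistical
structure matches what the analysis assumes, with every distribution
configurable and a closed-form ground truth:

- **Indications**: a configurable fraction of reports carry a glioma
  indication (default 0.75, emulating a glioma-enriched oncology extract),
  of which a fraction (default 0.8, chosen to match the strict/broad
  cohort ratios of 0.8-0.9 observed in published sensitivity analyses)
  uses higher-certainty malignant wording; the rest carry other cancer
  indications.
- **Exposures**: study drugs are drawn sequentially with baseline
  marginals (defaults 0.30 bevacizumab, 0.35 temozolomide, 0.06 lomustine,
  0.02 carmustine -- a realistic mix in which carmustine pairs land below
  the `a >= 3` analyzability threshold at moderate sample sizes, as they
  do in real extractions) and odds tilting for co-prescription
  (bevacizumab doubles temozolomide's odds and multiplies lomustine's by
  1.5, producing the mono / +TMZ / +LOM regimen mixture). Background
  concomitants (dexamethasone, levetiracetam, ondansetron) populate the
  comparator cells.
- **Events**: each endpoint is Bernoulli per report with
  `logit(p) = logit(baseline) + sum(log multiplier)` over exposed drugs.
  Effects are *odds* multipliers precisely so that the estimand equals the
  ROR: `true_odds_ratio()` marginalizes the generative model exactly by
  enumerating all exposure patterns, and with neutral co-exposures the
  marginal odds ratio equals the configured multiplier. Baseline
  per-report probabilities default to 0.03 (VTE), 0.02 (CNS bleeding) and
  0.012 (GI bleeding), giving event counts of the magnitude seen in the
  published glioma cohorts at comparable sizes. The default effect matrix
  encodes the published bevacizumab profile (2.3 for VTE and GI bleeding,
  1.5 for CNS bleeding; all other drugs neutral).
- **Demographics and noise**: missingness defaults mirror the published
  baseline table for bevacizumab reports (40% sex, 45% age, 71% weight
  unknown); a configurable fraction of cases (default 5%) is emitted twice
  as a version-2 near-copy differing in one demographic field, so
  deduplication correctness is observable.

Generation is vectorized and bitwise-reproducible for a fixed config and
seed, and leaves the caller's RNG stream untouched. What the generator
does *not* emulate: reporting delays and calendar time, notoriety bias,
non-English indication text, correlated missingness, and MedDRA coding
noise. Passing calibration tests on synthetic data therefore demonstrates
the correctness of the estimators under the assumed reporting model, not
robustness to those real-world distortions.

## Calibration and verification studies

The test suite runs four simulation studies at sizes chosen to keep the
full suite in the minutes range while leaving sampling error well inside
the asserted bands:

- *Null calibration*: 500 replicates of 5,000 reports with all effects 1;
  across analyzable pairs the fraction whose ROR 95% CI excludes 1 must
  lie in [0.02, 0.09] (nominal 5% two-sided, with small-sample skew).
- *Parameter recovery*: 100 replicates of 200,000 reports with a
  bevacizumab-VTE odds multiplier of 2.3; the mean estimated ROR must lie
  in (2.1, 2.5) and the CI must cover the closed-form truth at least 90%
  of the time.
- *Shrinkage oracle*: EBGM/EB05 agree with numerical integration of the
  posterior to 4 significant figures on 100 random `(a, E, prior)`
  triples, and converge to the observed O/E as evidence grows.
- *Recovery round trip*: 200 random tables with `a >= 3`, rounded to
  printed precision and recovered, always contain the original table.

## Known limitations

Disproportionality measures are reporting ratios, not incidence or risk;
nothing here adjusts for confounding by indication, treatment line,
radiotherapy or concomitant medication, and the package deliberately
provides no cross-database statistical comparison. The endpoint PT lists
are configurable approximations of unpublished originals. The recovery
oracle certifies printed *lower* CI bounds (and upper bounds only where
the event margin is large); it cannot disambiguate the exposure margin of
rare-event rows, and regimen-comparison rows that print only `a` and an
ROR are underdetermined and out of its scope.
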