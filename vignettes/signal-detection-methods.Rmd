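---
title: "Disproportionality methods behind faersignal"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Disproportionality methods behind faersignal}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(faersignal)
library(data.table)
```

## The problem and the model

Spontaneous reporting systems collect adverse-event reports without any
record of how many patients took each drug, so incidence cannot be
estimated. Case/non-case disproportionality sidesteps the missing
denominator by asking whether the *share* of target-event reports among
reports for the drug of interest exceeds the share in the rest of the
database. The package applies this to the tubulointerstitial nephritis
(TIN) Preferred Term among reports where a statin (rosuvastatin,
atorvastatin, simvastatin, pravastatin, pitavastatin or lovastatin — six
ingredients; fluvastatin is available behind a switch) is coded as the
Primary Suspect drug, stratified by calendar year 2017–2024 and by
pre-pandemic (2017–2019) versus pandemic-and-after (2020–2024) periods.

Four estimators are computed from each stratum's 2×2 table, because they
fail in different ways: the frequentist ROR and PRR are unstable at small
counts, while the Bayesian EBGM and IC shrink toward the database
background and under-call weak signals. A year is flagged on ROR > 1,
PRR ≥ 2, EBGM > 2 or IC > 0, and called an *important signal* only when
all four fire at once — the conjunction is what protects against any
single estimator's failure mode (2020 in the reference data is the
instructive case: IC marginally positive, PRR well under 2, so not
important).

## The empirical-Bayes shrinker

The MGPS model treats the observed count as a ∼ Poisson(λE), with the
relative reporting rate λ drawn from the two-component gamma mixture
w·Γ(α₁, β₁) + (1−w)·Γ(α₂, β₂) (shape/rate). The posterior is again a
gamma mixture, with components Γ(αⱼ + a, βⱼ + E) and weight

Q = w·f(a; α₁, β₁, E) / [w·f(a; α₁, β₁, E) + (1−w)·f(a; α₂, β₂, E)],

where f is the negative-binomial marginal, evaluated in log space to stay
finite at large counts. The posterior mean of ln λ has the digamma closed
form Q·(ψ(α₁+a) − ln(β₁+E)) + (1−Q)·(ψ(α₂+a) − ln(β₂+E)), and
EBGM = exp of it. The test suite checks this closed form against a
numerical integration of the posterior that uses neither the digamma
function nor the closed-form Q, to 1e−8 over a grid of (n, E) up to
(1000, 500). EB05, the 5th posterior percentile, is found by root-finding
on the mixture CDF; it is reported for completeness but takes no part in
flagging.

Hyperparameters can be fitted by maximizing the summed log marginal
likelihood over a drug–event pair universe (`pair_counts()` builds it at
report level), on an unconstrained scale (log shapes/rates, logit weight)
with three deterministic starts; components are reordered by prior mean
to resolve label switching. Sparse input (fewer than 100 usable pairs) or
optimizer failure falls back to the literature default prior
(0.2, 0.1, 2, 4, 1/3) with a warning. The annual-metrics layer uses the
default prior unless a fitted one is supplied: single-stratum (a, E)
pairs are far too few to fit on, and fitting scope is a choice the caller
should make explicitly.

The IC convention is IC = log₂(EBGM). That choice is pinned by internal
consistency of the reference annual metrics, where the printed IC equals
log₂ of the printed EBGM in every year up to rounding (e.g. log₂ 5.32 =
2.41, log₂ 2.71 = 1.44). A shrunk observed/expected variant
log₂((a+0.5)/(E+0.5)) is offered for reuse but is not the default.

## Cleaning rules and their edge cases

**Deduplication** is two passes, in order: exact duplicates on
(PRIMARYID, EVENT_DT, PT-set fingerprint) collapse first — the
fingerprint sorts normalized PTs so reaction order is irrelevant — then
only the largest CASEVERSION per CASEID survives. A missing CASEVERSION
counts as 0, so any explicitly versioned record supersedes it; version
ties break toward the larger PRIMARYID (the later submission identifier),
compared numerically via a length-then-lexicographic key. The operation
is idempotent and its audit conserves counts (input = retained + removals
by reason), both enforced by property tests.

**Name matching** is case-insensitive on word-boundary lexicon tokens, so
`"ROSUVASTATIN CALCIUM"` matches the rosuvastatin token while
`"NYSTATIN"` matches nothing; PROD_AI (the active-ingredient field) is
consulted before the verbatim DRUGNAME. The lexicon ships with generic
names and common brand/combination names and is user-extensible via a
plain-text file. The target PT is matched literally after trimming,
whitespace collapse and case folding — no MedDRA hierarchy or synonym
expansion, since the case definition is a single PT.

**Year binding** defaults to the FDA receipt date (the study window is
framed in terms of submission years), falling back to the quarter file's
own year; an event-date policy is available. Partial dates (YYYY, YYYYMM)
are kept partial, never coerced into fake full dates — year-level
stratification needs nothing more. Reports resolving outside 2017–2024
are excluded and audited.

**Age** is normalized to years from the unit code (DEC×10, MON÷12,
WK÷52.1775, DY÷365.25, HR÷8766); a missing unit is read as years, the
dominant convention in real extracts, while an unrecognized unit yields
missing-with-audit. The reporting bands are inclusive integer bands 0–17,
18–40, 41–60, 61–90, with ages above 90 in the open top band. The printed
band labels "61–90" and "≥90" overlap at 90; the package resolves the
overlap by keeping 90 in 61–90, a declared convention verified by an
enumeration test over all integer ages.

**Percentages** in descriptive tables are rounded half-away-from-zero to
one decimal (12/16 → 75.0, 3/16 → 18.8, 1/16 → 6.3), with the stratum
case count as denominator throughout; a report contributes to every
outcome code it carries but once to the denominator, so outcome
percentages need not sum to 100.

**Zero cells**: ROR and PRR receive the Haldane 0.5 correction only when
some cell is zero; with correction disabled, zero cells raise a classed
condition rather than propagating NaN. EBGM needs no correction, since
E > 0 suffices. Empty strata yield all-zero tables marked non-analyzable.

## What the generator emulates — and what it does not

`simulate_faers()` draws each report independently: year and quarter,
receipt and (possibly partial) event dates, a statin primary suspect with
per-year probability 0.10, otherwise a power-law-weighted background
drug; the TIN PT with probability 0.008·ρ(year) for statin reports and
0.008 otherwise; 1–3 reaction PTs (geometric), 0–3 concomitant drugs,
0–2 outcome codes, and demographics from fixed mixes (elderly-skewed ages
around 67 ± 15 years, hospitalization-heavy outcomes, US-dominated
countries). The default planted ratio ρ is 1 through 2020, then 2, 3,
2.5, 6 — a null-then-emergent trajectory shaped like the reference
analysis. Exact duplicates (2%) and second case versions (3%) are
injected, in two modes that exercise the two dedup passes separately:
same-PRIMARYID copies placed in the next quarter file, or fresh-PRIMARYID
copies sharing CASEID and CASEVERSION. The per-year sizes (8 × 5,000
reports for the recovery experiments) keep a full ten-seed end-to-end run
inside a couple of minutes while leaving ~40 expected background TIN
reports per year, enough for stable background cells.

`emulate_reference_margins()` instead calibrates the statin share and ρ(y) so
the *expected* per-year statin report counts and TIN case counts equal
the published margins (7,646 statin reports in 2017 through 8,503 in
2024; 5, 9, 2, 12, 17, 16, 17, 42 TIN cases), enabling shape-level
comparison against the reference table.

What passing recovery tests show is that the pipeline correctly recovers
a *planted* reporting-rate ratio from data whose generative model it
matches. Real FAERS data violate that model in ways the generator does
not attempt: reporting rates drift with publicity (the Weber effect and
stimulated reporting), drugs and events co-occur with pharmacological
structure, names are misspelled free text, duplicates are near- rather
than exact copies, and the full database is three orders of magnitude
larger. Recovery on synthetic data is therefore a correctness check on
the machinery, not evidence about the real statin–TIN association — and
the published per-year ROR confidence intervals and EBGM magnitudes
cannot be reproduced at this scale, because their background cells c and
d come from the full database.

## Design choices that were genuinely open

- **Background cells**: c and d count all non-statin-PS reports in the
  stratum, so reports with a statin as secondary suspect or concomitant
  sit in the background. Unit of counting is the report: a report with
  two PS statins counts once.
- **Dedup tie-break** (equal CASEVERSION under one CASEID): larger
  PRIMARYID wins — deterministic and monotone with submission order.
- **File dialect**: `$`-delimited with header, UTF-8 with Latin-1
  fallback, column names matched case-insensitively. Real extracts do not
  escape embedded delimiters, so the reader folds overflow fields back
  into the last column; the package's own writer escapes `$` inside
  fields so that write→read is an exact identity, which the round-trip
  property tests rely on.
- **Occupation grouping**: MD → Physician, PH → Pharmacist, OT/HP/RN →
  other healthcare professional, everything else (consumers, lawyers,
  missing) → unknown/other. The composition of the "other healthcare
  professional" group is a declared mapping, not something the reference
  tables pin down.
- **The PRR chi-square** companion of the classic Evans rule is computed
  (`prr_chisq()`) but excluded from flagging, which uses exactly the four
  thresholds above.
- An optional criterion on the ROR interval lower bound exists in
  `signal_thresholds()` but is off by default; the narrative "threshold
  of 2" sometimes quoted for ROR is treated as commentary, not a rule.

## Known limitations

Disproportionality quantifies reporting, not risk: no causal or
incidence statement follows from a flagged year. The pipeline performs
no probabilistic record linkage beyond the stated dedup keys, no
multiple-comparison adjustment across events (none is part of the
four-threshold rule), no time-to-onset analysis, and no per-molecule
statin comparisons — the class-level analysis set is the designed scope.
Hyperparameter fitting assumes a pair universe large enough for a
five-parameter mixture; per-stratum fitting is deliberately not offered
as a default.
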