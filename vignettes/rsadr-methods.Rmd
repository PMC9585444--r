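---
title: "Methods: building and interrogating a drug-ADR reference standard"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: building and interrogating a drug-ADR reference standard}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rsadr)
library(dplyr)
```

## The problem

Computational pharmacovigilance produces adverse-drug-reaction (ADR)
signals by the tens of thousands — disproportionality statistics from
spontaneous-report databases, odds and hazard ratios from
electronic-health-record (EHR) cohorts. Validating those signals
requires a *reference standard*: a grid of drug-ADR pairs labeled as
known associations (positive controls) or believed non-associations
(negative controls). No single public resource supplies such a grid at
useful scale, and the candidate resources speak different vocabularies
(product-label side-effect lists keyed to MedDRA preferred terms,
epidemiological reference sets keyed to outcome definitions, hospital
data keyed to LOINC tests, ICD-10 codes and coded nursing statements).

`rsadr` implements the construction pipeline in four stages:

1. **Vocabulary harmonization** (`pv_dictionary()`): every ADR concept
   is anchored on a MedDRA preferred term (PT) and carries its UMLS
   concept id, system organ class, WHO-ART / narrative terms, LOINC
   laboratory mappings (each with a *direction* of abnormality) and
   ICD-10 codes; drugs are anchored on ATC codes.
2. **Reference matrix assembly** (`ingest_source()`,
   `build_reference_matrix()`): each reference source votes 0
   (negative), 1 (positive) or 2 (unknown) on each cell of the
   drugs × ADRs grid; a consensus rule combines the votes.
3. **Signal statistics** (`build_contingency()`, `odds_ratio()`,
   `ehr_lab_signal()`, `load_partner_results()`): reporting odds
   ratios from report-level data, subject-level lab-abnormality odds
   ratios, and ingestion of partner-supplied summary estimates.
4. **Meta-analysis and causality** (`pool_random_effects()`,
   `assess_causality()`, `pair_report()`): DerSimonian–Laird pooling
   of the per-partner estimates and a WHO-UMC style categorical
   causality assessment per pair.

## The consensus vote

A cell's per-source labels are combined by a pluggable policy. The
default, `"flag"`, is deliberately conservative: unanimity keeps the
label, an empty vote set stays unknown, and any disagreement becomes
`"conflicting"`. Published reference sets are known to disagree — the
union counts reported for merged positive/negative sets do not equal
the per-source sums, evidence of an unstated dedup/conflict step — so
the default surfaces conflicts for review instead of resolving them
silently. `"negative-precedence"`, `"positive-precedence"` and
`"majority"` (ties conflict) are available when a hard 0/1 grid is
needed.

Storage is sparse by exception. A full-scale grid (1344 drugs × 4485
PTs = 6,027,840 cells) is more than 97% unknown, so only voted cells
are materialized and totals are computed from index sizes, never by
enumeration.

### Coverage rounding

Covered fractions are printed half-up with one decimal below 50% and
as whole percents at or above (2.33 → 2.3, 13.82 → 13.8, 52.78 → 53).
This is the only simple half-up rule consistent with the conventions
seen across published per-source coverage figures, which mix
one-decimal and integer renderings.

## Signal statistics

The 2×2 unit of analysis for spontaneous data is **one report**:
`a` co-mentions, `b` drug-only, `c` event-only, `d` neither. The
reporting odds ratio is `ad/bc` with Woolf log-scale standard error
`sqrt(1/a+1/b+1/c+1/d)`, a 95% Wald interval, and a two-sided Wald
p-value on the log scale (a Pearson chi-square is available via
`chisq_p()` as a side column; it never drives decisions). Duplicate
report deduplication is out of scope; the synthetic generator emits
unique reports.

**Continuity correction.** Zero cells are handled by Haldane–Anscombe
(+0.5 to every cell), applied *only* when a cell is zero and only when
enabled (`correction = TRUE`, the default in `signal_scan()`, since
batch scans over a sparse grid hit empty cells constantly). In strict
mode a zero cell is an explicit degenerate-table error.

**EHR lab signal.** `ehr_lab_signal()` is a declared simplification:
subjects are cross-classified by exposure and by occurrence of a
*direction-consistent* abnormal laboratory value (below range for a
`low` ADR, above range for `high`, either for `any`; a PT mapped to
several LOINC tests unions their abnormal events). For exposed
subjects only post-exposure abnormalities count. It does not attempt
covariate adjustment or subject sampling; partner estimates produced
by more sophisticated in-house EHR machinery enter the pipeline as
ingested rows instead.

**SE recovery from printed tables.** Partner rows often arrive as
point estimate plus p-value only. When a CI is present the SE is
`(ln hi − ln lo)/(2 × 1.959964)`; otherwise it is inverted from the
two-sided Wald p, `|ln OR| / z(1 − p/2)`; a bounded `"<.001"` is taken
at its bound, which gives the *largest* SE consistent with the bound —
the conservative choice for pooling. The recovery route is recorded on
every row (`se_source`), and pooling flags any SE-from-p input.

## Random-effects pooling

`pool_random_effects()` implements the DerSimonian–Laird moment
estimator — the pharmacovigilance default when only "a random-effects
model" is assumed: fixed weights `w = 1/se²`, Cochran's
`Q = Σ w (y − ŷ_F)²`,
`τ² = max(0, (Q − (k−1)) / (Σw − Σw²/Σw))`, then inverse-variance
pooling with weights `1/(se² + τ²)`. `I² = max(0, (Q−(k−1))/Q)·100`.
The z critical value is fixed at 1.959964 throughout for bit-stable
intervals. Hazard ratios pool on the log scale alongside odds ratios,
with a mixed-effect-measure warning: the alternative — discarding
partner evidence — is worse for a screening-stage consensus, but the
warning keeps the mixture visible. The estimator is recorded in every
export; REML could be added behind the same surface.

Known behavior tolerated by design: DL slightly undercovers at small
`k`; the package's own calibration checks accept 90–98% empirical
coverage of the true effect at `k = 6`, `τ = 0`.

## Causality rubric

The WHO-UMC categories require clinical course information
(dechallenge/rechallenge) that observational real-world evidence does
not supply, so the automatic rubric tops out at **possible**:

| condition | category |
|---|---|
| no estimates | conditional/unclassified |
| significant + user `rechallenge` flag | certain |
| significant + user `dechallenge` flag | probable/likely |
| CI spans 1 (or protective) + reference negative | unlikely |
| CI spans 1 (or protective), otherwise | conditional/unclassified |
| significant, single data partner | conditional/unclassified |
| significant, ≥ 2 partners | possible |

"Significant" means the pooled 95% CI excludes 1 *and* the pooled
point exceeds 1; protective effects (point < 1, CI excluding 1) set
their own flag and never upgrade a category. The rubric is an explicit
design stand-in for what is, in practice, often an expert judgment; it
is total and deterministic over the evidence flags and every fired
rule is recorded in `rubric_trace`.

## The synthetic-data generators

All inputs can be generated with recorded ground truth
(`sim_config()`, `simulate_reports()`, `simulate_partner_estimates()`,
`simulate_reference_fixture()`, `simulate_cohort()`), so the whole
pipeline is testable without licensed terminologies or real reporting
databases.

**Reports.** Drugs and events are mentioned independently at baseline
rates (defaults: drug 0.10, event 0.05 per report — mention rates
typical of a mid-prevalence drug and a common laboratory ADR in
spontaneous data). For a planted pair the event probability given the
drug is raised to `q = r·p/(1 − p + r·p)`, which makes the *expected*
2×2 carry exactly the reporting odds ratio `r` (the `c`/`d` margin is
untouched). The planted quantity is the ROR — the thing the estimator
measures — not a risk ratio. Default size is 20,000 reports, large
enough that the log-ROR estimator is approximately unbiased while a
multi-seed recovery run still takes seconds.

**Partner estimates.** `k` log estimates are drawn as
`y = μ + N(0, τ²) + N(0, se²)` and emitted with the true within-study
SE encoded in the CI. Defaults (`k = 6`, `μ = 0.4`, `se = 0.15`,
`τ = 0.2`) describe a realistic multi-site consortium: half a dozen
partners, moderate precision, heterogeneity comparable to the
within-study noise.

**Reference fixtures.** Sources receive exactly the requested numbers
of positive/negative cells, sampled disjointly across sources except
for an optional `conflict_quota` shared with opposite labels between
the first two sources — so the downstream conflicting-consensus count
is known exactly. The default census mirrors the published per-source
counts (140,230/0; 1,556/2,801; 421/349) on the 1344 × 4485 universe.

Each generator draws from its own seed stream derived from the master
seed, so adding a generator never perturbs existing fixtures, and
identical config + seed is byte-identical.

**What the generators do not emulate:** polypharmacy and comorbidity
correlation structure, temporal reporting trends, duplicate and
incomplete reports, informative lab-measurement timing, and the
terminological messiness of real source vocabularies. Passing
recovery tests therefore demonstrates the *estimators and accounting*
are correct under clean conditions, not that real FAERS/EHR extracts
would yield the same effect sizes.

## Numerical and degenerate-input choices

- Half-up rounding (not banker's) for printed percentages.
- `z = 1.959964` fixed everywhere a 95% interval is formed.
- `k = 0` pooling returns a typed no-estimates value (it drives the
  causality flag); a missing per-row SE is an error naming the row.
- Zero-cell 2×2: error in strict mode, +0.5 correction otherwise.
- Ambiguous synonyms, duplicate PTs/CUIs, malformed ATC/CUI/ICD-10
  codes and invalid LOINC directions are load-time errors naming rows;
  an unresolvable reference row is retained with a reason, and a pair
  referencing keys outside the matrix index is skipped with a warning
  count (the matrix is defined over the dictionary's universe).
- Terminology versions are carried as config strings and never
  validated against live services.

## Problem sizes used in the checks

The packaged checks run the full 1344 × 4485 accounting once
(sparse, a few seconds), 1,000 randomized pooling oracle comparisons,
500-replicate pooled-effect/τ² recovery, planted-ROR recovery on
20,000-report sets across seeds, 200 five-thousand-subject cohort
replicates for CI calibration, and exhaustive truth-table enumeration
for the consensus and causality rules. These sizes were chosen so the
Monte-Carlo error of each check is comfortably below the tolerance it
asserts.

## Known limitations

- The consensus vote records disagreement; it does not adjudicate it.
- SE-from-p recovery inherits the printed p's rounding; pooled CIs
  built from such rows are approximate, which is why the worked
  example's pooled interval is reported but not treated as exact.
- The lab signal is unadjusted and first-exposure based; it is a
  screening statistic, not an effect estimate for inference.
- The causality rubric is a transparent, deterministic stand-in for
  what is in practice a partly expert-driven judgment.
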