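# rsadr

Reference standards and signal statistics for pharmacovigilance.

Computational drug-safety pipelines emit adverse-drug-reaction (ADR)
signals far faster than they can be validated, because there is no
single reference standard saying which drug-ADR pairs are real and
which are known non-associations. `rsadr` builds one: it harmonizes
drug and ADR vocabularies (ATC; MedDRA preferred terms with UMLS CUIs,
system organ classes, WHO-ART/narrative terms, LOINC laboratory tests
with an abnormality direction, ICD-10 codes), ingests heterogeneous
reference sources into a sparse drugs × ADRs matrix of per-source
labels (0 = negative control, 1 = positive control, 2 = unknown) with
a consensus vote per cell, computes signal statistics from report- and
subject-level data, pools partner estimates with a random-effects
meta-analysis, and emits a WHO-UMC style causality category per pair.

The statistical core, in standard notation:

- **Reporting odds ratio** from the per-report 2×2 table
  (a = drug & event, b, c, d):
  `ROR = ad/bc`, `SE(ln ROR) = sqrt(1/a + 1/b + 1/c + 1/d)`, Wald 95%
  CI and two-sided Wald p on the log scale; Haldane–Anscombe +0.5
  correction for zero cells when enabled.
- **DerSimonian–Laird random-effects pooling** of k log-scale
  estimates: fixed weights `w_i = 1/se_i²`,
  `Q = Σ w_i (y_i − ŷ_F)²`,
  `τ̂² = max(0, (Q − (k−1)) / (Σw − Σw²/Σw))`, RE weights
  `w*_i = 1/(se_i² + τ̂²)`, pooled `ŷ = Σw*y/Σw*`, 95% CI
  `exp(ŷ ± 1.959964/√Σw*)`, `I² = max(0, (Q−(k−1))/Q)·100`.
- **Causality rubric** on the pooled CI and the reference consensus;
  the automatic scale tops out at "possible" (higher WHO-UMC
  categories need dechallenge/rechallenge evidence supplied
  explicitly).

Everything is tibble-in/tibble-out and pipe-friendly; fitted results
have `tidy()`, `glance()` and `autoplot()` methods. Seeded generators
(`sim_config()` and friends) produce every input format with recorded
ground truth.

## Worked example

The package bundles a miniature fixture (`example_fixture_dir()`)
mirroring a classic worked example: fluconazole (ATC J02AC01) and
hypokalemia (LOINC 2823_3, direction *low*; ICD-10 E87.6), with SIDER
voting positive, OMOP and EU-ADR abstaining, and four partner
estimates (HR 1.47, OR 3.04, OR 1.58, ROR 1.83, SEs recovered from
the printed p-values).

```r
library(rsadr)
demo <- example_fixture_dir()
dict <- read_pv_dictionary(demo, quiet = TRUE)
srcs <- lapply(c("SIDER", "OMOP", "EUADR"), function(id)
  ingest_source(file.path(demo, paste0("refsource_", id, ".tsv")), id, dict))
mat  <- build_reference_matrix(dict$drugs$drug_id, dict$adrs$pt_name, srcs)
est  <- load_partner_results(file.path(demo, "partner_results.tsv"), dict)
fl   <- est[est$drug == "fluconazole", ]
pair_report(dict, mat, fl, "fluconazole", "hypokalemia")
```

```
== Pair report: fluconazole / Hypokalemia ==
Drug
  ATC: J02AC01
ADR
  MedDRA PT: Hypokalemia
  SOC: Metabolism and nutrition disorders
  UMLS CUI: C0020621
Part 1: vocabulary mappings
  WHO-ART: Hypokalemia
  LOINC: 2823_3 (Potassium (moles/volume) in serum or plasma, direction=low)
  LOINC: 2823_3 (Potassium (moles/volume) in serum or plasma, direction=low)
  ICD-10: E87.6
Part 2: reference sources (0=negative, 1=positive, 2=unknown)
  SIDER: 1
  OMOP: 2
  EUADR: 2
  consensus: positive
Part 3: data partner estimates
  SNUH-MetaNurse: HR 1.47, p<.001
  SNUH-MetaLAB: OR 3.04, p<.001
  KYUH-MetaLAB: OR 1.58, p<.001
  FAERS: ROR 1.83, p<.001
Part 4: meta-analysis and causality
  pooled 1.68 (1.37-2.06), k=4
  causality: possible
```

Reading it: part 1 shows every vocabulary route by which the ADR can
be detected in narrative, laboratory or administrative data (the two
LOINC lines are the same potassium test mapped at two sites); part 2
shows one positive reference vote and two abstentions, hence a
positive consensus; part 3 lists the partner estimates on their
native scales; part 4 pools them on the log scale (OR 1.68, 95% CI
1.37–2.06 — significant, from ≥ 2 partners, reference-positive) and
the rubric returns **possible**, the ceiling for purely observational
evidence.

```r
glance(pool_random_effects(fl))
#> # A tibble: 1 × 8
#>       k pooled_point ci_low ci_high   tau2 q_stat    i2 warnings
#>   <int>        <dbl>  <dbl>   <dbl>  <dbl>  <dbl> <dbl> <chr>
#> 1     4         1.68   1.37    2.06 0.0150   4.63  35.2 mixed-effect-measures,se-recovered-from-p
```

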