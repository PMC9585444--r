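Package: rsadr
Title: Reference Standards and Signal Statistics for Pharmacovigilance
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Toolkit for constructing drug-adverse-drug-reaction (ADR)
    reference standards from heterogeneous evidence. Harmonizes drug and ADR
    vocabularies (ATC, MedDRA preferred terms, UMLS concept identifiers,
    WHO-ART, LOINC with abnormality direction, ICD-10) into a queryable
    dictionary; ingests positive/negative reference sources into a sparse
    drugs-by-ADRs matrix with per-source labels and a pluggable consensus
    vote; computes reporting odds ratios and odds ratios with log-scale
    uncertainty from spontaneous reports and electronic-health-record style
    cohorts; pools partner estimates with a DerSimonian-Laird random-effects
    meta-analysis; and assigns WHO-UMC style causality categories. Includes
    seeded synthetic-data generators with recorded ground truth so every
    stage is testable without access to licensed terminologies or real
    reporting databases.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    metafor,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
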