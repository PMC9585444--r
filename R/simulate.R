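## Synthetic-data generators. Every pipeline input can be produced here
## with recorded ground truth, so all stages are testable without
## licensed terminologies or real reporting databases.

## Run code under a derived, stream-specific seed without disturbing the
## caller's RNG state. One stream per generator: adding a generator
## never perturbs fixtures produced by another.
with_stream_seed <- function(seed, stream, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(derive_seed(seed, stream))
  force(code)
}

#' Configuration for the synthetic-data generators
#'
#' One config object drives all generators; identical config + seed
#' gives byte-identical outputs.
#'
#' @param seed integer master seed; each generator derives its own
#'   stream seed from it.
#' @param n_drugs,n_adrs size of the synthetic drug/ADR universe (keys
#'   `D0001...`, `A0001...`).
#' @param n_reports number of spontaneous reports to simulate.
#' @param planted_pairs data frame `drug`, `adr`, `true_ror` of
#'   associations to plant in the reports; each ADR may appear at most
#'   once (its conditional event probability is set by its drug).
#' @param baseline_drug_prob,baseline_event_prob per-report mention
#'   probabilities for unplanted drugs/events, in (0, 1).
#' @param partner_spec list `k`, `true_log_effect`, `within_se`, `tau`
#'   for the partner-estimate generator.
#' @param refsource_spec data frame `source_id`, `n_positive`,
#'   `n_negative` for the reference-source generator.
#' @param conflict_quota number of cells deliberately labeled positive
#'   by the first source and negative by the second (requires >= 2
#'   sources); all other sampled cells are disjoint across sources, so
#'   the consensus "conflicting" count equals the quota exactly.
#' @param dict_spec optional list `n_narrative`, `n_loinc`, `n_icd`:
#'   how many PTs receive a mapping in each channel (independent random
#'   subsets; channels may overlap).
#' @return object of class `sim_config`.
#' @export
sim_config <- function(seed = 1L, n_drugs = 10L, n_adrs = 8L,
                       n_reports = 20000L,
                       planted_pairs = NULL,
                       baseline_drug_prob = 0.1,
                       baseline_event_prob = 0.05,
                       partner_spec = list(k = 6L, true_log_effect = 0.4,
                                           within_se = 0.15, tau = 0.2),
                       refsource_spec = tibble::tibble(
                         source_id = c("SIDER", "OMOP", "EUADR"),
                         n_positive = c(140230L, 1556L, 421L),
                         n_negative = c(0L, 2801L, 349L)),
                       conflict_quota = 0L,
                       dict_spec = NULL) {
  stopifnot(baseline_drug_prob > 0, baseline_drug_prob < 1,
            baseline_event_prob > 0, baseline_event_prob < 1)
  if (!is.null(planted_pairs)) {
    planted_pairs <- tibble::as_tibble(planted_pairs)
    stopifnot(all(c("drug", "adr", "true_ror") %in% names(planted_pairs)),
              all(planted_pairs$true_ror > 0))
    if (anyDuplicated(planted_pairs$adr)) {
      abort("each ADR may be planted for at most one drug")
    }
  }
  refsource_spec <- tibble::as_tibble(refsource_spec)
  structure(
    list(seed = as.integer(seed), n_drugs = as.integer(n_drugs),
         n_adrs = as.integer(n_adrs), n_reports = as.integer(n_reports),
         planted_pairs = planted_pairs,
         baseline_drug_prob = baseline_drug_prob,
         baseline_event_prob = baseline_event_prob,
         partner_spec = partner_spec, refsource_spec = refsource_spec,
         conflict_quota = as.integer(conflict_quota),
         dict_spec = dict_spec),
    class = "sim_config")
}

drug_keys <- function(n) sprintf("D%04d", seq_len(n))
adr_keys <- function(n) sprintf("A%04d", seq_len(n))

#' Simulate spontaneous reports with planted associations
#'
#' Each report mentions every drug independently with probability
#' `baseline_drug_prob` and every event with `baseline_event_prob`,
#' except planted pairs: there the event probability *given the drug is
#' mentioned* is raised so that the expected 2x2 table has exactly the
#' requested reporting odds ratio. Writing `q` for that conditional
#' probability and `p` for the baseline event probability, the expected
#' ROR is `[q/(1-q)] / [p/(1-p)]`, so
#' `q = r*p / (1 - p + r*p)` plants ROR `r`. (The event keeps
#' probability `p` when the drug is absent, so the `c`/`d` margin is
#' untouched.)
#'
#' @param config a [sim_config()].
#' @param out_dir optional directory; writes `reports.tsv` and the
#'   `ground_truth.json` sidecar.
#' @return list: `reports` (a [as_report_table()] tibble) and
#'   `ground_truth` (planted pairs with their exact expected cells and
#'   true ROR).
#' @export
simulate_reports <- function(config, out_dir = NULL) {
  stopifnot(inherits(config, "sim_config"))
  dk <- drug_keys(config$n_drugs)
  ak <- adr_keys(config$n_adrs)
  n <- config$n_reports
  p_d <- config$baseline_drug_prob
  p_e <- config$baseline_event_prob

  planted <- config$planted_pairs
  if (!is.null(planted)) {
    bad <- setdiff(c(planted$drug, planted$adr), c(dk, ak))
    bad <- bad[!bad %in% dk & !bad %in% ak]
    if (length(bad)) {
      abort(paste0("planted pair keys outside the simulated universe: ",
                   paste(bad, collapse = ", ")))
    }
    odds <- planted$true_ror * p_e / (1 - p_e)
    planted$q <- odds / (1 + odds)
    if (any(planted$q <= 0 | planted$q >= 1)) {
      i <- which(planted$q <= 0 | planted$q >= 1)[1]
      abort(paste0("planted ROR for ", planted$drug[i], "/", planted$adr[i],
                   " pushes the conditional event probability out of (0,1)"))
    }
  }

  res <- with_stream_seed(config$seed, "reports", {
    drug_m <- matrix(rbinom(n * config$n_drugs, 1, p_d),
                     nrow = n, dimnames = list(NULL, dk))
    event_m <- matrix(rbinom(n * config$n_adrs, 1, p_e),
                      nrow = n, dimnames = list(NULL, ak))
    if (!is.null(planted)) {
      for (i in seq_len(nrow(planted))) {
        with_drug <- drug_m[, planted$drug[i]] == 1
        event_m[with_drug, planted$adr[i]] <-
          rbinom(sum(with_drug), 1, planted$q[i])
      }
    }
    list(drug_m = drug_m, event_m = event_m)
  })

  reports <- as_report_table(tibble::tibble(
    report_id = sprintf("R%06d", seq_len(n)),
    drugs = apply(res$drug_m, 1, function(r) dk[r == 1],
                  simplify = FALSE),
    events = apply(res$event_m, 1, function(r) ak[r == 1],
                   simplify = FALSE)))

  gt <- list(n_reports = n, baseline_drug_prob = p_d,
             baseline_event_prob = p_e)
  if (!is.null(planted)) {
    gt$planted <- dplyr::mutate(
      planted,
      expected_a = n * p_d * .data$q,
      expected_b = n * p_d * (1 - .data$q),
      expected_c = n * (1 - p_d) * p_e,
      expected_d = n * (1 - p_d) * (1 - p_e))
  }

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_reports(reports, file.path(out_dir, "reports.tsv"))
    jsonlite::write_json(gt, file.path(out_dir, "ground_truth.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  list(reports = reports, ground_truth = gt)
}

#' Simulate partner summary estimates around a known true effect
#'
#' Draws `k` log-scale estimates `y_i = mu + u_i + e_i` with
#' between-study deviation `u_i ~ N(0, tau^2)` and within-study noise
#' `e_i ~ N(0, within_se^2)`, then emits them in the
#' `partner_results.tsv` layout with the *true* within-study SE encoded
#' in the 95% CI and a two-sided Wald p-value.
#'
#' @param config a [sim_config()]; uses `partner_spec`.
#' @param drug,adr keys stamped on every row.
#' @param out_dir optional directory; writes `partner_results.tsv` and
#'   `ground_truth.json`.
#' @return list: `partners` (ingestable tibble) and `ground_truth`
#'   (`true_log_effect`, `tau`, `within_se`, the drawn per-study true
#'   effects).
#' @export
simulate_partner_estimates <- function(config, drug = "D0001",
                                       adr = "A0001", out_dir = NULL) {
  stopifnot(inherits(config, "sim_config"))
  ps <- config$partner_spec
  stopifnot(ps$k >= 1, ps$within_se > 0, ps$tau >= 0)
  draws <- with_stream_seed(config$seed, "partners", {
    u <- rnorm(ps$k, 0, ps$tau)
    e <- rnorm(ps$k, 0, ps$within_se)
    list(u = u, y = ps$true_log_effect + u + e)
  })
  y <- draws$y
  partners <- tibble::tibble(
    partner_id = sprintf("P%02d", seq_len(ps$k)),
    drug = drug, adr = adr, estimate_type = "OR",
    point = exp(y),
    ci_low = exp(y - Z95 * ps$within_se),
    ci_high = exp(y + Z95 * ps$within_se),
    p_value = as.character(2 * pnorm(-abs(y) / ps$within_se)),
    n = NA_character_)
  gt <- list(true_log_effect = ps$true_log_effect, tau = ps$tau,
             within_se = ps$within_se, k = ps$k,
             study_effects = ps$true_log_effect + draws$u)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_tsv_plain(partners, file.path(out_dir, "partner_results.tsv"))
    jsonlite::write_json(gt, file.path(out_dir, "ground_truth.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  list(partners = partners, ground_truth = gt)
}

## A few real SOC names for readable fixtures; cycled over the universe.
SOC_POOL <- c("Metabolism and nutrition disorders",
              "Hepatobiliary disorders",
              "Gastrointestinal disorders",
              "Nervous system disorders",
              "Skin and subcutaneous tissue disorders",
              "Cardiac disorders")

#' Simulate reference sources and the matching dictionary fixture
#'
#' Builds a synthetic drug/ADR universe (`drugs.tsv` / `adrs.tsv`
#' content with valid ATC codes and CUIs) and, for each entry of
#' `refsource_spec`, a reference source with exactly the requested
#' numbers of positive and negative pairs sampled from the universe.
#' Cells are disjoint across sources except for `conflict_quota` cells
#' shared between the first two sources with opposite labels, so the
#' downstream consensus "conflicting" count equals the quota exactly.
#'
#' @param config a [sim_config()].
#' @param out_dir optional directory; writes `drugs.tsv`, `adrs.tsv`,
#'   per-source `refsource_<id>.tsv`, optional mapping tables, and
#'   `ground_truth.json`.
#' @return list: `drugs`, `adrs`, mapping tables (`narrative`, `loinc`,
#'   `icd` — populated when `dict_spec` is set), `sources` (named list
#'   of pair tibbles in `refsource.tsv` layout), and `ground_truth`
#'   (per-source counts, the conflict quota, channel mapping counts).
#' @export
simulate_reference_fixture <- function(config, out_dir = NULL) {
  stopifnot(inherits(config, "sim_config"))
  dk <- drug_keys(config$n_drugs)
  ak <- adr_keys(config$n_adrs)
  total <- as.numeric(config$n_drugs) * config$n_adrs
  spec <- config$refsource_spec
  need <- sum(spec$n_positive + spec$n_negative) - config$conflict_quota
  if (any(spec$n_positive + spec$n_negative > total)) {
    abort("a source requests more pairs than the universe holds")
  }
  if (need > total) {
    abort("requested source pair counts exceed the drug x ADR universe")
  }
  if (config$conflict_quota > 0 && nrow(spec) < 2) {
    abort("conflict_quota requires at least two sources")
  }

  out <- with_stream_seed(config$seed, "refsources", {
    drugs <- tibble::tibble(
      drug_id = dk,
      name = paste0("drug-", tolower(dk)),
      ## injective mixed-radix encoding of the drug index into the
      ## 7-character ATC shape, so synthetic codes never collide
      atc_codes = {
        i <- seq_along(dk) - 1
        sprintf("%s%02d%s%s%02d",
                LETTERS[(i %/% (100 * 26 * 26 * 100)) %% 26 + 1],
                (i %/% (26 * 26 * 100)) %% 100,
                LETTERS[(i %/% (26 * 100)) %% 26 + 1],
                LETTERS[(i %/% 100) %% 26 + 1],
                i %% 100)
      })
    adrs <- tibble::tibble(
      pt_name = paste0("Synthetic reaction ", sub("^A", "", ak)),
      umls_cui = sprintf("C9%06d", seq_along(ak)),
      soc = SOC_POOL[(seq_along(ak) - 1) %% length(SOC_POOL) + 1])

    ## Sample disjoint cell indices for all sources in one pass, then
    ## carve per-source slices; conflict cells are re-used across the
    ## first two sources with opposite labels.
    n_conf <- config$conflict_quota
    cells <- sample(total, need)
    pos <- 1L
    take <- function(n) {
      if (n == 0) return(numeric(0))
      out <- cells[pos:(pos + n - 1)]
      pos <<- pos + n
      out
    }
    conf_cells <- take(n_conf)
    sources <- list()
    for (i in seq_len(nrow(spec))) {
      np <- spec$n_positive[i]
      nn <- spec$n_negative[i]
      if (i == 1 && n_conf > 0) {
        p_cells <- c(conf_cells, take(np - n_conf))
        n_cells_i <- take(nn)
      } else if (i == 2 && n_conf > 0) {
        p_cells <- take(np)
        n_cells_i <- c(conf_cells, take(nn - n_conf))
      } else {
        p_cells <- take(np)
        n_cells_i <- take(nn)
      }
      idx <- c(p_cells, n_cells_i)
      sources[[spec$source_id[i]]] <- tibble::tibble(
        drug = dk[(idx - 1) %% config$n_drugs + 1],
        adr = adrs$pt_name[(idx - 1) %/% config$n_drugs + 1],
        label = rep(c("positive", "negative"),
                    c(length(p_cells), length(n_cells_i))),
        evidence = "synthetic")
    }

    maps <- list(narrative = NULL, loinc = NULL, icd = NULL)
    ds <- config$dict_spec
    if (!is.null(ds)) {
      pick <- function(n) sort(sample(length(ak), min(n, length(ak))))
      ni <- pick(ds$n_narrative %||% 0)
      li <- pick(ds$n_loinc %||% 0)
      ii <- pick(ds$n_icd %||% 0)
      maps$narrative <- tibble::tibble(
        pt_name = adrs$pt_name[ni], site_id = "SITE1",
        statement = paste0("statement for ", adrs$pt_name[ni]),
        who_art_term = adrs$pt_name[ni])
      maps$loinc <- tibble::tibble(
        pt_name = adrs$pt_name[li],
        loinc_id = sprintf("%d_%d", 1000 + li, li %% 10),
        common_name = paste0("analyte ", li),
        direction = c("low", "high", "any")[li %% 3 + 1],
        site_id = "SITE1", local_code = sprintf("L%03d", li),
        local_name = paste0("local test ", li))
      maps$icd <- tibble::tibble(
        pt_name = adrs$pt_name[ii],
        icd10_code = sprintf("%s%02d.%d",
                             LETTERS[ii %% 26 + 1], ii %% 100, ii %% 10),
        icd10_name = adrs$pt_name[ii])
    }
    list(drugs = drugs, adrs = adrs, sources = sources, maps = maps)
  })

  gt <- list(
    n_drugs = config$n_drugs, n_adrs = config$n_adrs, total_cells = total,
    sources = as.data.frame(spec), conflict_quota = config$conflict_quota,
    channel_counts = if (is.null(config$dict_spec)) NULL else list(
      narrative = nrow(out$maps$narrative),
      laboratory = nrow(out$maps$loinc),
      disease_classification = nrow(out$maps$icd)))

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_tsv_plain(out$drugs, file.path(out_dir, "drugs.tsv"))
    write_tsv_plain(out$adrs, file.path(out_dir, "adrs.tsv"))
    for (id in names(out$sources)) {
      write_tsv_plain(out$sources[[id]],
                      file.path(out_dir, paste0("refsource_", id, ".tsv")))
    }
    if (!is.null(out$maps$narrative)) {
      write_tsv_plain(out$maps$narrative,
                      file.path(out_dir, "adr_narrative.tsv"))
      write_tsv_plain(out$maps$loinc, file.path(out_dir, "adr_loinc.tsv"))
      write_tsv_plain(out$maps$icd, file.path(out_dir, "adr_icd.tsv"))
    }
    jsonlite::write_json(gt, file.path(out_dir, "ground_truth.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  c(out[c("drugs", "adrs")], out$maps,
    list(sources = out$sources, ground_truth = gt))
}

#' Simulate a subject-level cohort with a planted exposure-lab odds ratio
#'
#' Builds `cohort_exposures` / `cohort_labs` style tables: each subject
#' is exposed to the drug with probability `p_exposed` (exposure starts
#' day 0) and receives one measurement of the given LOINC test on day 5.
#' Unexposed subjects go below the reference range with probability
#' `baseline_prob`; exposed subjects with the probability whose odds are
#' `true_or` times the baseline odds, so the expected subject-level 2x2
#' carries exactly the planted odds ratio.
#'
#' @param n_subjects cohort size.
#' @param true_or planted odds ratio (> 0).
#' @param p_exposed exposure probability, in (0, 1).
#' @param baseline_prob baseline abnormal-low probability, in (0, 1).
#' @param drug,loinc_id keys used in the emitted tables.
#' @param seed integer seed (own stream).
#' @return list: `exposures`, `labs` (tibbles), `ground_truth`
#'   (planted OR and expected cells).
#' @export
simulate_cohort <- function(n_subjects = 5000, true_or = 2,
                            p_exposed = 0.3, baseline_prob = 0.1,
                            drug = "D0001", loinc_id = "2823_3",
                            seed = 1L) {
  stopifnot(true_or > 0, p_exposed > 0, p_exposed < 1,
            baseline_prob > 0, baseline_prob < 1)
  odds <- true_or * baseline_prob / (1 - baseline_prob)
  q <- odds / (1 + odds)
  res <- with_stream_seed(seed, "cohort", {
    exposed <- rbinom(n_subjects, 1, p_exposed) == 1
    p <- ifelse(exposed, q, baseline_prob)
    abnormal <- rbinom(n_subjects, 1, p) == 1
    list(exposed = exposed, abnormal = abnormal)
  })
  ids <- sprintf("S%05d", seq_len(n_subjects))
  exposures <- tibble::tibble(subject_id = ids[res$exposed], drug = drug,
                              start_day = 0)
  labs <- tibble::tibble(
    subject_id = ids, loinc_id = loinc_id, day = 5,
    value = ifelse(res$abnormal, 2.8, 4.5),
    ref_low = 3.5, ref_high = 5.5)
  gt <- list(true_or = true_or, q_exposed = q,
             baseline_prob = baseline_prob,
             expected_a = n_subjects * p_exposed * q,
             expected_b = n_subjects * p_exposed * (1 - q),
             expected_c = n_subjects * (1 - p_exposed) * baseline_prob,
             expected_d = n_subjects * (1 - p_exposed) * (1 - baseline_prob))
  list(exposures = exposures, labs = labs, ground_truth = gt)
}
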