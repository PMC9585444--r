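#' Consolidated four-part report for one drug-ADR pair
#'
#' Assembles the full evidence record for a pair: part 1, all
#' cross-vocabulary mappings of the ADR (and the drug's ATC codes);
#' part 2, the per-source reference labels (0/1/2 encoding, 2 for a
#' source without a vote); part 3, each partner effect estimate; part 4,
#' the pooled random-effects result and the causality assessment.
#'
#' @param dictionary a [pv_dictionary()].
#' @param matrix a [build_reference_matrix()] result, or `NULL`.
#' @param estimates effect-estimate tibble for the pair (may be empty).
#' @param drug drug term (name, ATC code, or id); must resolve.
#' @param adr ADR term (PT, CUI, or synonym); must resolve.
#' @param user_flags passed to [assess_causality()].
#' @return object of class `pair_report` with elements `drug`, `adr`,
#'   `part1` (mappings), `part2` (per-source labels + consensus),
#'   `part3` (estimates tibble), `part4` (`meta_result` +
#'   `causality_assessment`) and a `meta`data block recording the
#'   conventions in force (estimator, SE-from-p rule, z value,
#'   terminology versions).
#' @export
pair_report <- function(dictionary, matrix = NULL, estimates = NULL,
                        drug, adr, user_flags = character()) {
  dc <- resolve_drug(dictionary, drug)
  ac <- resolve_adr(dictionary, adr)
  if (is.null(dc)) abort(paste0("cannot resolve drug: ", drug))
  if (is.null(ac)) abort(paste0("cannot resolve ADR: ", adr))

  if (is.null(estimates) || nrow(estimates) == 0) {
    estimates <- load_partner_results(
      tibble::tibble(partner_id = character(), drug = character(),
                     adr = character(), estimate_type = character(),
                     point = character()))
  }

  part2 <- NULL
  consensus <- "unknown"
  if (!is.null(matrix)) {
    labs <- cell_labels(matrix, dc$drug_id, ac$pt_name)
    part2 <- tibble::tibble(
      source_id = matrix$sources,
      value = ifelse(matrix$sources %in% names(labs),
                     as.character(labs[matrix$sources]), "2"))
    consensus <- consensus_of(matrix, dc$drug_id, ac$pt_name)
  }

  meta <- pool_random_effects(estimates, pair = c(dc$drug_id, ac$pt_name))
  causality <- assess_causality(meta, consensus = consensus,
                                user_flags = user_flags)

  structure(
    list(
      drug = dc, adr = ac,
      part1 = list(
        atc_codes = dc$atc_codes[[1]],
        soc = ac$soc, umls_cui = ac$umls_cui,
        who_art_terms = ac$who_art_terms[[1]],
        narrative_terms = ac$narrative_terms[[1]],
        loinc_mappings = ac$loinc_mappings[[1]],
        icd10_codes = ac$icd10_codes[[1]]),
      part2 = list(labels = part2, consensus = consensus),
      part3 = estimates,
      part4 = list(meta = meta, causality = causality),
      meta = list(estimator = "DerSimonian-Laird",
                  se_from_p = "two-sided Wald inversion; '<x' bounds at x",
                  z95 = Z95,
                  versions = dictionary$versions)),
    class = "pair_report")
}

#' @export
print.pair_report <- function(x, ...) {
  cat("== Pair report: ", x$drug$name, " / ", x$adr$pt_name, " ==\n",
      sep = "")
  cat("Drug\n  ATC: ", paste(x$part1$atc_codes, collapse = " | "), "\n",
      sep = "")
  cat("ADR\n  MedDRA PT: ", x$adr$pt_name, "\n  SOC: ", x$part1$soc,
      "\n  UMLS CUI: ", x$part1$umls_cui, "\n", sep = "")
  cat("Part 1: vocabulary mappings\n")
  cat("  WHO-ART: ", paste(x$part1$who_art_terms, collapse = " | "), "\n",
      sep = "")
  lm <- x$part1$loinc_mappings
  if (!is.null(lm) && nrow(lm)) {
    for (i in seq_len(nrow(lm))) {
      cat("  LOINC: ", lm$loinc_id[i], " (", lm$common_name[i],
          ", direction=", lm$direction[i], ")\n", sep = "")
    }
  }
  cat("  ICD-10: ", paste(x$part1$icd10_codes, collapse = " | "), "\n",
      sep = "")
  cat("Part 2: reference sources (0=negative, 1=positive, 2=unknown)\n")
  if (!is.null(x$part2$labels)) {
    for (i in seq_len(nrow(x$part2$labels))) {
      cat("  ", x$part2$labels$source_id[i], ": ",
          x$part2$labels$value[i], "\n", sep = "")
    }
  }
  cat("  consensus: ", x$part2$consensus, "\n", sep = "")
  cat("Part 3: data partner estimates\n")
  if (nrow(x$part3)) {
    for (i in seq_len(nrow(x$part3))) {
      r <- x$part3[i, ]
      p_str <- if (is.na(r$p_value)) "" else if (isTRUE(r$p_is_bound)) {
        paste0(", p<", sub("^0", "", fmt_num(r$p_value, 3)))
      } else {
        paste0(", p=", sub("^0", "", fmt_num(r$p_value, 3)))
      }
      cat("  ", r$partner_id, ": ", r$estimate_type, " ",
          fmt_num(r$point), p_str, "\n", sep = "")
    }
  } else {
    cat("  (none)\n")
  }
  cat("Part 4: meta-analysis and causality\n")
  m <- x$part4$meta
  if (m$k > 0) {
    cat("  pooled ", fmt_num(m$pooled_point), " (", fmt_num(m$ci_low),
        "-", fmt_num(m$ci_high), "), k=", m$k, "\n", sep = "")
  } else {
    cat("  no estimates to pool\n")
  }
  cat("  causality: ", x$part4$causality$category, "\n", sep = "")
  invisible(x)
}

## Serialize a pair report to plain lists ready for JSON. Numbers are
## kept at 6 significant digits in the export.
pair_report_list <- function(report) {
  sig <- function(x) if (is.numeric(x)) signif(x, 6) else x
  est_df <- function(df) {
    df <- as.data.frame(df)
    df[] <- lapply(df, sig)
    df
  }
  m <- report$part4$meta
  list(
    drug = list(drug_id = report$drug$drug_id, name = report$drug$name,
                atc_codes = as.list(report$drug$atc_codes[[1]])),
    adr = list(pt_name = report$adr$pt_name,
               umls_cui = report$adr$umls_cui, soc = report$adr$soc),
    part1 = list(
      who_art_terms = as.list(report$part1$who_art_terms),
      narrative_terms = est_df(report$part1$narrative_terms),
      loinc_mappings = est_df(report$part1$loinc_mappings),
      icd10_codes = as.list(report$part1$icd10_codes)),
    part2 = list(
      labels = if (is.null(report$part2$labels)) NULL
               else est_df(report$part2$labels),
      consensus = report$part2$consensus),
    part3 = est_df(report$part3),
    part4 = list(
      k = m$k, pooled_point = sig(m$pooled_point),
      ci_low = sig(m$ci_low), ci_high = sig(m$ci_high),
      tau2 = sig(m$tau2), q_stat = sig(m$q_stat), i2 = sig(m$i2),
      warnings = as.list(m$warnings),
      causality = report$part4$causality$category,
      evidence_flags = as.list(report$part4$causality$evidence_flags),
      rubric_trace = as.list(report$part4$causality$rubric_trace)),
    metadata = list(estimator = report$meta$estimator,
                    se_from_p = report$meta$se_from_p,
                    z95 = report$meta$z95,
                    versions = report$meta$versions))
}

#' Write a pair report to JSON
#'
#' Four top-level blocks (`part1`..`part4`) plus drug/ADR identity and a
#' metadata block echoing the conventions in force; numbers at 6
#' significant digits.
#'
#' @param report a [pair_report()].
#' @param path output file; `NULL` returns the JSON string.
#' @return the path (invisibly) or the JSON string.
#' @export
write_pair_report <- function(report, path = NULL) {
  stopifnot(inherits(report, "pair_report"))
  x <- pair_report_list(report)
  if (is.null(path)) {
    return(jsonlite::toJSON(x, auto_unbox = TRUE, null = "null",
                            digits = NA, pretty = TRUE))
  }
  jsonlite::write_json(x, path, auto_unbox = TRUE, null = "null",
                       digits = NA, pretty = TRUE)
  invisible(path)
}

#' Read a pair report JSON back into a list
#'
#' Returns the parsed JSON structure (not a reconstructed `pair_report`
#' object); writing a report, reading it, and re-serializing is
#' value-identical.
#'
#' @param path JSON file written by [write_pair_report()].
#' @return nested list mirroring the JSON blocks.
#' @export
read_pair_report <- function(path) {
  jsonlite::read_json(path, simplifyVector = FALSE)
}
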