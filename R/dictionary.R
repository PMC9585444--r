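#' Build a pharmacovigilance vocabulary dictionary
#'
#' Assembles the controlled-vocabulary dictionary that anchors every ADR
#' concept on a MedDRA preferred term (PT) and every drug on its ATC
#' code(s). Three mapping channels attach to a PT: clinical-narrative
#' terms (WHO-ART coded nursing/narrative statements), laboratory tests
#' (LOINC, each carrying the direction of abnormality that constitutes
#' the event), and disease-classification codes (ICD-10). A synonym
#' index (PT names, UMLS CUIs, and explicit synonyms) supports
#' case-insensitive resolution of free terms onto PTs.
#'
#' All inputs are plain data frames; [read_pv_dictionary()] builds the
#' same object from the TSV file layout.
#'
#' @param drugs data frame with columns `drug_id`, `name`, `atc_codes`
#'   (pipe-separated string, e.g. `"J02AC01"`).
#' @param adrs data frame with columns `pt_name`, `umls_cui`, `soc`.
#' @param narrative optional data frame: `pt_name`, `site_id`,
#'   `statement`, `who_art_term`.
#' @param loinc optional data frame: `pt_name`, `loinc_id`,
#'   `common_name`, `direction` (one of `"high"`, `"low"`, `"any"`),
#'   `site_id`, `local_code`, `local_name`.
#' @param icd optional data frame: `pt_name`, `icd10_code`, `icd10_name`.
#' @param synonyms optional data frame: `synonym`, `pt_name`.
#' @param versions named list of terminology version strings, recorded in
#'   output metadata and never validated against live terminologies.
#' @param quiet suppress the channel-count message.
#'
#' @return An object of class `pv_dictionary`: a list of normalized
#'   tibbles (`drugs`, `adrs`, `narrative`, `loinc`, `icd`), the synonym
#'   and drug lookup indexes, per-channel mapping counts (`channels`),
#'   and the `versions` metadata.
#'
#' Load-time validation fails on duplicate PT names or CUIs, ambiguous
#' synonyms (one term pointing at two PTs), malformed ATC/CUI/ICD-10
#' codes, bad LOINC directions, and mapping rows referencing unknown
#' PTs; error messages name the offending rows.
#'
#' @export
#' @examples
#' d <- pv_dictionary(
#'   drugs = data.frame(drug_id = "D1", name = "Fluconazole",
#'                      atc_codes = "J02AC01"),
#'   adrs  = data.frame(pt_name = "Hypokalemia", umls_cui = "C0020621",
#'                      soc = "Metabolism and nutrition disorders")
#' )
#' resolve_adr(d, "hypokalemia")$pt_name
pv_dictionary <- function(drugs, adrs, narrative = NULL, loinc = NULL,
                          icd = NULL, synonyms = NULL,
                          versions = list(), quiet = FALSE) {
  drugs <- tibble::as_tibble(drugs)
  adrs <- tibble::as_tibble(adrs)
  need <- function(df, cols, what) {
    miss <- setdiff(cols, names(df))
    if (length(miss)) {
      abort(paste0(what, " table is missing column(s): ",
                   paste(miss, collapse = ", ")))
    }
  }
  need(drugs, c("drug_id", "name", "atc_codes"), "drugs")
  need(adrs, c("pt_name", "umls_cui", "soc"), "adrs")

  if (anyDuplicated(drugs$drug_id)) {
    dup <- unique(drugs$drug_id[duplicated(drugs$drug_id)])
    abort(paste0("duplicate drug_id in drugs table: ",
                 paste(dup, collapse = ", ")))
  }
  if (anyDuplicated(adrs$pt_name)) {
    dup <- unique(adrs$pt_name[duplicated(adrs$pt_name)])
    abort(paste0("duplicate pt_name in adrs table: ",
                 paste(dup, collapse = ", ")))
  }
  cui <- adrs$umls_cui[nzchar(adrs$umls_cui)]
  if (anyDuplicated(cui)) {
    dup <- unique(cui[duplicated(cui)])
    abort(paste0("duplicate umls_cui in adrs table: ",
                 paste(dup, collapse = ", ")))
  }
  bad_cui <- which(nzchar(adrs$umls_cui) & !is_valid_cui(adrs$umls_cui))
  if (length(bad_cui)) {
    abort(paste0("malformed UMLS CUI in adrs row(s) ",
                 paste(bad_cui, collapse = ", "), ": ",
                 paste(adrs$umls_cui[bad_cui], collapse = ", ")))
  }

  drugs$atc_codes <- if (is.list(drugs$atc_codes)) {
    drugs$atc_codes
  } else {
    split_pipes(as.character(drugs$atc_codes))
  }
  atc_flat <- unlist(drugs$atc_codes)
  bad_atc <- atc_flat[!is_valid_atc(atc_flat)]
  if (length(bad_atc)) {
    rows <- which(vapply(drugs$atc_codes,
                         function(v) any(!is_valid_atc(v)) && length(v) > 0,
                         logical(1)))
    abort(paste0("malformed ATC code(s) in drugs row(s) ",
                 paste(rows, collapse = ", "), ": ",
                 paste(unique(bad_atc), collapse = ", ")))
  }

  empty_or <- function(df, cols) {
    if (is.null(df)) {
      return(tibble::as_tibble(setNames(
        rep(list(character()), length(cols)), cols)))
    }
    df <- tibble::as_tibble(df)
    need(df, cols, paste(cols[2], "mapping"))
    df
  }
  narrative <- empty_or(narrative, c("pt_name", "site_id", "statement",
                                     "who_art_term"))
  loinc <- empty_or(loinc, c("pt_name", "loinc_id", "common_name",
                             "direction", "site_id", "local_code",
                             "local_name"))
  icd <- empty_or(icd, c("pt_name", "icd10_code", "icd10_name"))
  synonyms <- empty_or(synonyms, c("synonym", "pt_name"))

  bad_dir <- which(!loinc$direction %in% c("high", "low", "any"))
  if (length(bad_dir)) {
    abort(paste0("invalid LOINC direction in row(s) ",
                 paste(bad_dir, collapse = ", "),
                 " (must be high/low/any): ",
                 paste(unique(loinc$direction[bad_dir]), collapse = ", ")))
  }
  bad_icd <- which(!is_valid_icd10(icd$icd10_code))
  if (length(bad_icd)) {
    abort(paste0("malformed ICD-10 code in row(s) ",
                 paste(bad_icd, collapse = ", "), ": ",
                 paste(icd$icd10_code[bad_icd], collapse = ", ")))
  }
  for (nm in c("narrative", "loinc", "icd", "synonyms")) {
    df <- get(nm)
    unknown <- setdiff(unique(df$pt_name), adrs$pt_name)
    if (length(unknown)) {
      abort(paste0(nm, " mapping references unknown pt_name(s): ",
                   paste(unknown, collapse = ", ")))
    }
  }

  ## Synonym index: every PT resolves to itself; CUIs and explicit
  ## synonyms are additional keys. One key -> two PTs is a load error.
  idx <- dplyr::bind_rows(
    tibble::tibble(key = normalize_term(adrs$pt_name), pt_name = adrs$pt_name),
    tibble::tibble(key = normalize_term(adrs$umls_cui[nzchar(adrs$umls_cui)]),
                   pt_name = adrs$pt_name[nzchar(adrs$umls_cui)]),
    tibble::tibble(key = normalize_term(synonyms$synonym),
                   pt_name = synonyms$pt_name)
  )
  idx <- dplyr::distinct(idx)
  amb <- idx |>
    dplyr::count(.data$key) |>
    dplyr::filter(.data$n > 1)
  if (nrow(amb)) {
    abort(paste0("ambiguous synonym(s) mapping to multiple PTs: ",
                 paste(amb$key, collapse = ", ")))
  }

  drug_idx <- dplyr::bind_rows(
    tibble::tibble(key = normalize_term(drugs$drug_id),
                   drug_id = drugs$drug_id),
    tibble::tibble(key = normalize_term(drugs$name), drug_id = drugs$drug_id),
    tibble::tibble(key = normalize_term(unlist(drugs$atc_codes)),
                   drug_id = rep(drugs$drug_id,
                                 lengths(drugs$atc_codes)))
  ) |> dplyr::distinct()
  amb_d <- drug_idx |>
    dplyr::count(.data$key) |>
    dplyr::filter(.data$n > 1)
  if (nrow(amb_d)) {
    abort(paste0("ambiguous drug name/ATC key(s): ",
                 paste(amb_d$key, collapse = ", ")))
  }

  ## Channel accounting: a PT counts toward a channel if it has >= 1
  ## mapping there; channels overlap, so counts need not partition the
  ## PT universe. "not mapped" = absent from all three channels.
  mapped <- list(narrative = unique(narrative$pt_name),
                 laboratory = unique(loinc$pt_name),
                 disease_classification = unique(icd$pt_name))
  any_mapped <- unique(unlist(mapped))
  channels <- tibble::tibble(
    channel = c("narrative", "laboratory", "disease_classification",
                "not_mapped"),
    n_pt = unname(c(lengths(mapped),
                    sum(!adrs$pt_name %in% any_mapped)))
  )

  out <- structure(
    list(drugs = drugs, adrs = adrs, narrative = narrative, loinc = loinc,
         icd = icd, synonyms = synonyms, synonym_index = idx,
         drug_index = drug_idx, channels = channels,
         versions = versions),
    class = "pv_dictionary"
  )
  if (!quiet) {
    inform(paste0("pv_dictionary: ", nrow(drugs), " drugs, ", nrow(adrs),
                  " ADR PTs (mapped: ",
                  paste(channels$channel, channels$n_pt, sep = "=",
                        collapse = ", "), ")"))
  }
  out
}

#' @export
print.pv_dictionary <- function(x, ...) {
  cat("<pv_dictionary>\n")
  cat("  drugs:", nrow(x$drugs), " ADR PTs:", nrow(x$adrs), "\n")
  ch <- setNames(x$channels$n_pt, x$channels$channel)
  cat("  channels: narrative=", ch[["narrative"]],
      " laboratory=", ch[["laboratory"]],
      " disease=", ch[["disease_classification"]],
      " not-mapped=", ch[["not_mapped"]], "\n", sep = "")
  if (length(x$versions)) {
    cat("  versions:", paste(names(x$versions), unlist(x$versions),
                             sep = "=", collapse = ", "), "\n")
  }
  invisible(x)
}

#' Per-channel mapping counts of a dictionary
#'
#' One row per channel (narrative / laboratory / disease_classification /
#' not_mapped) with the number of preferred terms carrying at least one
#' mapping in that channel. Channels overlap: a PT mapped in two channels
#' counts in both, so the column need not sum to the PT total.
#'
#' @param dictionary a [pv_dictionary()].
#' @return tibble with columns `channel`, `n_pt`.
#' @export
channel_counts <- function(dictionary) {
  stopifnot(inherits(dictionary, "pv_dictionary"))
  dictionary$channels
}

#' Resolve a term to an ADR concept
#'
#' Looks up a free term — a MedDRA PT name, a UMLS CUI, or a registered
#' synonym — case-insensitively and whitespace-normalized, and returns
#' the matching concept with all its cross-vocabulary mappings.
#' Ambiguity is impossible because it is rejected at dictionary load.
#'
#' @param dictionary a [pv_dictionary()].
#' @param term character scalar to resolve.
#' @return A one-row tibble with columns `pt_name`, `umls_cui`, `soc`,
#'   and list-columns `who_art_terms`, `narrative_terms`,
#'   `loinc_mappings`, `icd10_codes`; or `NULL` when the term is unknown
#'   (not-found is a value, not an error).
#' @export
resolve_adr <- function(dictionary, term) {
  stopifnot(inherits(dictionary, "pv_dictionary"), length(term) == 1)
  key <- normalize_term(term)
  hit <- dictionary$synonym_index$pt_name[dictionary$synonym_index$key == key]
  if (length(hit) == 0) return(NULL)
  adr_concept(dictionary, hit[[1]])
}

## Materialize the full concept record for a known PT.
adr_concept <- function(dictionary, pt) {
  row <- dictionary$adrs[dictionary$adrs$pt_name == pt, ]
  narr <- dictionary$narrative[dictionary$narrative$pt_name == pt, ]
  lab <- dictionary$loinc[dictionary$loinc$pt_name == pt, ]
  icd <- dictionary$icd[dictionary$icd$pt_name == pt, ]
  tibble::tibble(
    pt_name = row$pt_name,
    umls_cui = row$umls_cui,
    soc = row$soc,
    who_art_terms = list(unique(narr$who_art_term[nzchar(narr$who_art_term)])),
    narrative_terms = list(narr[c("site_id", "statement")]),
    loinc_mappings = list(lab[c("loinc_id", "common_name", "direction",
                                "site_id", "local_code", "local_name")]),
    icd10_codes = list(unique(icd$icd10_code))
  )
}

#' Resolve a term to a drug concept
#'
#' Matches by drug name (case-insensitive), ATC code, or drug id.
#'
#' @inheritParams resolve_adr
#' @return A one-row tibble (`drug_id`, `name`, list-column `atc_codes`)
#'   or `NULL` when unknown.
#' @export
resolve_drug <- function(dictionary, term) {
  stopifnot(inherits(dictionary, "pv_dictionary"), length(term) == 1)
  key <- normalize_term(term)
  hit <- dictionary$drug_index$drug_id[dictionary$drug_index$key == key]
  if (length(hit) == 0) return(NULL)
  dictionary$drugs[dictionary$drugs$drug_id == hit[[1]], ]
}

#' Read a dictionary from its TSV file layout
#'
#' Expects `drugs.tsv`, `adrs.tsv` and the optional mapping tables
#' `adr_narrative.tsv`, `adr_loinc.tsv`, `adr_icd.tsv`,
#' `adr_synonyms.tsv` in `dir` (UTF-8, tab-separated, header row).
#'
#' @param dir directory containing the TSV files.
#' @inheritParams pv_dictionary
#' @return a [pv_dictionary()].
#' @export
read_pv_dictionary <- function(dir, versions = list(), quiet = FALSE) {
  pth <- function(f) file.path(dir, f)
  opt <- function(f) if (file.exists(pth(f))) read_tsv_strict(pth(f)) else NULL
  for (f in c("drugs.tsv", "adrs.tsv")) {
    if (!file.exists(pth(f))) abort(paste0("missing dictionary file: ", pth(f)))
  }
  pv_dictionary(
    drugs = read_tsv_strict(pth("drugs.tsv")),
    adrs = read_tsv_strict(pth("adrs.tsv")),
    narrative = opt("adr_narrative.tsv"),
    loinc = opt("adr_loinc.tsv"),
    icd = opt("adr_icd.tsv"),
    synonyms = opt("adr_synonyms.tsv"),
    versions = versions, quiet = quiet
  )
}

#' Write a dictionary back to its TSV file layout
#'
#' Inverse of [read_pv_dictionary()]; reloading the written directory
#' reproduces the dictionary field-for-field.
#'
#' @param dictionary a [pv_dictionary()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_pv_dictionary <- function(dictionary, dir) {
  stopifnot(inherits(dictionary, "pv_dictionary"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  drugs_out <- dictionary$drugs
  drugs_out$atc_codes <- join_pipes(drugs_out$atc_codes)
  write_tsv_plain(drugs_out, file.path(dir, "drugs.tsv"))
  write_tsv_plain(dictionary$adrs, file.path(dir, "adrs.tsv"))
  write_tsv_plain(dictionary$narrative, file.path(dir, "adr_narrative.tsv"))
  write_tsv_plain(dictionary$loinc, file.path(dir, "adr_loinc.tsv"))
  write_tsv_plain(dictionary$icd, file.path(dir, "adr_icd.tsv"))
  write_tsv_plain(dictionary$synonyms, file.path(dir, "adr_synonyms.tsv"))
  invisible(dir)
}
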