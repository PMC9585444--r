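#' Ingest a positive/negative reference source
#'
#' Reads one reference source (a SIDER-, OMOP- or EU-ADR-like table of
#' drug-ADR pairs labeled positive or negative) and harmonizes it
#' through the vocabulary dictionary: drugs are resolved by name or ATC
#' code, ADRs by PT name, CUI or synonym. Rows that fail resolution are
#' retained in `unresolved` with a reason rather than dropped silently.
#'
#' @param data data frame with columns `drug`, `adr`, `label`
#'   (`"positive"`/`"negative"`, case-insensitive) and optionally
#'   `evidence` (pipe-separated evidence kinds); or a path to a TSV file
#'   with those columns.
#' @param source_id short identifier for the source (e.g. `"SIDER"`).
#' @param dictionary a [pv_dictionary()].
#' @param evidence_kinds character vector describing the evidence behind
#'   the source (e.g. `"FDA product label"`); defaults to the union of
#'   the `evidence` column if present.
#'
#' @return An object of class `ref_source`: `source_id`,
#'   `evidence_kinds`, `pairs` (tibble `drug_id`, `pt_name`, `label`)
#'   and `unresolved` (tibble of raw rows with a `reason`).
#'   A pair appearing twice with different labels within the source is a
#'   load error naming the pair; an unrecognized label string is an
#'   error naming the row.
#' @export
ingest_source <- function(data, source_id, dictionary,
                          evidence_kinds = NULL) {
  stopifnot(inherits(dictionary, "pv_dictionary"))
  if (is.character(data) && length(data) == 1) {
    data <- read_tsv_strict(data)
  }
  data <- tibble::as_tibble(data)
  miss <- setdiff(c("drug", "adr", "label"), names(data))
  if (length(miss)) {
    abort(paste0("reference source is missing column(s): ",
                 paste(miss, collapse = ", ")))
  }
  if (is.null(evidence_kinds)) {
    evidence_kinds <- if ("evidence" %in% names(data)) {
      sort(unique(unlist(split_pipes(data$evidence))))
    } else {
      character()
    }
  }
  if (nrow(data) == 0) {
    return(structure(
      list(source_id = source_id, evidence_kinds = evidence_kinds,
           pairs = tibble::tibble(drug_id = character(),
                                  pt_name = character(),
                                  label = character()),
           unresolved = tibble::tibble(row = integer(), drug = character(),
                                       adr = character(),
                                       reason = character())),
      class = "ref_source"))
  }

  lab <- normalize_term(data$label)
  bad <- which(!lab %in% c("positive", "negative"))
  if (length(bad)) {
    abort(paste0("unknown label string in row(s) ",
                 paste(head(bad, 5), collapse = ", "), " of source ",
                 source_id, ": ",
                 paste(unique(data$label[bad]), collapse = ", ")))
  }

  ## Vectorized resolution through the dictionary indexes (joins, not
  ## per-row lookups: SIDER-scale sources have >100k rows).
  res <- tibble::tibble(
    row = seq_len(nrow(data)),
    drug = as.character(data$drug), adr = as.character(data$adr),
    label = lab,
    drug_key = normalize_term(as.character(data$drug)),
    adr_key = normalize_term(as.character(data$adr))
  ) |>
    dplyr::left_join(dplyr::rename(dictionary$drug_index,
                                   drug_key = "key"),
                     by = "drug_key") |>
    dplyr::left_join(dplyr::rename(dictionary$synonym_index,
                                   adr_key = "key"),
                     by = "adr_key")

  unresolved <- res |>
    dplyr::filter(is.na(.data$drug_id) | is.na(.data$pt_name)) |>
    dplyr::mutate(reason = dplyr::case_when(
      is.na(.data$drug_id) & is.na(.data$pt_name) ~ "unknown drug and ADR",
      is.na(.data$drug_id) ~ "unknown drug",
      TRUE ~ "unknown ADR"
    )) |>
    dplyr::select("row", "drug", "adr", "reason")

  pairs <- res |>
    dplyr::filter(!is.na(.data$drug_id), !is.na(.data$pt_name)) |>
    dplyr::distinct(.data$drug_id, .data$pt_name, .data$label)

  conflict <- pairs |>
    dplyr::count(.data$drug_id, .data$pt_name) |>
    dplyr::filter(.data$n > 1)
  if (nrow(conflict)) {
    abort(paste0("source ", source_id,
                 " labels the same pair both positive and negative: ",
                 paste(paste0(conflict$drug_id, "/", conflict$pt_name),
                       collapse = "; ")))
  }

  structure(
    list(source_id = source_id, evidence_kinds = evidence_kinds,
         pairs = pairs, unresolved = unresolved),
    class = "ref_source")
}

#' @export
print.ref_source <- function(x, ...) {
  np <- sum(x$pairs$label == "positive")
  nn <- sum(x$pairs$label == "negative")
  cat("<ref_source ", x$source_id, "> ", np, " positive, ", nn,
      " negative, ", nrow(x$unresolved), " unresolved\n", sep = "")
  invisible(x)
}

#' Combine per-source votes into one consensus label
#'
#' The consensus vote turns the per-source 0/1 labels of one matrix cell
#' into a single value. The default policy flags disagreement instead of
#' resolving it: unanimity keeps the label, an empty vote set is
#' unknown, and mixed votes become `"conflicting"` so they can be
#' reviewed rather than silently overruled. Alternative precedence and
#' majority policies are available for pipelines that need a hard 0/1.
#'
#' @param labels named integer vector of per-source labels, each 0
#'   (negative) or 1 (positive); names are source ids. May be empty.
#' @param policy one of `"flag"` (default), `"negative-precedence"`,
#'   `"positive-precedence"`, `"majority"` (ties conflict).
#' @return character scalar: `"positive"`, `"negative"`, `"unknown"`, or
#'   `"conflicting"`. See [consensus_code()] for the 0/1/2/C file
#'   encoding.
#' @export
#' @examples
#' consensus_label(c(SIDER = 1L, OMOP = 1L))
#' consensus_label(c(SIDER = 1L, OMOP = 0L))
#' consensus_label(c(SIDER = 1L, OMOP = 0L), policy = "negative-precedence")
consensus_label <- function(labels, policy = c("flag", "negative-precedence",
                                               "positive-precedence",
                                               "majority")) {
  policy <- match.arg(policy)
  stopifnot(all(labels %in% c(0L, 1L)))
  consensus_from_counts(sum(labels == 1L), sum(labels == 0L), policy)
}

## Vectorized consensus over (n positive votes, n negative votes).
consensus_from_counts <- function(n_pos, n_neg, policy) {
  total <- n_pos + n_neg
  switch(policy,
    "flag" = dplyr::case_when(
      total == 0 ~ "unknown",
      n_pos > 0 & n_neg > 0 ~ "conflicting",
      n_pos > 0 ~ "positive",
      TRUE ~ "negative"),
    "negative-precedence" = dplyr::case_when(
      total == 0 ~ "unknown",
      n_neg > 0 ~ "negative",
      TRUE ~ "positive"),
    "positive-precedence" = dplyr::case_when(
      total == 0 ~ "unknown",
      n_pos > 0 ~ "positive",
      TRUE ~ "negative"),
    "majority" = dplyr::case_when(
      total == 0 ~ "unknown",
      n_pos > n_neg ~ "positive",
      n_neg > n_pos ~ "negative",
      TRUE ~ "conflicting")
  )
}

#' Encode consensus labels for file export
#'
#' Maps `"negative"`/`"positive"`/`"unknown"`/`"conflicting"` to the
#' matrix cell encoding `"0"`/`"1"`/`"2"`/`"C"`.
#'
#' @param label character vector of consensus labels.
#' @return character vector of codes.
#' @export
consensus_code <- function(label) {
  unname(c(negative = "0", positive = "1", unknown = "2",
           conflicting = "C")[label])
}

#' Assemble the sparse drugs-by-ADRs reference matrix
#'
#' Places every ingested source's labeled pairs on a common drug x ADR
#' grid and computes a consensus label per cell. Storage is sparse by
#' exception: only cells carrying at least one vote are materialized;
#' an absent cell means unknown (2) in every source, and total cell
#' counts come from the index sizes, never from enumeration — a
#' 1344 x 4485 grid has 6,027,840 conceptual cells of which typically
#' fewer than 3% carry a label.
#'
#' @param drugs character vector of drug ids forming the row index.
#' @param adrs character vector of PT names forming the column index.
#' @param sources list of [ingest_source()] results.
#' @param policy consensus policy, see [consensus_label()].
#' @return An object of class `ref_matrix`: the two ordered indexes,
#'   sparse `cells` (tibble `drug_id`, `pt_name`, `source_id`, `value`
#'   0/1), sparse `consensus` (tibble `drug_id`, `pt_name`, `consensus`),
#'   source ids, the policy, and `n_skipped` — the count of source pairs
#'   referencing drugs/ADRs outside the indexes, which are skipped with
#'   a warning rather than erroring.
#' @export
build_reference_matrix <- function(drugs, adrs, sources = list(),
                                   policy = "flag") {
  if (anyDuplicated(drugs)) abort("duplicate drug_ids in drug index")
  if (anyDuplicated(adrs)) abort("duplicate pt_names in ADR index")
  if (inherits(sources, "ref_source")) sources <- list(sources)
  stopifnot(all(vapply(sources, inherits, logical(1), "ref_source")))

  cells <- purrr::map_dfr(sources, function(s) {
    dplyr::mutate(s$pairs, source_id = s$source_id,
                  value = as.integer(.data$label == "positive")) |>
      dplyr::select("drug_id", "pt_name", "source_id", "value")
  })
  if (nrow(cells) == 0) {
    cells <- tibble::tibble(drug_id = character(), pt_name = character(),
                            source_id = character(), value = integer())
  }
  in_index <- cells$drug_id %in% drugs & cells$pt_name %in% adrs
  n_skipped <- sum(!in_index)
  if (n_skipped > 0) {
    warn(paste0(n_skipped,
                " source pair(s) reference drugs/ADRs outside the matrix",
                " index and were skipped"))
    cells <- cells[in_index, ]
  }

  consensus <- cells |>
    dplyr::summarise(n_pos = sum(.data$value == 1L),
                     n_neg = sum(.data$value == 0L),
                     .by = c("drug_id", "pt_name")) |>
    dplyr::mutate(consensus = consensus_from_counts(.data$n_pos, .data$n_neg,
                                                    policy)) |>
    dplyr::select("drug_id", "pt_name", "consensus")

  structure(
    list(drug_index = as.character(drugs), adr_index = as.character(adrs),
         cells = cells, consensus = consensus,
         sources = vapply(sources, `[[`, character(1), "source_id"),
         policy = policy, n_skipped = n_skipped),
    class = "ref_matrix")
}

#' @export
print.ref_matrix <- function(x, ...) {
  total <- n_cells(x)
  cat("<ref_matrix> ", length(x$drug_index), " drugs x ",
      length(x$adr_index), " ADRs = ", format(total, big.mark = ","),
      " pairs\n", sep = "")
  cat("  sources:", paste(x$sources, collapse = ", "), "\n")
  cat("  labeled cells:", nrow(x$cells), " consensus policy:", x$policy, "\n")
  invisible(x)
}

#' Total conceptual cell count of a reference matrix
#'
#' `|drugs| x |ADRs|`, computed from the index sizes (the matrix itself
#' stores only labeled cells). Returned as double to stay exact past the
#' 32-bit integer range.
#'
#' @param matrix a [build_reference_matrix()] result.
#' @return numeric scalar.
#' @export
n_cells <- function(matrix) {
  stopifnot(inherits(matrix, "ref_matrix"))
  as.numeric(length(matrix$drug_index)) * length(matrix$adr_index)
}

#' Consensus label of one cell
#'
#' @param matrix a `ref_matrix`.
#' @param drug_id,pt_name cell coordinates (must lie in the indexes).
#' @return character consensus label; `"unknown"` for any cell that
#'   carries no vote.
#' @export
consensus_of <- function(matrix, drug_id, pt_name) {
  stopifnot(inherits(matrix, "ref_matrix"))
  if (!drug_id %in% matrix$drug_index || !pt_name %in% matrix$adr_index) {
    abort(paste0("pair ", drug_id, "/", pt_name, " outside the matrix index"))
  }
  hit <- matrix$consensus$consensus[
    matrix$consensus$drug_id == drug_id & matrix$consensus$pt_name == pt_name]
  if (length(hit) == 0) "unknown" else hit[[1]]
}

#' Per-source labels of one cell
#'
#' @inheritParams consensus_of
#' @return named integer vector (source id -> 0/1); sources without a
#'   vote for the cell are absent (i.e. unknown, 2).
#' @export
cell_labels <- function(matrix, drug_id, pt_name) {
  stopifnot(inherits(matrix, "ref_matrix"))
  sub <- matrix$cells[matrix$cells$drug_id == drug_id &
                        matrix$cells$pt_name == pt_name, ]
  setNames(sub$value, sub$source_id)
}

#' Coverage accounting for one source (or all sources)
#'
#' For each source, counts its positive and negative labels on the
#' matrix and derives the unknowns and the covered fraction of the full
#' grid. The accounting identity `positives + negatives + unknowns =
#' |drugs| x |ADRs|` holds by construction. Covered fraction is
#' half-up rounded: one decimal below 50%, whole percent at or above
#' (so 2.3%, 13.8%, 53%).
#'
#' @param matrix a `ref_matrix`.
#' @param source_id one source id, or `NULL` for a row per source.
#' @return tibble with columns `source_id`, `n_positive`, `n_negative`,
#'   `n_unknown`, `covered_fraction`.
#' @export
coverage_stats <- function(matrix, source_id = NULL) {
  stopifnot(inherits(matrix, "ref_matrix"))
  ids <- source_id %||% matrix$sources
  unknown_src <- setdiff(ids, matrix$sources)
  if (length(unknown_src)) {
    abort(paste0("unknown source_id: ", paste(unknown_src, collapse = ", ")))
  }
  total <- n_cells(matrix)
  purrr::map_dfr(ids, function(id) {
    sub <- matrix$cells[matrix$cells$source_id == id, ]
    n_pos <- sum(sub$value == 1L)
    n_neg <- sum(sub$value == 0L)
    tibble::tibble(
      source_id = id, n_positive = n_pos, n_negative = n_neg,
      n_unknown = total - n_pos - n_neg,
      covered_fraction = round_coverage(100 * (n_pos + n_neg) / total))
  })
}

#' Write a reference matrix to sparse TSV files
#'
#' Emits `matrix_cells.tsv` (drug_id, pt_name, source_id, value 0/1),
#' `matrix_consensus.tsv` (drug_id, pt_name, consensus 0/1/2/C; only
#' non-unknown cells are written), and `matrix_index.tsv` carrying the
#' ordered drug/ADR indexes so that [read_reference_matrix()]
#' round-trips exactly.
#'
#' @param matrix a `ref_matrix`.
#' @param dir output directory.
#' @return `dir`, invisibly.
#' @export
write_reference_matrix <- function(matrix, dir) {
  stopifnot(inherits(matrix, "ref_matrix"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_tsv_plain(matrix$cells, file.path(dir, "matrix_cells.tsv"))
  cons <- dplyr::mutate(matrix$consensus,
                        consensus = consensus_code(.data$consensus))
  write_tsv_plain(cons, file.path(dir, "matrix_consensus.tsv"))
  idx <- dplyr::bind_rows(
    tibble::tibble(axis = "drug", key = matrix$drug_index),
    tibble::tibble(axis = "adr", key = matrix$adr_index))
  write_tsv_plain(idx, file.path(dir, "matrix_index.tsv"))
  write_tsv_plain(tibble::tibble(source_id = matrix$sources,
                                 policy = matrix$policy),
                  file.path(dir, "matrix_sources.tsv"))
  invisible(dir)
}

#' Read a reference matrix written by [write_reference_matrix()]
#'
#' @param dir directory holding the sparse TSV export.
#' @return a `ref_matrix`.
#' @export
read_reference_matrix <- function(dir) {
  cells <- read_tsv_strict(file.path(dir, "matrix_cells.tsv"))
  cells$value <- as.integer(cells$value)
  cons <- read_tsv_strict(file.path(dir, "matrix_consensus.tsv"))
  code_rev <- c(`0` = "negative", `1` = "positive", `2` = "unknown",
                C = "conflicting")
  cons$consensus <- unname(code_rev[cons$consensus])
  idx <- read_tsv_strict(file.path(dir, "matrix_index.tsv"))
  src <- read_tsv_strict(file.path(dir, "matrix_sources.tsv"))
  structure(
    list(drug_index = idx$key[idx$axis == "drug"],
         adr_index = idx$key[idx$axis == "adr"],
         cells = cells, consensus = cons,
         sources = src$source_id, policy = unique(src$policy)[1] %||% "flag",
         n_skipped = 0L),
    class = "ref_matrix")
}
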