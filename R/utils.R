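## Internal helpers shared across modules.

#' Round half-up to a number of decimal places
#'
#' Base `round()` rounds half to even; coverage percentages follow the
#' half-up convention common in printed tables, so 52.78 -> 53 and
#' 2.25 -> 2.3 at one decimal.
#'
#' @param x numeric vector.
#' @param digits decimal places.
#' @return rounded numeric vector.
#' @keywords internal
round_half_up <- function(x, digits = 0) {
  f <- 10^digits
  sign(x) * floor(abs(x) * f + 0.5) / f
}

# Coverage percent display rule: one decimal below 50%, whole percent
# at or above (2.33 -> 2.3, 13.82 -> 13.8, 52.78 -> 53).
round_coverage <- function(pct) {
  ifelse(pct < 50, round_half_up(pct, 1), round_half_up(pct, 0))
}

#' Normalize a term for dictionary lookup
#'
#' Lower-cases, trims, and collapses internal whitespace, so that
#' "Hypokalemia", "hypokalemia" and " hypokalemia " hit the same index key.
#'
#' @param x character vector.
#' @return normalized character vector.
#' @export
#' @examples
#' normalize_term("  Hepatic   function Abnormal ")
normalize_term <- function(x) {
  stringr::str_squish(stringr::str_to_lower(x))
}

## Code-pattern validators. Patterns are structural only; no live
## terminology is consulted (versions are carried as config strings).
is_valid_atc <- function(x) {
  stringr::str_detect(x, "^[A-Za-z]\\d{2}[A-Za-z]{2}\\d{2}$")
}

is_valid_cui <- function(x) {
  stringr::str_detect(x, "^C\\d+$")
}

is_valid_icd10 <- function(x) {
  stringr::str_detect(x, "^[A-Za-z]\\d{2}(\\.\\d{1,2})?$")
}

## Split a pipe-separated field into a character vector (empty -> chr(0)).
split_pipes <- function(x) {
  out <- stringr::str_split(x, stringr::fixed("|"))
  lapply(out, function(v) {
    v <- stringr::str_trim(v)
    v[nzchar(v)]
  })
}

join_pipes <- function(x) {
  vapply(x, function(v) paste(v, collapse = "|"), character(1))
}

## readr wrapper: all TSV interfaces are UTF-8, tab-separated, header row.
read_tsv_strict <- function(path, col_types = NULL) {
  readr::read_tsv(path, col_types = col_types %||% readr::cols(.default = "c"),
                  progress = FALSE, show_col_types = FALSE,
                  na = character())
}

write_tsv_plain <- function(df, path) {
  readr::write_tsv(df, path, na = "", progress = FALSE)
  invisible(path)
}

## Deterministic child-seed derivation: one stream per generator so adding
## a generator never perturbs existing fixtures. Keeps results < 2^31.
derive_seed <- function(seed, stream) {
  offsets <- c(reports = 101L, partners = 211L, refsources = 307L,
               cohort = 401L, dictionary = 503L)
  if (!stream %in% names(offsets)) {
    abort(paste0("unknown generator stream: ", stream))
  }
  (as.integer(seed) %% 1000000L) * 1009L + offsets[[stream]]
}

fmt_num <- function(x, digits = 2) {
  formatC(x, format = "f", digits = digits)
}
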