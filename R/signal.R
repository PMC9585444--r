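#' Coerce a data frame to a spontaneous-report table
#'
#' A report table has one row per spontaneous report: a unique
#' `report_id`, the set of drugs mentioned, and the set of events
#' (ADR terms) mentioned. Sets may arrive as list-columns or as
#' pipe-separated strings (the `reports.tsv` file dialect).
#'
#' @param data data frame with columns `report_id`, `drugs`, `events`,
#'   or a path to a TSV file with pipe-separated `drugs`/`events`.
#' @return tibble of class `report_table` with list-columns `drugs` and
#'   `events`. Duplicate `report_id`s are an error.
#' @export
as_report_table <- function(data) {
  if (is.character(data) && length(data) == 1) data <- read_tsv_strict(data)
  data <- tibble::as_tibble(data)
  miss <- setdiff(c("report_id", "drugs", "events"), names(data))
  if (length(miss)) {
    abort(paste0("report table is missing column(s): ",
                 paste(miss, collapse = ", ")))
  }
  if (anyDuplicated(data$report_id)) {
    abort("duplicate report_id in report table")
  }
  if (!is.list(data$drugs)) data$drugs <- split_pipes(data$drugs)
  if (!is.list(data$events)) data$events <- split_pipes(data$events)
  class(data) <- c("report_table", class(data))
  data
}

#' Write a report table to TSV (pipe-separated set columns)
#'
#' @param reports a [as_report_table()] table.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_reports <- function(reports, path) {
  out <- tibble::tibble(report_id = reports$report_id,
                        drugs = join_pipes(reports$drugs),
                        events = join_pipes(reports$events))
  write_tsv_plain(out, path)
}

#' Build the 2x2 contingency table for one drug-event pair
#'
#' Cross-classifies every report by mention of the drug and mention of
#' the event: `a` = both, `b` = drug without event, `c` = event without
#' drug, `d` = neither. The analysis unit is one report.
#'
#' @param reports a report table (coerced via [as_report_table()]).
#' @param drug drug key to look for in each report's drug set.
#' @param event event key to look for in each report's event set.
#' @return object of class `contingency_2x2` with integer fields
#'   `a`, `b`, `c`, `d`.
#' @export
#' @examples
#' rt <- as_report_table(tibble::tibble(
#'   report_id = 1:4,
#'   drugs = list("d", "d", character(), character()),
#'   events = list("e", character(), "e", character())))
#' build_contingency(rt, "d", "e")
build_contingency <- function(reports, drug, event) {
  if (!inherits(reports, "report_table")) reports <- as_report_table(reports)
  has_d <- vapply(reports$drugs, function(v) drug %in% v, logical(1))
  has_e <- vapply(reports$events, function(v) event %in% v, logical(1))
  contingency_2x2(sum(has_d & has_e), sum(has_d & !has_e),
                  sum(!has_d & has_e), sum(!has_d & !has_e))
}

#' Construct a 2x2 contingency table from counts
#'
#' @param a,b,c,d non-negative integer cell counts (exposed/event,
#'   exposed/no event, unexposed/event, unexposed/no event).
#' @return object of class `contingency_2x2`.
#' @export
contingency_2x2 <- function(a, b, c, d) {
  cells <- c(a = a, b = b, c = c, d = d)
  if (any(cells < 0) || any(cells != round(cells))) {
    abort("contingency cells must be non-negative integers")
  }
  structure(as.list(cells), class = "contingency_2x2")
}

#' @export
print.contingency_2x2 <- function(x, ...) {
  m <- matrix(c(x$a, x$c, x$b, x$d), 2, 2,
              dimnames = list(c("exposed", "unexposed"),
                              c("event", "no event")))
  cat("<contingency_2x2> n =", x$a + x$b + x$c + x$d, "\n")
  print(m)
  invisible(x)
}

## Internal constructor for a one-row effect-estimate tibble; the shared
## currency between signal computation, partner ingestion and pooling.
new_estimate <- function(partner_id = NA_character_, drug = NA_character_,
                         adr = NA_character_, estimate_type, point,
                         log_se = NA_real_, ci_low = NA_real_,
                         ci_high = NA_real_, p_value = NA_real_,
                         p_is_bound = FALSE, n_units = NA_real_,
                         provenance, se_source = NA_character_) {
  tibble::tibble(
    partner_id = partner_id, drug = drug, adr = adr,
    estimate_type = estimate_type, point = point, log_point = log(point),
    log_se = log_se, ci_low = ci_low, ci_high = ci_high,
    p_value = p_value, p_is_bound = p_is_bound, n_units = n_units,
    provenance = provenance, se_source = se_source)
}

#' (Reporting) odds ratio with log-scale uncertainty from a 2x2 table
#'
#' Computes the odds ratio `ad/bc` with the standard Woolf log-scale
#' standard error `sqrt(1/a + 1/b + 1/c + 1/d)`, a 95% Wald confidence
#' interval, and a two-sided Wald p-value on the log scale. When the
#' table comes from spontaneous reports the statistic is the reporting
#' odds ratio (ROR), the workhorse disproportionality measure.
#'
#' Zero cells make the estimator degenerate. With
#' `correction = TRUE` the Haldane-Anscombe correction (+0.5 to every
#' cell) is applied, and only when some cell is zero — batch scans over
#' a large drug-ADR grid hit empty cells constantly. With correction
#' disabled a zero cell is an explicit error.
#'
#' @param table a [contingency_2x2()].
#' @param correction apply +0.5 continuity correction when a cell is 0.
#' @param estimate_type `"ROR"` (report data) or `"OR"` (subject data).
#' @param drug,adr,partner_id optional identifiers carried on the
#'   estimate row.
#' @return one-row effect-estimate tibble: `point`, `log_point`,
#'   `log_se`, `ci_low`/`ci_high`, `p_value`, provenance `"computed"`.
#' @export
#' @examples
#' odds_ratio(contingency_2x2(20, 5, 10, 40))
odds_ratio <- function(table, correction = FALSE, estimate_type = "ROR",
                       drug = NA_character_, adr = NA_character_,
                       partner_id = NA_character_) {
  stopifnot(inherits(table, "contingency_2x2"))
  cells <- c(table$a, table$b, table$c, table$d)
  n <- sum(cells)
  if (any(cells == 0)) {
    if (!correction) {
      abort(paste0("degenerate 2x2 table (zero cell: ",
                   paste(c("a", "b", "c", "d")[cells == 0], collapse = ","),
                   "); enable the continuity correction or use more data"))
    }
    cells <- cells + 0.5
  }
  point <- (cells[1] * cells[4]) / (cells[2] * cells[3])
  log_se <- sqrt(sum(1 / cells))
  lp <- log(point)
  p <- 2 * pnorm(-abs(lp) / log_se)
  new_estimate(partner_id = partner_id, drug = drug, adr = adr,
               estimate_type = estimate_type, point = point,
               log_se = log_se,
               ci_low = exp(lp - Z95 * log_se),
               ci_high = exp(lp + Z95 * log_se),
               p_value = p, n_units = n, provenance = "computed",
               se_source = "cells")
}

#' Pearson chi-square p-value for a 2x2 table
#'
#' Companion statistic to the Wald p of [odds_ratio()]; reported as an
#' alternative column only, it never drives decisions.
#'
#' @param table a [contingency_2x2()].
#' @param correct Yates continuity correction (passed to
#'   [stats::chisq.test()]).
#' @return numeric p-value.
#' @export
chisq_p <- function(table, correct = FALSE) {
  m <- matrix(c(table$a, table$c, table$b, table$d), 2, 2)
  suppressWarnings(stats::chisq.test(m, correct = correct)$p.value)
}

#' EHR-style laboratory signal for one drug-ADR pair
#'
#' A deliberately simple subject-level signal: subjects are classified
#' exposed (any exposure record for the drug) versus not, and as having
#' a direction-consistent abnormal laboratory event versus not. A lab
#' value is an event only if it is abnormal on the side the ADR's LOINC
#' mapping declares (`low`: below the reference range; `high`: above;
#' `any`: either) — a value above range never counts toward a
#' `direction = "low"` ADR. When a PT maps to several LOINC tests their
#' abnormal events are unioned. For exposed subjects only abnormalities
#' observed after the first exposure day count; the 2x2 then feeds
#' [odds_ratio()].
#'
#' @param exposures data frame `subject_id`, `drug`, `start_day`.
#' @param labs data frame `subject_id`, `loinc_id`, `day`, `value`,
#'   `ref_low`, `ref_high`.
#' @param drug drug key matched against `exposures$drug`.
#' @param adr a one-row ADR concept from [resolve_adr()] (needs at least
#'   one LOINC mapping).
#' @param correction passed to [odds_ratio()].
#' @return list of class `lab_signal`: `computable` (logical), `reason`
#'   (when not computable), `table` (a `contingency_2x2`) and `estimate`
#'   (an odds-ratio row, `estimate_type = "OR"`). An ADR without a LOINC
#'   mapping yields a non-computable value, not an error.
#' @export
ehr_lab_signal <- function(exposures, labs, drug, adr, correction = FALSE) {
  stopifnot(is.data.frame(adr), nrow(adr) == 1)
  maps <- adr$loinc_mappings[[1]]
  if (is.null(maps) || nrow(maps) == 0) {
    return(structure(list(computable = FALSE,
                          reason = paste0("ADR '", adr$pt_name,
                                          "' has no laboratory mapping"),
                          table = NULL, estimate = NULL),
                     class = "lab_signal"))
  }
  exposures <- tibble::as_tibble(exposures)
  labs <- tibble::as_tibble(labs)

  expo <- exposures[exposures$drug == drug, , drop = FALSE]
  expo <- if (nrow(expo) == 0) {
    tibble::tibble(subject_id = character(), start_day = numeric())
  } else {
    dplyr::summarise(expo, start_day = min(.data$start_day),
                     .by = "subject_id")
  }

  dirs <- dplyr::distinct(maps, .data$loinc_id, .data$direction)
  ab <- labs |>
    dplyr::inner_join(dirs, by = "loinc_id") |>
    dplyr::mutate(abnormal = dplyr::case_when(
      .data$direction == "low" ~ .data$value < .data$ref_low,
      .data$direction == "high" ~ .data$value > .data$ref_high,
      TRUE ~ .data$value < .data$ref_low | .data$value > .data$ref_high)) |>
    dplyr::filter(.data$abnormal) |>
    dplyr::left_join(expo, by = "subject_id") |>
    dplyr::filter(is.na(.data$start_day) | .data$day > .data$start_day) |>
    dplyr::distinct(.data$subject_id)

  subjects <- union(exposures$subject_id, labs$subject_id)
  exposed <- subjects %in% expo$subject_id
  event <- subjects %in% ab$subject_id
  tab <- contingency_2x2(sum(exposed & event), sum(exposed & !event),
                         sum(!exposed & event), sum(!exposed & !event))
  est <- tryCatch(
    odds_ratio(tab, correction = correction, estimate_type = "OR",
               drug = drug, adr = adr$pt_name),
    error = function(e) e)
  if (inherits(est, "error")) {
    return(structure(list(computable = FALSE,
                          reason = conditionMessage(est),
                          table = tab, estimate = NULL),
                     class = "lab_signal"))
  }
  structure(list(computable = TRUE, reason = NULL, table = tab,
                 estimate = est),
            class = "lab_signal")
}

#' @export
print.lab_signal <- function(x, ...) {
  if (!x$computable) {
    cat("<lab_signal> not computable:", x$reason, "\n")
  } else {
    cat("<lab_signal> OR ", fmt_num(x$estimate$point), " (",
        fmt_num(x$estimate$ci_low), "-", fmt_num(x$estimate$ci_high),
        "), n = ", x$estimate$n_units, "\n", sep = "")
  }
  invisible(x)
}

## Recover a log-scale SE from whatever uncertainty a partner row
## carries. Printed tables often give only point + p; the two-sided
## Wald inversion |log OR| / z(1 - p/2) is then the only route, and a
## bounded "<.001" is taken at its bound, which yields the largest
## (most conservative) SE consistent with the bound.
recover_log_se <- function(log_point, ci_low, ci_high, p_value, p_is_bound) {
  if (!is.na(ci_low) && !is.na(ci_high)) {
    list(log_se = (log(ci_high) - log(ci_low)) / (2 * Z95), source = "ci")
  } else if (!is.na(p_value)) {
    if (abs(log_point) < .Machine$double.eps) {
      return(list(log_se = NA_real_, source = "none"))
    }
    z <- qnorm(1 - p_value / 2)
    list(log_se = abs(log_point) / z,
         source = if (p_is_bound) "p-bound" else "p")
  } else {
    list(log_se = NA_real_, source = "none")
  }
}

#' Load pre-computed partner effect estimates
#'
#' Ingests the summary results contributed by data partners (EHR-based
#' odds or hazard ratios, spontaneous-report RORs) from the
#' `partner_results.tsv` layout: `partner_id`, `drug`, `adr`,
#' `estimate_type` (OR/HR/ROR), `point`, `ci_low`, `ci_high`,
#' `p_value`, `n`, empty fields allowed. A log-scale SE is recovered
#' from the CI when present, otherwise inverted from the p-value
#' (a bounded p like `"<.001"` is taken at its bound, the conservative
#' choice); the recovery route is recorded per row in `se_source`.
#'
#' @param data data frame or TSV path in the layout above.
#' @param dictionary optional [pv_dictionary()]; when given, drug/ADR
#'   keys are resolved and the harmonized ids recorded.
#' @return effect-estimate tibble, one row per input row, provenance
#'   `"ingested"`. Non-positive points and p-values outside (0, 1] are
#'   row errors.
#' @export
load_partner_results <- function(data, dictionary = NULL) {
  if (is.character(data) && length(data) == 1) data <- read_tsv_strict(data)
  data <- tibble::as_tibble(data)
  if (nrow(data) == 0) {
    return(new_estimate(estimate_type = character(), point = numeric(),
                        provenance = character())[0, ])
  }
  miss <- setdiff(c("partner_id", "drug", "adr", "estimate_type", "point"),
                  names(data))
  if (length(miss)) {
    abort(paste0("partner results missing column(s): ",
                 paste(miss, collapse = ", ")))
  }
  for (col in c("ci_low", "ci_high", "p_value", "n")) {
    if (!col %in% names(data)) data[[col]] <- NA
  }

  num <- function(x) suppressWarnings(as.numeric(x))
  point <- num(data$point)
  bad <- which(is.na(point) | point <= 0)
  if (length(bad)) {
    abort(paste0("non-positive or unparseable point estimate in row(s) ",
                 paste(bad, collapse = ", ")))
  }
  et <- toupper(as.character(data$estimate_type))
  bad_et <- which(!et %in% c("OR", "HR", "ROR"))
  if (length(bad_et)) {
    abort(paste0("estimate_type must be OR/HR/ROR; bad row(s) ",
                 paste(bad_et, collapse = ", ")))
  }

  p_raw <- as.character(data$p_value)
  p_raw[is.na(p_raw)] <- ""
  p_is_bound <- stringr::str_detect(p_raw, "^<")
  p_num <- num(stringr::str_remove(p_raw, "^<"))
  bad_p <- which(nzchar(p_raw) &
                   (is.na(p_num) | p_num <= 0 | p_num > 1))
  if (length(bad_p)) {
    abort(paste0("p_value outside (0,1] and not a '<' bound in row(s) ",
                 paste(bad_p, collapse = ", ")))
  }

  rows <- purrr::pmap_dfr(
    list(seq_len(nrow(data)), point, num(data$ci_low), num(data$ci_high),
         p_num, p_is_bound),
    function(i, pt, lo, hi, p, pb) {
      rec <- recover_log_se(log(pt), lo, hi, p, pb)
      new_estimate(
        partner_id = as.character(data$partner_id[i]),
        drug = as.character(data$drug[i]), adr = as.character(data$adr[i]),
        estimate_type = et[i], point = pt, log_se = rec$log_se,
        ci_low = lo, ci_high = hi, p_value = p, p_is_bound = pb,
        n_units = num(data$n)[i], provenance = "ingested",
        se_source = rec$source)
    })

  if (!is.null(dictionary)) {
    rows$drug_id <- vapply(rows$drug, function(d) {
      hit <- resolve_drug(dictionary, d)
      if (is.null(hit)) NA_character_ else hit$drug_id
    }, character(1), USE.NAMES = FALSE)
    rows$pt_name <- vapply(rows$adr, function(a) {
      hit <- resolve_adr(dictionary, a)
      if (is.null(hit)) NA_character_ else hit$pt_name
    }, character(1), USE.NAMES = FALSE)
  }
  rows
}

#' Scan all drug-event pairs of a report table for signals
#'
#' Computes the reporting odds ratio for every pair mentioned together
#' in at least `min_a` reports, with the continuity correction enabled
#' (batch scans hit zero cells constantly).
#'
#' @param reports a report table.
#' @param min_a minimum co-mention count to include a pair.
#' @return tibble of effect-estimate rows, one per retained pair,
#'   ordered by descending point estimate.
#' @export
signal_scan <- function(reports, min_a = 3) {
  if (!inherits(reports, "report_table")) reports <- as_report_table(reports)
  n_total <- nrow(reports)
  long_d <- tibble::tibble(report_id = rep(reports$report_id,
                                           lengths(reports$drugs)),
                           drug = unlist(reports$drugs)) |> dplyr::distinct()
  long_e <- tibble::tibble(report_id = rep(reports$report_id,
                                           lengths(reports$events)),
                           event = unlist(reports$events)) |> dplyr::distinct()
  pairs <- dplyr::inner_join(long_d, long_e, by = "report_id",
                             relationship = "many-to-many") |>
    dplyr::count(.data$drug, .data$event, name = "a") |>
    dplyr::filter(.data$a >= min_a)
  if (nrow(pairs) == 0) {
    return(new_estimate(estimate_type = character(), point = numeric(),
                        provenance = character())[0, ])
  }
  n_d <- dplyr::count(long_d, .data$drug, name = "n_drug")
  n_e <- dplyr::count(long_e, .data$event, name = "n_event")
  pairs <- pairs |>
    dplyr::left_join(n_d, by = "drug") |>
    dplyr::left_join(n_e, by = "event")
  purrr::pmap_dfr(pairs, function(drug, event, a, n_drug, n_event) {
    tab <- contingency_2x2(a, n_drug - a, n_event - a,
                           n_total - n_drug - n_event + a)
    odds_ratio(tab, correction = TRUE, estimate_type = "ROR",
               drug = drug, adr = event, partner_id = "scan")
  }) |>
    dplyr::arrange(dplyr::desc(.data$point))
}
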