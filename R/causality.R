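## WHO-UMC style causality categories, ordered.
CAUSALITY_LEVELS <- c("certain", "probable/likely", "possible", "unlikely",
                      "conditional/unclassified")

#' Assign a WHO-UMC style causality category to a drug-ADR pair
#'
#' Derives a set of evidence flags from the pooled meta-analysis and the
#' reference-matrix consensus, then applies a deterministic rubric.
#' Observational real-world evidence alone cannot establish the
#' dechallenge/rechallenge criteria the higher WHO-UMC categories
#' require, so the automatic rubric tops out at "possible"; "certain"
#' and "probable/likely" are reachable only through explicit
#' user-supplied clinical flags.
#'
#' Flags: `pooled-significant` (95% CI excludes 1 and pooled point > 1),
#' `pooled-protective` (CI excludes 1, point < 1, never upgrades),
#' `reference-positive`/`-negative`/`-conflicting` from the consensus,
#' `single-source-only` (exactly one data partner), `no-estimates`.
#'
#' Default rubric, evaluated top-down (first match wins, making the
#' category a total deterministic function of the flags):
#' \itemize{
#'   \item no estimates -> conditional/unclassified
#'   \item significant + user `rechallenge` flag -> certain
#'   \item significant + user `dechallenge` flag -> probable/likely
#'   \item not significant (CI spans 1, or protective) + reference
#'     negative -> unlikely
#'   \item not significant otherwise -> conditional/unclassified
#'   \item significant but a single data partner -> conditional/unclassified
#'   \item significant with >= 2 partners -> possible
#' }
#'
#' @param meta a [pool_random_effects()] result.
#' @param consensus consensus label of the pair in the reference matrix
#'   (`"positive"`, `"negative"`, `"unknown"`, `"conflicting"`).
#' @param n_partners number of distinct data partners behind the pooled
#'   estimates; defaults to the number of distinct `partner_id`s (or
#'   `k` when ids are absent).
#' @param user_flags optional character vector; `"dechallenge"` and/or
#'   `"rechallenge"` unlock the higher categories.
#' @return object of class `causality_assessment`: `pair`, `category`,
#'   `evidence_flags`, `rubric_trace` (fired rules, in order).
#' @export
#' @examples
#' est <- load_partner_results(tibble::tibble(
#'   partner_id = c("A", "B"), drug = "d", adr = "a",
#'   estimate_type = "OR", point = c(2.1, 1.8),
#'   ci_low = c(1.5, 1.2), ci_high = c(2.9, 2.7), p_value = NA, n = NA))
#' assess_causality(pool_random_effects(est), consensus = "positive")
assess_causality <- function(meta, consensus = "unknown", n_partners = NULL,
                             user_flags = character()) {
  stopifnot(inherits(meta, "meta_result"))
  if (!consensus %in% c("positive", "negative", "unknown", "conflicting")) {
    abort(paste0("unknown consensus label: ", consensus))
  }
  if (is.null(n_partners)) {
    ids <- meta$estimates$partner_id
    n_partners <- if (meta$k == 0) {
      0L
    } else if (all(is.na(ids))) {
      meta$k
    } else {
      length(unique(ids[!is.na(ids)]))
    }
  }

  flags <- character()
  if (meta$k == 0) flags <- c(flags, "no-estimates")
  significant <- meta$k > 0 && !is.na(meta$ci_low) &&
    (meta$ci_low > 1 || meta$ci_high < 1)
  if (significant && meta$pooled_point > 1) {
    flags <- c(flags, "pooled-significant")
  }
  if (significant && meta$pooled_point < 1) {
    flags <- c(flags, "pooled-protective")
  }
  flags <- c(flags, switch(consensus,
                           positive = "reference-positive",
                           negative = "reference-negative",
                           conflicting = "reference-conflicting",
                           NULL))
  if (meta$k > 0 && n_partners == 1) flags <- c(flags, "single-source-only")

  trace <- character()
  harmful <- "pooled-significant" %in% flags
  category <- if ("no-estimates" %in% flags) {
    trace <- c(trace, "no-estimates -> conditional/unclassified")
    "conditional/unclassified"
  } else if (harmful && "rechallenge" %in% user_flags) {
    trace <- c(trace, "significant + rechallenge -> certain")
    "certain"
  } else if (harmful && "dechallenge" %in% user_flags) {
    trace <- c(trace, "significant + dechallenge -> probable/likely")
    "probable/likely"
  } else if (!harmful && "reference-negative" %in% flags) {
    trace <- c(trace, "not significant + reference-negative -> unlikely")
    "unlikely"
  } else if (!harmful) {
    trace <- c(trace, "not significant -> conditional/unclassified")
    "conditional/unclassified"
  } else if ("single-source-only" %in% flags) {
    trace <- c(trace, "significant, single partner -> conditional/unclassified")
    "conditional/unclassified"
  } else {
    trace <- c(trace, "significant, >=2 partners -> possible")
    "possible"
  }

  structure(
    list(pair = meta$pair, category = category, evidence_flags = flags,
         rubric_trace = trace),
    class = "causality_assessment")
}

#' @export
print.causality_assessment <- function(x, ...) {
  cat("<causality_assessment> ", x$category, "\n", sep = "")
  cat("  flags:", paste(x$evidence_flags, collapse = ", "), "\n")
  cat("  trace:", paste(x$rubric_trace, collapse = "; "), "\n")
  invisible(x)
}
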