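#' Pool partner estimates with a DerSimonian-Laird random-effects model
#'
#' Inverse-variance pooling of log-scale effect estimates allowing for
#' between-study variance, with the DerSimonian-Laird moment estimator
#' of tau-squared — the pharmacovigilance-field default when nothing
#' more is assumed about the heterogeneity:
#'
#' fixed weights `w_i = 1/se_i^2`; `Q = sum w_i (y_i - y_fixed)^2`;
#' `tau2 = max(0, (Q - (k-1)) / (sum w - sum w^2 / sum w))`;
#' random-effects weights `w*_i = 1/(se_i^2 + tau2)`; pooled log effect
#' `sum w* y / sum w*` with 95% CI `exp(pooled +/- 1.959964/sqrt(sum w*))`.
#'
#' Heterogeneity is summarized by Q and `I2 = max(0, (Q-(k-1))/Q) x 100`.
#' Hazard ratios are pooled on the log scale alongside odds ratios; a
#' mixed-effect-measure warning flag is set when types differ. Further
#' warning flags mark SE-recovered-from-p inputs and `k < 3`.
#'
#' @param estimates effect-estimate tibble (see [load_partner_results()]
#'   or [odds_ratio()]); every row must carry `log_se`. `k = 0` returns
#'   a no-estimates result (which drives the causality flag) rather
#'   than erroring.
#' @param pair optional `c(drug, adr)` identifier carried on the result.
#' @return object of class `meta_result`: `k`, `pooled_log`,
#'   `pooled_point`, `ci_low`/`ci_high`, `pooled_se`, `tau2`, `q_stat`,
#'   `i2`, `fixed_effect_log`, `warnings`, and the input `estimates`.
#' @export
#' @examples
#' est <- dplyr::bind_rows(
#'   odds_ratio(contingency_2x2(20, 80, 10, 90)),
#'   odds_ratio(contingency_2x2(30, 70, 15, 85)))
#' pool_random_effects(est)
pool_random_effects <- function(estimates, pair = NULL) {
  estimates <- tibble::as_tibble(estimates)
  k <- nrow(estimates)
  warnings <- character()
  if (k == 0) {
    return(structure(
      list(pair = pair, k = 0L, pooled_log = NA_real_,
           pooled_point = NA_real_, ci_low = NA_real_, ci_high = NA_real_,
           pooled_se = NA_real_, tau2 = NA_real_, q_stat = NA_real_,
           i2 = NA_real_, fixed_effect_log = NA_real_,
           warnings = "no-estimates", estimates = estimates,
           estimator = "DL"),
      class = "meta_result"))
  }
  if (any(is.na(estimates$log_se) | estimates$log_se <= 0)) {
    bad <- which(is.na(estimates$log_se) | estimates$log_se <= 0)
    ids <- estimates$partner_id[bad]
    ids[is.na(ids)] <- paste0("row ", bad[is.na(ids)])
    abort(paste0("estimate(s) without a usable log-scale SE: ",
                 paste(ids, collapse = ", ")))
  }
  if (length(unique(estimates$estimate_type)) > 1) {
    warnings <- c(warnings, "mixed-effect-measures")
  }
  if (any(estimates$se_source %in% c("p", "p-bound"), na.rm = TRUE)) {
    warnings <- c(warnings, "se-recovered-from-p")
  }
  if (k < 3) warnings <- c(warnings, "k<3")

  y <- estimates$log_point
  v <- estimates$log_se^2
  w <- 1 / v
  fixed <- sum(w * y) / sum(w)
  q <- sum(w * (y - fixed)^2)
  tau2 <- if (k > 1) max(0, (q - (k - 1)) / (sum(w) - sum(w^2) / sum(w))) else 0
  ws <- 1 / (v + tau2)
  pooled <- sum(ws * y) / sum(ws)
  se <- 1 / sqrt(sum(ws))
  i2 <- if (k > 1 && q > 0) max(0, (q - (k - 1)) / q) * 100 else 0

  structure(
    list(pair = pair, k = k, pooled_log = pooled,
         pooled_point = exp(pooled),
         ci_low = exp(pooled - Z95 * se), ci_high = exp(pooled + Z95 * se),
         pooled_se = se, tau2 = tau2, q_stat = q, i2 = i2,
         fixed_effect_log = fixed, warnings = warnings,
         estimates = estimates, estimator = "DL"),
    class = "meta_result")
}

#' @export
print.meta_result <- function(x, ...) {
  if (x$k == 0) {
    cat("<meta_result> no estimates\n")
    return(invisible(x))
  }
  cat("<meta_result> k = ", x$k, ", pooled ", fmt_num(x$pooled_point),
      " (", fmt_num(x$ci_low), "-", fmt_num(x$ci_high), ")\n", sep = "")
  cat("  tau2 = ", signif(x$tau2, 4), ", Q = ", signif(x$q_stat, 4),
      ", I2 = ", fmt_num(x$i2, 1), "%\n", sep = "")
  if (length(x$warnings)) {
    cat("  warnings:", paste(x$warnings, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Tidy per-study rows of a meta-analysis
#'
#' @param x a [pool_random_effects()] result.
#' @param ... unused.
#' @return tibble with one row per pooled estimate plus its
#'   random-effects weight (percent).
#' @export
tidy.meta_result <- function(x, ...) {
  if (x$k == 0) {
    return(tibble::tibble(partner_id = character(),
                          estimate_type = character(),
                          point = numeric(), log_point = numeric(),
                          log_se = numeric(), weight_pct = numeric()))
  }
  wts <- 1 / (x$estimates$log_se^2 + x$tau2)
  tibble::tibble(
    partner_id = x$estimates$partner_id,
    estimate_type = x$estimates$estimate_type,
    point = x$estimates$point,
    log_point = x$estimates$log_point,
    log_se = x$estimates$log_se,
    weight_pct = 100 * wts / sum(wts))
}

#' One-row summary of a meta-analysis
#'
#' @inheritParams tidy.meta_result
#' @return one-row tibble: `k`, `pooled_point`, `ci_low`, `ci_high`,
#'   `tau2`, `q_stat`, `i2`, `warnings` (comma-joined).
#' @export
glance.meta_result <- function(x, ...) {
  tibble::tibble(k = x$k, pooled_point = x$pooled_point,
                 ci_low = x$ci_low, ci_high = x$ci_high,
                 tau2 = x$tau2, q_stat = x$q_stat, i2 = x$i2,
                 warnings = paste(x$warnings, collapse = ","))
}

#' Forest plot of a pooled meta-analysis
#'
#' Per-partner points with 95% intervals and the pooled random-effects
#' estimate, on a log-scaled ratio axis.
#'
#' @param object a `meta_result`.
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.meta_result <- function(object, ...) {
  if (object$k == 0) abort("nothing to plot: no estimates")
  td <- tidy(object)
  td$partner_id[is.na(td$partner_id)] <-
    paste0("study ", which(is.na(td$partner_id)))
  rows <- dplyr::bind_rows(
    tibble::tibble(label = td$partner_id, point = td$point,
                   lo = exp(td$log_point - Z95 * td$log_se),
                   hi = exp(td$log_point + Z95 * td$log_se),
                   pooled = FALSE),
    tibble::tibble(label = "RE pooled", point = object$pooled_point,
                   lo = object$ci_low, hi = object$ci_high, pooled = TRUE))
  rows$label <- factor(rows$label, levels = rev(rows$label))
  ggplot2::ggplot(rows, ggplot2::aes(x = .data$point, y = .data$label,
                                     colour = .data$pooled)) +
    ggplot2::geom_vline(xintercept = 1, linetype = 2, colour = "grey50") +
    ggplot2::geom_pointrange(ggplot2::aes(xmin = .data$lo,
                                          xmax = .data$hi),
                             show.legend = FALSE) +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "effect (ratio scale)", y = NULL) +
    ggplot2::theme_minimal()
}
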