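mk_est <- function(y, se, type = "OR", partner = NULL) {
  if (is.null(partner)) partner <- sprintf("P%02d", seq_along(y))
  load_partner_results(tibble::tibble(
    partner_id = partner,
    drug = "d", adr = "a", estimate_type = type,
    point = exp(y),
    ci_low = exp(y - 1.959964 * se), ci_high = exp(y + 1.959964 * se),
    p_value = NA, n = NA))
}

test_that("k = 1 pooling is the identity; homogeneity gives tau2 = 0", {
  one <- pool_random_effects(mk_est(log(2), 0.1))
  expect_equal(one$pooled_point, 2)
  expect_equal(one$tau2, 0)
  expect_equal(one$ci_low, exp(log(2) - 0.195996), tolerance = 1e-6)
  expect_equal(one$ci_high, exp(log(2) + 0.195996), tolerance = 1e-6)

  three <- pool_random_effects(mk_est(rep(0.5, 3), rep(0.2, 3)))
  expect_equal(three$q_stat, 0)
  expect_equal(three$tau2, 0)
  expect_equal(three$pooled_log, 0.5)
  expect_equal(three$pooled_se, 0.2 / sqrt(3))
  expect_equal(three$i2, 0)
})

test_that("DL matches an independent closed-form oracle to 1e-10", {
  set.seed(909)
  for (i in 1:1000) {
    k <- sample(2:8, 1)
    y <- rnorm(k, 0.3, 0.5)
    se <- runif(k, 0.05, 0.6)
    m <- pool_random_effects(mk_est(y, se))
    o <- dl_oracle(y, se)
    expect_equal(m$pooled_log, o$pooled, tolerance = 1e-10)
    expect_equal(m$tau2, o$tau2, tolerance = 1e-10)
    expect_equal(m$q_stat, o$q, tolerance = 1e-10)
    expect_equal(m$fixed_effect_log, o$fixed, tolerance = 1e-10)
    ## structural invariants
    expect_gte(m$tau2, 0)
    expect_gte(m$pooled_log, min(y) - 1e-12)
    expect_lte(m$pooled_log, max(y) + 1e-12)
    if (m$tau2 == 0) {
      expect_equal(m$pooled_log, m$fixed_effect_log, tolerance = 1e-12)
    }
    expect_equal(m$i2,
                 if (m$q_stat > 0) max(0, (m$q_stat - (k - 1)) / m$q_stat) * 100
                 else 0)
  }
})

test_that("DL agrees with metafor as an independent implementation", {
  skip_if_not_installed("metafor")
  set.seed(5150)
  for (i in 1:100) {
    k <- sample(2:8, 1)
    y <- rnorm(k, 0.3, 0.5)
    se <- runif(k, 0.05, 0.6)
    m <- pool_random_effects(mk_est(y, se))
    r <- metafor::rma(yi = y, sei = se, method = "DL")
    expect_equal(m$pooled_log, as.numeric(r$beta), tolerance = 1e-8)
    expect_equal(m$tau2, r$tau2, tolerance = 1e-8)
    expect_equal(m$q_stat, r$QE, tolerance = 1e-8)
  }
})

test_that("adding a pooled-value estimate leaves the pool fixed at tau2=0", {
  est <- mk_est(rep(0.4, 4), c(0.1, 0.2, 0.15, 0.3))
  m <- pool_random_effects(est)
  expect_equal(m$tau2, 0)
  more <- dplyr::bind_rows(est, mk_est(m$pooled_log, 0.25, partner = "PX"))
  m2 <- pool_random_effects(more)
  expect_lt(abs(m2$pooled_log - m$pooled_log), 1e-12)
  ## CI width strictly decreases with an added finite-SE estimate
  expect_lt(m2$ci_high - m2$ci_low, m$ci_high - m$ci_low)
})

test_that("warnings flag mixed measures, SE-from-p inputs, and small k", {
  mixed <- dplyr::bind_rows(mk_est(0.4, 0.2, type = "OR"),
                            mk_est(0.5, 0.2, type = "HR", partner = "PH"))
  expect_true("mixed-effect-measures" %in%
                pool_random_effects(mixed)$warnings)
  expect_true("k<3" %in% pool_random_effects(mixed)$warnings)

  from_p <- load_partner_results(tibble::tibble(
    partner_id = c("A", "B", "C"), drug = "d", adr = "a",
    estimate_type = "OR", point = c(2, 1.8, 2.2),
    ci_low = NA, ci_high = NA, p_value = c("<.001", ".02", ".001"), n = NA))
  expect_true("se-recovered-from-p" %in%
                pool_random_effects(from_p)$warnings)
})

test_that("k = 0 is a no-estimates value; missing SE is a named error", {
  empty <- pool_random_effects(mk_est(numeric(0), numeric(0)))
  expect_equal(empty$k, 0)
  expect_true("no-estimates" %in% empty$warnings)

  bad <- mk_est(c(0.4, 0.5), c(0.2, 0.2))
  bad$log_se[2] <- NA
  expect_error(pool_random_effects(bad), "P02")
})

test_that("seeded generator recovery: pooled effect and tau2 (k=6)", {
  ## 500 seeded replicates of k = 6 estimates, true log effect 0.4,
  ## within-study SE 0.15, between-study tau 0.2 (tau2 = 0.04)
  pooled <- numeric(500)
  tau2 <- numeric(500)
  for (s in 1:500) {
    cfg <- sim_config(seed = s, partner_spec = list(
      k = 6L, true_log_effect = 0.4, within_se = 0.15, tau = 0.2))
    sim <- simulate_partner_estimates(cfg)
    m <- pool_random_effects(load_partner_results(sim$partners))
    pooled[s] <- m$pooled_log
    tau2[s] <- m$tau2
  }
  mc_se <- stats::sd(pooled) / sqrt(500)
  expect_lt(abs(mean(pooled) - 0.4), 3 * mc_se)
  expect_gte(stats::median(tau2), 0.02)
  expect_lte(stats::median(tau2), 0.08)
})

test_that("95% CI coverage of the true effect stays in the 90-98% band", {
  ## k = 6 >= 5, tau = 0: DL's slight undercoverage at small k tolerated
  hits <- vapply(1:300, function(s) {
    cfg <- sim_config(seed = s, partner_spec = list(
      k = 6L, true_log_effect = 0.4, within_se = 0.15, tau = 0))
    sim <- simulate_partner_estimates(cfg)
    m <- pool_random_effects(load_partner_results(sim$partners))
    m$ci_low <= exp(0.4) && m$ci_high >= exp(0.4)
  }, logical(1))
  expect_gte(mean(hits), 0.90)
  expect_lte(mean(hits), 0.98)
})

test_that("tidy/glance/autoplot expose the pooled result", {
  m <- pool_random_effects(mk_est(c(0.3, 0.5, 0.4), c(0.1, 0.2, 0.15)))
  td <- tidy(m)
  expect_equal(nrow(td), 3)
  expect_equal(sum(td$weight_pct), 100)
  gl <- glance(m)
  expect_equal(gl$k, 3)
  expect_equal(gl$pooled_point, m$pooled_point)
  p <- autoplot(m)
  expect_s3_class(p, "ggplot")
})
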