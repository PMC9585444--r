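test_that("ingest_source resolves, normalizes, and tracks unresolved rows", {
  d <- demo_dictionary()
  s <- ingest_source(
    data.frame(drug = c("Fluconazole", "famotidine", "unknownium"),
               adr = c("hypokalemia", "hepatic function abnormality",
                       "Hypokalemia"),
               label = c("Positive", "NEGATIVE", "positive")),
    "T", d)
  expect_equal(nrow(s$pairs), 2)
  expect_setequal(s$pairs$label, c("positive", "negative"))
  expect_equal(s$pairs$pt_name[s$pairs$drug_id == "D_FAM"],
               "Hepatic function abnormal")
  expect_equal(nrow(s$unresolved), 1)
  expect_equal(s$unresolved$reason, "unknown drug")

  empty <- ingest_source(file.path(demo_dir(), "refsource_OMOP.tsv"),
                         "OMOP", d)
  expect_equal(nrow(empty$pairs), 0)

  expect_error(
    ingest_source(data.frame(drug = c("fluconazole", "fluconazole"),
                             adr = "Hypokalemia",
                             label = c("positive", "negative")),
                  "X", d),
    "both positive and negative")
  expect_error(
    ingest_source(data.frame(drug = "fluconazole", adr = "Hypokalemia",
                             label = "maybe"), "X", d),
    "unknown label")
})

test_that("consensus matches the rule-table oracle over all vote maps", {
  srcs <- c("S", "O", "E")
  policies <- c("flag", "negative-precedence", "positive-precedence",
                "majority")
  ## every subset of sources x every 0/1 assignment (maps of size <= 3)
  for (n in 0:3) {
    for (who in utils::combn(3, n, simplify = FALSE)) {
      grid <- if (n == 0) list(integer(0)) else
        asplit(as.matrix(expand.grid(rep(list(0:1), n))), 1)
      for (vals in grid) {
        labels <- setNames(as.integer(vals), srcs[who])
        for (pol in policies) {
          expect_equal(consensus_label(labels, pol),
                       consensus_oracle(labels, pol),
                       label = paste(pol, paste(labels, collapse = "")))
        }
      }
    }
  }
  ## permutation invariance
  expect_equal(consensus_label(c(A = 1L, B = 0L)),
               consensus_label(c(B = 0L, A = 1L)))
})

test_that("documented consensus examples hold", {
  expect_equal(consensus_code(consensus_label(setNames(integer(0),
                                                       character(0)))), "2")
  expect_equal(consensus_code(consensus_label(c(S = 1L, O = 1L))), "1")
  expect_equal(consensus_label(c(S = 1L, O = 0L)), "conflicting")
  expect_equal(consensus_label(c(S = 1L, O = 0L),
                               policy = "negative-precedence"), "negative")
})

test_that("accounting identity holds over random shapes and sparse sources", {
  d0 <- demo_dictionary()
  set.seed(1203)
  for (rep in 1:8) {
    nd <- sample(2:30, 1)
    na <- sample(2:30, 1)
    cfg <- sim_config(seed = rep, n_drugs = nd, n_adrs = na,
                      refsource_spec = tibble::tibble(
                        source_id = c("S1", "S2"),
                        n_positive = sample(0:((nd * na) %/% 5), 2),
                        n_negative = sample(0:((nd * na) %/% 5), 2)))
    fx <- simulate_reference_fixture(cfg)
    dict <- pv_dictionary(fx$drugs, fx$adrs, quiet = TRUE)
    sources <- lapply(names(fx$sources), function(id) {
      ingest_source(fx$sources[[id]], id, dict)
    })
    m <- build_reference_matrix(dict$drugs$drug_id, dict$adrs$pt_name,
                                sources)
    cov <- coverage_stats(m)
    expect_equal(cov$n_positive + cov$n_negative + cov$n_unknown,
                 rep(nd * na, 2))
    expect_equal(cov$n_positive, fx$ground_truth$sources$n_positive)
    expect_equal(cov$n_negative, fx$ground_truth$sources$n_negative)
  }
})

test_that("consensus is source-order invariant and idempotent", {
  d <- demo_dictionary()
  srcs <- unname(demo_sources(d))
  m1 <- build_reference_matrix(d$drugs$drug_id, d$adrs$pt_name, srcs)
  m2 <- build_reference_matrix(d$drugs$drug_id, d$adrs$pt_name, rev(srcs))
  ord <- function(x) dplyr::arrange(x, drug_id, pt_name)
  expect_equal(ord(m1$consensus), ord(m2$consensus))
  ## recomputing consensus from stored cells changes nothing
  again <- m1$cells |>
    dplyr::summarise(n_pos = sum(value == 1L), n_neg = sum(value == 0L),
                     .by = c(drug_id, pt_name))
  expect_equal(nrow(again), nrow(m1$consensus))
})

test_that("pairs outside the index are skipped with a warning count", {
  d <- demo_dictionary()
  s <- ingest_source(data.frame(drug = "fluconazole", adr = "Hypokalemia",
                                label = "positive"), "S", d)
  expect_warning(
    m <- build_reference_matrix("D_FAM", d$adrs$pt_name, list(s)),
    "skipped")
  expect_equal(m$n_skipped, 1)
  expect_equal(nrow(m$cells), 0)
  expect_error(build_reference_matrix(c("D1", "D1"), "A1", list()),
               "duplicate drug_ids")
})

test_that("matrix serialization round-trips exactly", {
  m <- demo_matrix()
  dir <- withr::local_tempdir()
  write_reference_matrix(m, dir)
  m2 <- read_reference_matrix(dir)
  expect_equal(m2$drug_index, m$drug_index)
  expect_equal(m2$adr_index, m$adr_index)
  expect_equal(tibble::as_tibble(m2$cells), tibble::as_tibble(m$cells))
  expect_equal(tibble::as_tibble(m2$consensus),
               tibble::as_tibble(m$consensus))
  ## bit-exact file round trip: write again, bytes identical
  dir2 <- withr::local_tempdir()
  write_reference_matrix(m2, dir2)
  for (f in c("matrix_cells.tsv", "matrix_consensus.tsv",
              "matrix_index.tsv")) {
    expect_identical(readBin(file.path(dir, f), "raw", 1e6),
                     readBin(file.path(dir2, f), "raw", 1e6), label = f)
  }
})

test_that("coverage rounding follows the half-up, <50% one-decimal rule", {
  ## 165+234 of 756 cells -> 52.78 -> 53; 94 of 680 -> 13.8
  cfgO <- sim_config(seed = 3, n_drugs = 189, n_adrs = 4,
                     refsource_spec = tibble::tibble(
                       source_id = "OMOP", n_positive = 165L,
                       n_negative = 234L))
  fxO <- simulate_reference_fixture(cfgO)
  dO <- pv_dictionary(fxO$drugs, fxO$adrs, quiet = TRUE)
  mO <- build_reference_matrix(dO$drugs$drug_id, dO$adrs$pt_name,
                               list(ingest_source(fxO$sources$OMOP, "OMOP",
                                                  dO)))
  expect_equal(coverage_stats(mO, "OMOP")$covered_fraction, 53)
  expect_error(coverage_stats(mO, "SIDER"), "unknown source_id")
})
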