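#' Resolve a run configuration
#'
#' A run config names the inputs and conventions of one pipeline run:
#' dictionary directory, reference-source files, optional report and
#' partner-result files, consensus policy, continuity-correction flag,
#' estimator, seed, output directory, and terminology version strings.
#' Accepts a YAML file path or a plain list; unspecified fields take
#' defaults. The resolved config is written next to every run's outputs
#' together with its hash, so a run is reproducible from its artifacts.
#'
#' @param config YAML path or named list.
#' @return list of class `run_config` with all fields populated and a
#'   `hash` attribute.
#' @export
run_config <- function(config = list()) {
  if (is.character(config) && length(config) == 1) {
    config <- yaml::read_yaml(config)
  }
  defaults <- list(
    dictionary = NULL, sources = list(), reports = NULL, partners = NULL,
    policy = "flag", correction = TRUE, estimator = "DL",
    seed = 1L, out = "rsadr_out",
    versions = list(meddra = "unpinned", loinc = "unpinned",
                    icd10 = "unpinned", atc = "unpinned"))
  cfg <- modifyList(defaults, config)
  cfg$hash <- rlang::hash(cfg[setdiff(names(cfg), "hash")])
  structure(cfg, class = "run_config")
}

#' Build the reference-standard artifacts end to end
#'
#' Runs vocabulary loading and reference-set construction in one pass:
#' reads the dictionary, ingests every configured source, assembles the
#' consensus-labeled reference matrix over the dictionary's full drug
#' and ADR universe, and computes per-source coverage. Artifacts
#' (sparse matrix TSVs, `coverage.json`, a copy of the dictionary, the
#' resolved config) are written under the configured output directory.
#'
#' @param config a [run_config()] (or list/YAML path coerced to one).
#' @return list with `dictionary`, `sources`, `matrix`, `coverage`
#'   (invisible); artifacts on disk under `config$out`.
#' @export
rsadr_build <- function(config) {
  cfg <- if (inherits(config, "run_config")) config else run_config(config)
  if (is.null(cfg$dictionary)) abort("run config must name a dictionary dir")
  dict <- read_pv_dictionary(cfg$dictionary, versions = cfg$versions,
                             quiet = TRUE)
  inform(paste0("build: dictionary loaded (", nrow(dict$drugs), " drugs, ",
                nrow(dict$adrs), " ADR PTs)"))
  sources <- purrr::imap(cfg$sources, function(path, id) {
    s <- ingest_source(path, id, dict)
    inform(paste0("build: source ", id, ": ", nrow(s$pairs), " pairs, ",
                  nrow(s$unresolved), " unresolved"))
    s
  })
  mat <- build_reference_matrix(dict$drugs$drug_id, dict$adrs$pt_name,
                                unname(sources), policy = cfg$policy)
  cov <- coverage_stats(mat)
  inform(paste0("build: matrix ", length(mat$drug_index), " x ",
                length(mat$adr_index), " = ",
                format(n_cells(mat), big.mark = ","), " pairs; ",
                nrow(mat$cells), " labeled cells"))

  dir.create(cfg$out, showWarnings = FALSE, recursive = TRUE)
  write_reference_matrix(mat, file.path(cfg$out, "matrix"))
  write_pv_dictionary(dict, file.path(cfg$out, "dictionary"))
  jsonlite::write_json(cov, file.path(cfg$out, "coverage.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  if (!is.null(cfg$partners)) {
    file.copy(cfg$partners, file.path(cfg$out, "partner_results.tsv"),
              overwrite = TRUE)
  }
  cfg_out <- unclass(cfg)
  jsonlite::write_json(cfg_out, file.path(cfg$out, "run_config.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       null = "null")
  invisible(list(dictionary = dict, sources = sources, matrix = mat,
                 coverage = cov))
}

#' Query built artifacts for one drug-ADR pair
#'
#' The file-based replacement for an interactive explorer: loads the
#' artifacts written by [rsadr_build()], resolves the pair, pools any
#' partner estimates on file for it, and returns the consolidated
#' [pair_report()] (printed fields ordered SOC, ADR, drug, identifiers,
#' per-source labels, partner estimates, meta, causality).
#'
#' @param artifacts_dir directory written by [rsadr_build()].
#' @param pair `"DRUG:ADR"` string, or length-2 character vector.
#' @return a `pair_report`; unknown drugs/ADRs are an error.
#' @export
rsadr_query <- function(artifacts_dir, pair) {
  if (length(pair) == 1) pair <- strsplit(pair, ":", fixed = TRUE)[[1]]
  if (length(pair) != 2) abort("pair must be 'DRUG:ADR'")
  dict <- read_pv_dictionary(file.path(artifacts_dir, "dictionary"),
                             quiet = TRUE)
  mat <- read_reference_matrix(file.path(artifacts_dir, "matrix"))
  est <- NULL
  pfile <- file.path(artifacts_dir, "partner_results.tsv")
  if (file.exists(pfile)) {
    all_est <- load_partner_results(pfile, dictionary = dict)
    dc <- resolve_drug(dict, pair[1])
    ac <- resolve_adr(dict, pair[2])
    if (!is.null(dc) && !is.null(ac)) {
      est <- all_est[!is.na(all_est$drug_id) & all_est$drug_id == dc$drug_id &
                       !is.na(all_est$pt_name) &
                       all_est$pt_name == ac$pt_name, ]
    }
  }
  pair_report(dict, mat, est, drug = pair[1], adr = pair[2])
}

#' Path to the bundled worked-example fixture
#'
#' A miniature, hand-written fixture mirroring the package's worked
#' example: a dictionary containing fluconazole (ATC J02AC01) and
#' famotidine with the ADRs hypokalemia (LOINC 2823_3 direction low,
#' ICD-10 E87.6) and hepatic function abnormal, three reference sources
#' in which only SIDER votes on fluconazole/hypokalemia, and the four
#' partner estimate rows for each pair. All content is synthetic in the
#' sense of being package-authored; no licensed terminology is bundled.
#'
#' @return directory path inside the installed package.
#' @export
example_fixture_dir <- function() {
  system.file("extdata", "fluconazole_demo", package = "rsadr")
}
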