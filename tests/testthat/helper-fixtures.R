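## Shared fixtures, all built in code or read from the bundled
## worked-example directory.

demo_dir <- function() example_fixture_dir()

demo_dictionary <- function() {
  read_pv_dictionary(demo_dir(), quiet = TRUE)
}

demo_sources <- function(dict = demo_dictionary()) {
  lapply(c(SIDER = "SIDER", OMOP = "OMOP", EUADR = "EUADR"), function(id) {
    ingest_source(file.path(demo_dir(), paste0("refsource_", id, ".tsv")),
                  id, dict)
  })
}

demo_matrix <- function(dict = demo_dictionary()) {
  build_reference_matrix(dict$drugs$drug_id, dict$adrs$pt_name,
                         unname(demo_sources(dict)))
}

demo_partner_estimates <- function(dict = demo_dictionary()) {
  load_partner_results(file.path(demo_dir(), "partner_results.tsv"),
                       dictionary = dict)
}

## Independent closed-form DerSimonian-Laird evaluation used as the
## oracle against the package implementation.
dl_oracle <- function(y, se) {
  v <- se^2
  w <- 1 / v
  fixed <- sum(w * y) / sum(w)
  q <- sum(w * (y - fixed)^2)
  k <- length(y)
  tau2 <- if (k > 1) max(0, (q - (k - 1)) / (sum(w) - sum(w^2) / sum(w))) else 0
  ws <- 1 / (v + tau2)
  list(pooled = sum(ws * y) / sum(ws), tau2 = tau2, q = q, fixed = fixed,
       se = 1 / sqrt(sum(ws)))
}

## Brute-force double-loop recount of a 2x2 from a report table.
contingency_oracle <- function(reports, drug, event) {
  a <- b <- c <- d <- 0L
  for (i in seq_len(nrow(reports))) {
    hd <- drug %in% reports$drugs[[i]]
    he <- event %in% reports$events[[i]]
    if (hd && he) a <- a + 1L
    else if (hd) b <- b + 1L
    else if (he) c <- c + 1L
    else d <- d + 1L
  }
  c(a = a, b = b, c = c, d = d)
}

## Rule-by-rule consensus oracle, evaluated per label map.
consensus_oracle <- function(labels, policy) {
  n_pos <- sum(labels == 1L)
  n_neg <- sum(labels == 0L)
  if (n_pos + n_neg == 0) return("unknown")
  switch(policy,
    "flag" = if (n_pos > 0 && n_neg > 0) "conflicting"
             else if (n_pos > 0) "positive" else "negative",
    "negative-precedence" = if (n_neg > 0) "negative" else "positive",
    "positive-precedence" = if (n_pos > 0) "positive" else "negative",
    "majority" = if (n_pos > n_neg) "positive"
                 else if (n_neg > n_pos) "negative" else "conflicting")
}
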