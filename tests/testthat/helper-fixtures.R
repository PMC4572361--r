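# Shared fixtures, built once per test run. Everything is generated in
# code from seeded specs; no binary fixtures.

.fixture_env <- new.env(parent = emptyenv())

# the standard planted table: 4 targets x 3 series x 5 compounds,
# 5 invalid rows, 5 qualifier rows, seed 7
standard_fixture <- function() {
  if (is.null(.fixture_env$std)) {
    spec <- fixtureSpec()
    fx <- makeSyntheticTsv(spec, tempfile(fileext = ".tsv"))
    tab <- buildReferenceTable(fx$path, verbose = FALSE)
    .fixture_env$std <- list(spec = spec, fx = fx, table = tab)
  }
  .fixture_env$std
}

# a small two-series fixture for cheaper tests
small_fixture <- function() {
  if (is.null(.fixture_env$small)) {
    spec <- fixtureSpec(n_targets = 2, series_per_target = 1,
                        compounds_per_series = 5, n_invalid_smiles = 0,
                        n_qualifier_rows = 0, seed = 11)
    fx <- makeSyntheticTsv(spec, tempfile(fileext = ".tsv"))
    tab <- buildReferenceTable(fx$path, families = "path", verbose = FALSE)
    .fixture_env$small <- list(spec = spec, fx = fx, table = tab)
  }
  .fixture_env$small
}

# metric profiles over the full 12-series pair panel (the calibration
# panel the package would derive a default selection from)
rich_profiles <- function() {
  if (is.null(.fixture_env$prof)) {
    panel <- makePairPanel(fixtureSpec())
    .fixture_env$prof <- metricProfiles(panel)
  }
  .fixture_env$prof
}

# independent brute-force oracle for the bit-vector formulas: literal
# position-by-position enumeration, no popcount shortcuts
oracle_bit_similarity <- function(x, y, formula) {
  a <- 0L; b <- 0L; cc <- 0L
  for (i in seq_along(x)) {
    if (x[i]) a <- a + 1L
    if (y[i]) b <- b + 1L
    if (x[i] && y[i]) cc <- cc + 1L
  }
  if (a == 0L && b == 0L) return(1)
  if (a == 0L || b == 0L) return(0)
  switch(formula,
         tanimoto = cc / (a + b - cc),
         dice = 2 * cc / (a + b),
         cosine = cc / sqrt(a * b))
}

# independent brute-force scan oracle: loop over every record, compute
# the similarity, filter, sort with the documented tie-breaks
oracle_scan <- function(query, table, config) {
  recs <- records(table)
  sims <- vapply(recs$smiles, function(s) pathSimilarity(query, s),
                 numeric(1), USE.NAMES = FALSE)
  keep <- which(sims >= config$similarity_threshold &
                recs$affinity_nM <= config$affinity_cutoff_nM)
  out <- recs[keep, , drop = FALSE]
  out$similarity <- sims[keep]
  out <- out[order(-out$similarity, out$affinity_nM, out$monomer_id), ,
             drop = FALSE]
  rownames(out) <- NULL
  out
}

# exhaustive subset oracle for the correlation filter: all k-subsets,
# minimize the maximum pairwise |r|
oracle_min_max_cor <- function(cm, k) {
  n <- ncol(cm)
  best <- NULL; best_val <- Inf
  for (subset in utils::combn(n, k, simplify = FALSE)) {
    sub <- abs(cm[subset, subset, drop = FALSE])
    diag(sub) <- 0
    v <- max(sub)
    if (v < best_val - 1e-12) { best_val <- v; best <- subset }
  }
  list(subset = best, value = best_val)
}

max_pairwise_abs_cor <- function(cm, subset) {
  sub <- abs(cm[subset, subset, drop = FALSE])
  diag(sub) <- 0
  max(sub)
}
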