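# Bit-vector similarity formulas, the metric catalog, metric profiles,
# the correlation filter and the averaged similarity metric.

.FORMULAS <- c("tanimoto", "dice", "cosine")

#' Bit-vector fingerprint similarity
#'
#' With a and b the set-bit counts of the two fingerprints and c the
#' count of shared bits: Tanimoto = c/(a+b-c), Dice = 2c/(a+b),
#' Cosine = c/sqrt(a*b). By convention two all-zero fingerprints score 1
#' under every formula and a single all-zero fingerprint scores 0 (the
#' textbook formulas are 0/0 there).
#'
#' @param fp_a,fp_b \code{BitFingerprint} objects or plain logical
#'   vectors of equal length
#' @param formula one of "tanimoto", "dice", "cosine"
#' @return similarity in [0, 1]
#' @examples
#' a <- c(TRUE, TRUE, FALSE); b <- c(TRUE, FALSE, TRUE)
#' bitSimilarity(a, b, "tanimoto")
#' @export
bitSimilarity <- function(fp_a, fp_b, formula = c("tanimoto", "dice", "cosine")) {
  formula <- match.arg(formula)
  if (is(fp_a, "BitFingerprint") && is(fp_b, "BitFingerprint")) {
    if (fp_a@family != fp_b@family)
      stop(sprintf("fingerprints are not comparable: families '%s' vs '%s'",
                   fp_a@family, fp_b@family), call. = FALSE)
    fp_a <- fp_a@bits; fp_b <- fp_b@bits
  } else {
    fp_a <- as.logical(fp_a); fp_b <- as.logical(fp_b)
  }
  if (length(fp_a) != length(fp_b))
    stop(sprintf("fingerprints are not comparable: lengths %d vs %d",
                 length(fp_a), length(fp_b)), call. = FALSE)
  a <- sum(fp_a); b <- sum(fp_b); cc <- sum(fp_a & fp_b)
  .bitFormula(a, b, cc, formula)
}

.bitFormula <- function(a, b, cc, formula) {
  if (a == 0 && b == 0) return(1)
  if (a == 0 || b == 0) return(0)
  switch(formula,
         tanimoto = cc / (a + b - cc),
         dice = 2 * cc / (a + b),
         cosine = cc / sqrt(a * b))
}

# similarity of one fingerprint against every row of a fingerprint matrix
.bitSimilarityRows <- function(mat, fp, formula) {
  a <- rowSums(mat)
  b <- sum(fp)
  cc <- as.numeric(mat %*% fp)
  out <- switch(formula,
                tanimoto = cc / (a + b - cc),
                dice = 2 * cc / (a + b),
                cosine = cc / sqrt(a * b))
  out[a == 0 & b == 0] <- 1
  out[xor(a == 0, b == 0)] <- 0
  out[is.na(out)] <- 0
  out
}

#' Path-fingerprint Tanimoto similarity between two compounds
#'
#' The package's flagship fast similarity: Tanimoto over the
#' Daylight-style topological subgraph-hash fingerprint (all branched
#' bond subgraphs up to 7 bonds, hashed into 2048 bits, 2 bits per
#' subgraph) with default parameters.
#'
#' @param smiles_a,smiles_b SMILES strings
#' @return Tanimoto similarity in [0, 1]
#' @examples
#' pathSimilarity("CCO", "CCCO")
#' @export
pathSimilarity <- function(smiles_a, smiles_b) {
  ma <- molFromSmiles(smiles_a); mb <- molFromSmiles(smiles_b)
  bitSimilarity(.fpFromMol(ma, "path"), .fpFromMol(mb, "path"), "tanimoto")
}

#' The similarity-metric catalog
#'
#' Crosses every registered fingerprint family with the three bit-vector
#' comparison formulas (Tanimoto, Dice, Cosine): 14 families x 3 formulas
#' = 42 enumerable metrics, of which 3N are computable with the N
#' families available here.
#'
#' @param families family registry (defaults to the shipped one)
#' @return a \code{MetricCatalog}
#' @export
metricCatalog <- function(families = fingerprintFamilies()) {
  metrics <- expand.grid(family_id = families$family_id,
                         formula = .FORMULAS,
                         KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  metrics$metric_id <- paste(metrics$family_id, metrics$formula, sep = ":")
  metrics$available <- metrics$family_id %in%
    families$family_id[families$available]
  new("MetricCatalog", families = families, formulas = .FORMULAS,
      metrics = metrics)
}

#' @param x a MetricCatalog
#' @param available_only drop metrics whose family is not computable
#' @rdname metricCatalog
#' @export
catalogMetrics <- function(x, available_only = FALSE) {
  m <- x@metrics
  if (available_only) m <- m[m$available, , drop = FALSE]
  `rownames<-`(m, NULL)
}

#' Similarity profiles of compound pairs under every available metric
#'
#' Applies each computable metric of the catalog to each compound pair;
#' this pairs-by-metrics matrix is the input to the correlation filter.
#' Pairs whose structures fail to parse are dropped and recorded in the
#' "failed_pairs" attribute.
#'
#' @param pairs data.frame with columns smiles_a, smiles_b
#' @param catalog a \code{MetricCatalog}
#' @return numeric matrix (pairs x metrics), values in [0, 1]
#' @export
metricProfiles <- function(pairs, catalog = metricCatalog()) {
  stopifnot(is.data.frame(pairs), all(c("smiles_a", "smiles_b") %in% names(pairs)))
  metrics <- catalogMetrics(catalog, available_only = TRUE)
  smis <- unique(c(pairs$smiles_a, pairs$smiles_b))
  mols <- .parseBatch(smis)
  ok_smis <- smis[!vapply(mols, is.null, logical(1))]
  keep <- pairs$smiles_a %in% ok_smis & pairs$smiles_b %in% ok_smis
  failed <- which(!keep)
  pairs <- pairs[keep, , drop = FALSE]
  fams <- unique(metrics$family_id)
  fps <- computeFingerprints(ok_smis, fams,
                             mols = mols[match(ok_smis, smis)])
  ia <- match(pairs$smiles_a, ok_smis)
  ib <- match(pairs$smiles_b, ok_smis)
  prof <- matrix(NA_real_, nrow(pairs), nrow(metrics),
                 dimnames = list(NULL, metrics$metric_id))
  for (k in seq_len(nrow(metrics))) {
    fam <- metrics$family_id[k]; form <- metrics$formula[k]
    m <- fps[[fam]]
    prof[, k] <- vapply(seq_len(nrow(pairs)), function(i)
      .bitFormula(sum(m[ia[i], ]), sum(m[ib[i], ]),
                  sum(m[ia[i], ] & m[ib[i], ]), form), numeric(1))
  }
  attr(prof, "failed_pairs") <- failed
  prof
}

#' Select the k least mutually correlated similarity metrics
#'
#' Computes the Pearson correlation matrix of the metric columns over the
#' pair panel, then greedily eliminates redundancy: repeatedly locate the
#' metric pair with the highest absolute correlation and drop the member
#' with the larger mean absolute correlation to the surviving metrics
#' (ties broken by dropping the later catalog column), until k remain.
#' Zero-variance metrics get correlation 0 to everything, with a warning.
#'
#' @param profiles pairs x metrics matrix from \code{metricProfiles}
#' @param k number of metrics to retain (default 5)
#' @return a \code{MetricSelection}
#' @export
correlationFilter <- function(profiles, k = 5) {
  stopifnot(is.matrix(profiles), ncol(profiles) >= 2, nrow(profiles) >= 3)
  if (k > ncol(profiles))
    stop("k cannot exceed the number of metrics", call. = FALSE)
  sds <- apply(profiles, 2, stats::sd)
  if (any(sds == 0))
    warning(sprintf("constant-profile metric(s): %s; correlations set to 0",
                    paste(colnames(profiles)[sds == 0], collapse = ", ")))
  cm <- suppressWarnings(stats::cor(profiles))
  cm[is.na(cm)] <- 0
  diag(cm) <- 1
  alive <- seq_len(ncol(profiles))
  while (length(alive) > k) {
    sub <- abs(cm[alive, alive, drop = FALSE])
    diag(sub) <- -1
    mx <- which(sub == max(sub), arr.ind = TRUE)[1, ]
    i <- alive[mx[1]]; j <- alive[mx[2]]
    mean_i <- mean(abs(cm[i, setdiff(alive, i)]))
    mean_j <- mean(abs(cm[j, setdiff(alive, j)]))
    drop <- if (mean_i > mean_j) i
            else if (mean_j > mean_i) j
            else max(i, j)              # tie: later catalog index goes
    alive <- setdiff(alive, drop)
  }
  sel_ids <- colnames(profiles)[alive]
  parts <- strsplit(sel_ids, ":", fixed = TRUE)
  selected <- data.frame(
    metric_id = sel_ids,
    family_id = vapply(parts, `[`, character(1), 1),
    formula = vapply(parts, `[`, character(1), 2),
    stringsAsFactors = FALSE)
  new("MetricSelection", selected = selected, correlation = cm,
      panel = list(n_pairs = nrow(profiles), k = k))
}

#' Averaged multi-metric similarity
#'
#' The unweighted arithmetic mean of the selected metrics' similarity
#' scores for one compound pair (default selection size 5).
#'
#' @param smiles_a,smiles_b SMILES strings
#' @param selection a \code{MetricSelection}
#' @return mean similarity in [0, 1]
#' @export
averagedSimilarity <- function(smiles_a, smiles_b, selection) {
  stopifnot(is(selection, "MetricSelection"))
  sel <- selection@selected
  if (nrow(sel) == 0) stop("empty metric selection", call. = FALSE)
  fams <- unique(sel$family_id)
  fps <- computeFingerprints(c(smiles_a, smiles_b), fams)
  mean(vapply(seq_len(nrow(sel)), function(k) {
    m <- fps[[sel$family_id[k]]]
    .bitFormula(sum(m[1, ]), sum(m[2, ]), sum(m[1, ] & m[2, ]),
                sel$formula[k])
  }, numeric(1)))
}

#' Save / load a metric selection as JSON
#'
#' @param selection a \code{MetricSelection}
#' @param path file path
#' @export
writeMetricSelection <- function(selection, path) {
  jsonlite::write_json(list(
    format = "fmct-metric-selection", version = 1L,
    selected = selection@selected,
    correlation = selection@correlation,
    metric_ids = colnames(selection@correlation),
    panel = selection@panel), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname writeMetricSelection
#' @export
readMetricSelection <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(x$format, "fmct-metric-selection"))
    stop("not a metric-selection file", call. = FALSE)
  cm <- as.matrix(x$correlation)
  dimnames(cm) <- list(x$metric_ids, x$metric_ids)
  new("MetricSelection", selected = as.data.frame(x$selected),
      correlation = cm, panel = as.list(x$panel))
}
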