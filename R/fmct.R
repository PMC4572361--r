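# The target-prediction engine: scan, UniProt merging, single-query and
# batch reports, MCS re-ranking.

#' Query configuration for target prediction
#'
#' @param variant similarity variant: single path-fingerprint Tanimoto
#'   ("path_tanimoto", the fast default), five-metric average ("avg5"),
#'   pure MCS ("pure_mcs"), or fingerprint scan re-ranked by MCS
#'   ("path_then_mcs")
#' @param similarity_threshold minimum similarity, inclusive (so a
#'   threshold of 1.0 returns exact matches); default 0.7
#' @param affinity_cutoff_nM maximum affinity in nM; default 10000
#'   (10 uM), matching the customary potency cutoff
#' @param top_n_per_compound targets reported per compound in batch mode
#' @param selection a \code{MetricSelection}, required for "avg5"
#' @param mcs_opts options for the MCS variants
#' @return configuration list
#' @export
queryConfig <- function(variant = c("path_tanimoto", "avg5", "pure_mcs",
                                    "path_then_mcs"),
                        similarity_threshold = 0.7,
                        affinity_cutoff_nM = 10000,
                        top_n_per_compound = 3,
                        selection = NULL,
                        mcs_opts = mcsOpts()) {
  variant <- match.arg(variant)
  stopifnot(similarity_threshold >= 0, similarity_threshold <= 1,
            affinity_cutoff_nM > 0, top_n_per_compound >= 1)
  list(variant = variant, similarity_threshold = similarity_threshold,
       affinity_cutoff_nM = affinity_cutoff_nM,
       top_n_per_compound = top_n_per_compound,
       selection = selection, mcs_opts = mcs_opts)
}

# similarity of the query against a subset of table records under the
# configured variant (the scan's inner loop)
.querySimilarities <- function(query_smiles, table, config, idx) {
  recs <- table@records[idx, , drop = FALSE]
  variant <- config$variant
  if (variant %in% c("path_tanimoto", "path_then_mcs")) {
    if (!"path" %in% names(table@fingerprints))
      stop("table lacks the 'path' fingerprint family; rebuild with it",
           call. = FALSE)
    qfp <- .fpFromMol(molFromSmiles(query_smiles), "path")
    return(.bitSimilarityRows(table@fingerprints$path[idx, , drop = FALSE],
                              qfp, "tanimoto"))
  }
  if (variant == "avg5") {
    sel <- config$selection
    if (is.null(sel))
      stop("variant 'avg5' needs a MetricSelection in the query config",
           call. = FALSE)
    seldf <- sel@selected
    missing_fam <- setdiff(unique(seldf$family_id), names(table@fingerprints))
    if (length(missing_fam))
      stop(sprintf("table lacks fingerprint families needed by the selection: %s",
                   paste(missing_fam, collapse = ", ")), call. = FALSE)
    qfps <- computeFingerprints(query_smiles, unique(seldf$family_id))
    sims <- vapply(seq_len(nrow(seldf)), function(k) {
      fam <- seldf$family_id[k]
      .bitSimilarityRows(table@fingerprints[[fam]][idx, , drop = FALSE],
                         qfps[[fam]][1, ], seldf$formula[k])
    }, numeric(length(idx)))
    if (length(idx) == 1L) return(mean(sims))
    return(rowMeans(matrix(sims, nrow = length(idx))))
  }
  # pure_mcs
  vapply(recs$smiles, function(s)
    mcsSimilarity(query_smiles, s, config$mcs_opts)@similarity, numeric(1),
    USE.NAMES = FALSE)
}

#' Scan a query compound against a reference table
#'
#' Computes the similarity of the query to every record, then returns the
#' records passing both gates: affinity at most the cutoff and similarity
#' at least the threshold (inclusive). Hits are sorted by similarity
#' (desc), affinity (asc), monomer id (asc) so reports are reproducible.
#'
#' @param query_smiles query compound SMILES
#' @param table a \code{ReferenceTable}
#' @param config a \code{\link{queryConfig}}
#' @return data.frame of compound hits (record fields + similarity;
#'   mcs_similarity column reserved for re-ranking)
#' @export
scanTable <- function(query_smiles, table, config = queryConfig()) {
  stopifnot(is(table, "ReferenceTable"))
  if (nRecords(table) == 0) stop("empty reference table", call. = FALSE)
  molFromSmiles(query_smiles)  # structure gate before any work
  idx <- which(table@records$affinity_nM <= config$affinity_cutoff_nM)
  hits <- table@records[idx, , drop = FALSE]
  if (length(idx)) {
    sims <- .querySimilarities(query_smiles, table, config, idx)
    keep <- sims >= config$similarity_threshold
    hits <- hits[keep, , drop = FALSE]
    hits$similarity <- sims[keep]
    hits$record_index <- idx[keep]
  } else {
    hits$similarity <- numeric(0)
    hits$record_index <- integer(0)
  }
  hits$mcs_similarity <- rep(NA_real_, nrow(hits))
  ord <- order(-hits$similarity, hits$affinity_nM, hits$monomer_id)
  hits <- hits[ord, , drop = FALSE]
  rownames(hits) <- NULL
  hits
}

#' Re-rank fingerprint hits by MCS similarity
#'
#' Computes the MCS similarity of the query to every hit and reorders by
#' (MCS similarity desc, fingerprint similarity desc, monomer id asc).
#' The hit set is unchanged; a per-hit search-budget exhaustion keeps the
#' best-so-far MCS value and sorts with it.
#'
#' @param hits data.frame from \code{\link{scanTable}}
#' @param query_smiles the query compound
#' @param opts MCS options
#' @return the same hits, mcs_similarity populated, re-sorted
#' @export
mcsRerank <- function(hits, query_smiles, opts = mcsOpts()) {
  if (nrow(hits) == 0) return(hits)
  mcs <- lapply(hits$smiles, function(s) mcsSimilarity(query_smiles, s, opts))
  hits$mcs_similarity <- vapply(mcs, function(m) m@similarity, numeric(1))
  hits$mcs_timed_out <- vapply(mcs, function(m) m@timedOut, logical(1))
  ord <- order(-hits$mcs_similarity, -hits$similarity, hits$monomer_id)
  hits <- hits[ord, , drop = FALSE]
  rownames(hits) <- NULL
  hits
}

#' Merge compound hits into per-protein target hits
#'
#' Several similar compounds frequently bind the same protein; duplicate
#' protein hits are merged on the UniProt primary accession. Records
#' without an accession are grouped under their target name instead and
#' flagged. Supporting compound hits are preserved per target, ordered by
#' ranking similarity.
#'
#' @param hits data.frame of compound hits
#' @param rank_by which similarity column drives ranking ("similarity" or
#'   "mcs_similarity")
#' @return list(target_hits = data.frame, supporting = list of
#'   data.frames)
#' @export
mergeByUniprot <- function(hits, rank_by = "similarity") {
  if (nrow(hits) == 0)
    return(list(target_hits = data.frame(
      uniprot_primary = character(), target_name = character(),
      best_similarity = numeric(), n_supporting = integer(),
      no_accession = logical(), stringsAsFactors = FALSE),
      supporting = list()))
  no_acc <- is.na(hits$uniprot_primary) | !nzchar(trimws(hits$uniprot_primary))
  key <- ifelse(no_acc, paste0("name:", hits$target_name), hits$uniprot_primary)
  rank_sim <- hits[[rank_by]]
  groups <- split(seq_len(nrow(hits)), key)
  th <- do.call(rbind, lapply(names(groups), function(k) {
    g <- groups[[k]]
    data.frame(
      uniprot_primary = if (startsWith(k, "name:")) NA_character_ else k,
      target_name = hits$target_name[g[which.max(rank_sim[g])]],
      best_similarity = max(rank_sim[g]),
      n_supporting = length(g),
      no_accession = startsWith(k, "name:"),
      stringsAsFactors = FALSE)
  }))
  supporting <- lapply(names(groups), function(k) {
    g <- groups[[k]]
    s <- hits[g[order(-rank_sim[g], hits$affinity_nM[g], hits$monomer_id[g])],
              , drop = FALSE]
    rownames(s) <- NULL
    s
  })
  ord <- order(-th$best_similarity, th$target_name)
  list(target_hits = `rownames<-`(th[ord, , drop = FALSE], NULL),
       supporting = supporting[ord])
}

#' Predict protein targets for a single query compound
#'
#' The full single-compound workflow: scan the reference table with the
#' configured similarity variant, (for the hybrid variant) re-rank hits
#' by MCS similarity, merge hits by UniProt accession and report ranked
#' target hypotheses.
#'
#' @param query_smiles query compound SMILES
#' @param table a \code{ReferenceTable}
#' @param config a \code{\link{queryConfig}}
#' @return a \code{\linkS4class{PredictionReport}}
#' @export
predictTargets <- function(query_smiles, table, config = queryConfig()) {
  hits <- scanTable(query_smiles, table, config)
  rank_by <- "similarity"
  if (config$variant == "path_then_mcs" && nrow(hits)) {
    hits <- mcsRerank(hits, query_smiles, config$mcs_opts)
    rank_by <- "mcs_similarity"
  }
  merged <- mergeByUniprot(hits, rank_by = rank_by)
  rng <- if (nrow(hits)) {
    rs <- hits[[rank_by]]
    c(max(rs), min(rs))
  } else c(NA_real_, NA_real_)
  cfg <- config
  cfg$selection <- NULL  # keep the report lightweight
  new("PredictionReport", query = query_smiles,
      canonical = canonicalSmiles(query_smiles),
      config = cfg, targetHits = merged$target_hits,
      supporting = merged$supporting, similarityRange = rng)
}

#' Batch target prediction with a condensed top-N report
#'
#' One row per query compound listing its top N candidate targets
#' (default 3). Unparsable queries are reported per row, not fatal;
#' every parsable row equals the truncation of the corresponding
#' single-compound report.
#'
#' @param queries named character vector of SMILES, or a file path
#'   (.smi: one SMILES per line, optional id after whitespace; .sdf:
#'   V2000)
#' @param table a \code{ReferenceTable}
#' @param config a \code{\link{queryConfig}}
#' @return data.frame, one row per query
#' @export
predictTargetsBatch <- function(queries, table, config = queryConfig()) {
  if (is.character(queries) && length(queries) == 1 && file.exists(queries))
    queries <- readQueryFile(queries)
  if (is.null(names(queries)) || !all(nzchar(names(queries))))
    names(queries) <- sprintf("query_%d", seq_along(queries))
  n_top <- config$top_n_per_compound
  rows <- lapply(seq_along(queries), function(i) {
    row <- list(query_id = names(queries)[i], smiles = unname(queries[i]),
                error = NA_character_)
    rep <- tryCatch(predictTargets(queries[[i]], table, config),
                    fmct_structure_error = function(e) e)
    if (inherits(rep, "condition")) {
      row$error <- conditionMessage(rep)
      th <- NULL
    } else th <- targetHits(rep)
    for (k in seq_len(n_top)) {
      has <- !is.null(th) && nrow(th) >= k
      row[[sprintf("target_%d", k)]] <- if (has) th$target_name[k] else NA_character_
      row[[sprintf("uniprot_%d", k)]] <- if (has) th$uniprot_primary[k] else NA_character_
      row[[sprintf("similarity_%d", k)]] <- if (has) th$best_similarity[k] else NA_real_
    }
    as.data.frame(row, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (all(!is.na(out$error)) && nrow(out) > 0)
    stop("no query compound could be parsed", call. = FALSE)
  out
}

#' Read query compounds from a .smi or .sdf file
#'
#' @param path file path; .smi = one SMILES per line with optional id,
#'   .sdf = V2000 structures (converted through the toolkit)
#' @return named character vector of SMILES
#' @export
readQueryFile <- function(path) {
  if (grepl("\\.sdf$", path, ignore.case = TRUE)) {
    sdf <- ChemmineR::read.SDFset(path)
    smi <- as.character(ChemmineR::sdf2smiles(sdf))
    names(smi) <- ChemmineR::sdfid(sdf)
    return(smi)
  }
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  parts <- strsplit(lines, "[ \t]+")
  smi <- vapply(parts, `[`, character(1), 1)
  ids <- vapply(seq_along(parts), function(i)
    if (length(parts[[i]]) > 1) parts[[i]][2] else sprintf("query_%d", i),
    character(1))
  stats::setNames(smi, ids)
}

#' Write a prediction report to CSV
#'
#' Single-compound mode: one target per row with its best supporting
#' compound evidence. Column order is fixed: target_name, uniprot,
#' best_similarity, supporting_monomer_id, supporting_smiles,
#' affinity_type, affinity_nM.
#'
#' @param report a \code{PredictionReport}
#' @param path output CSV path
#' @export
writeReport <- function(report, path) {
  th <- targetHits(report)
  sup <- supportingHits(report)
  out <- do.call(rbind, lapply(seq_len(nrow(th)), function(i) {
    s <- sup[[i]][1, ]
    data.frame(target_name = th$target_name[i],
               uniprot = th$uniprot_primary[i],
               best_similarity = th$best_similarity[i],
               supporting_monomer_id = s$monomer_id,
               supporting_smiles = s$smiles,
               affinity_type = s$affinity_type,
               affinity_nM = s$affinity_nM,
               stringsAsFactors = FALSE)
  }))
  if (is.null(out))
    out <- data.frame(target_name = character(), uniprot = character(),
                      best_similarity = numeric(),
                      supporting_monomer_id = character(),
                      supporting_smiles = character(),
                      affinity_type = character(), affinity_nM = numeric())
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}
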