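# Reference-set reduction: per-target clustering and representative
# selection, producing a condensed table with the same schema.

#' Configuration for reference-set reduction
#'
#' The clustering gate is stated as "a distance threshold of 0.8" in the
#' source workflow; read literally (Tanimoto distance <= 0.8, i.e.
#' similarity >= 0.2) that is implausibly loose, so the default
#' interpretation here is a SIMILARITY threshold: a compound joins a
#' cluster when its Tanimoto similarity to the cluster leader is at
#' least \code{cluster_threshold}. Set \code{distance = TRUE} to restore
#' the literal distance reading (membership when 1 - similarity <=
#' threshold).
#'
#' @param cluster_threshold threshold on the 0-1 scale, default 0.8
#' @param representatives_per_cluster representatives kept per cluster
#' @param selection_policy "highest_affinity" (lowest affinity_nM wins,
#'   ties by monomer id) or "random" (seeded uniform draw)
#' @param seed integer seed for the random policy
#' @param distance interpret the threshold as a distance, see above
#' @param method "leader" (deterministic sphere-exclusion, the default)
#'   or "agglomerative" (complete-linkage; exact but quadratic, for
#'   small groups and as a cross-check)
#' @return configuration list
#' @export
reductionConfig <- function(cluster_threshold = 0.8,
                            representatives_per_cluster = 1,
                            selection_policy = c("highest_affinity", "random"),
                            seed = 1L, distance = FALSE,
                            method = c("leader", "agglomerative")) {
  stopifnot(cluster_threshold > 0, cluster_threshold < 1,
            representatives_per_cluster >= 1)
  list(cluster_threshold = cluster_threshold,
       representatives_per_cluster = representatives_per_cluster,
       selection_policy = match.arg(selection_policy),
       seed = as.integer(seed), distance = isTRUE(distance),
       method = match.arg(method))
}

#' Group table records by protein target
#'
#' Records partition by UniProt primary accession; records lacking an
#' accession group under a flagged target-name key ("name:<target>") so
#' they still carry signal rather than being dropped.
#'
#' @param table a \code{ReferenceTable}
#' @return named list of integer record indices
#' @export
groupByTarget <- function(table) {
  stopifnot(is(table, "ReferenceTable"), nRecords(table) > 0)
  recs <- table@records
  no_acc <- is.na(recs$uniprot_primary) | !nzchar(trimws(recs$uniprot_primary))
  key <- ifelse(no_acc, paste0("name:", recs$target_name), recs$uniprot_primary)
  split(seq_len(nrow(recs)), key)
}

# leader clustering over path-fingerprint Tanimoto
.leaderCluster <- function(fp, order_idx, sim_threshold) {
  clusters <- list()   # each: list(leader_row, members)
  for (i in order_idx) {
    placed <- FALSE
    for (ci in seq_along(clusters)) {
      leader <- clusters[[ci]]$leader
      s <- .bitFormula(sum(fp[leader, ]), sum(fp[i, ]),
                       sum(fp[leader, ] & fp[i, ]), "tanimoto")
      if (s >= sim_threshold) {
        clusters[[ci]]$members <- c(clusters[[ci]]$members, i)
        placed <- TRUE
        break
      }
    }
    if (!placed)
      clusters[[length(clusters) + 1]] <- list(leader = i, members = i)
  }
  lapply(clusters, `[[`, "members")
}

#' Cluster one target group by fingerprint similarity
#'
#' Default algorithm: leader (sphere-exclusion) clustering. Records are
#' visited in (affinity asc, monomer id asc) order; a record joins the
#' first cluster whose leader is at least as similar as the threshold,
#' otherwise it founds a new cluster. Deterministic and O(n k). The
#' agglomerative method (complete linkage cut at the threshold) serves as
#' an exact cross-check on small groups.
#'
#' @param table a \code{ReferenceTable}
#' @param idx integer record indices of one target group
#' @param config a \code{\link{reductionConfig}}
#' @param key group label for the result
#' @return a \code{\linkS4class{ClusterSet}}
#' @export
clusterGroup <- function(table, idx, config = reductionConfig(),
                         key = "group") {
  stopifnot(length(idx) >= 1)
  if (!"path" %in% names(table@fingerprints))
    stop("clustering needs the 'path' fingerprint family in the table",
         call. = FALSE)
  recs <- table@records[idx, , drop = FALSE]
  fp <- table@fingerprints$path
  sim_threshold <- if (config$distance) 1 - config$cluster_threshold
                   else config$cluster_threshold
  ord <- idx[order(recs$affinity_nM, recs$monomer_id)]
  if (config$method == "leader") {
    clusters <- .leaderCluster(fp, ord, sim_threshold)
  } else {
    if (length(idx) == 1) clusters <- list(idx)
    else {
      sims <- outer(seq_along(ord), seq_along(ord), Vectorize(function(i, j)
        .bitFormula(sum(fp[ord[i], ]), sum(fp[ord[j], ]),
                    sum(fp[ord[i], ] & fp[ord[j], ]), "tanimoto")))
      hc <- stats::hclust(stats::as.dist(1 - sims), method = "complete")
      memb <- stats::cutree(hc, h = 1 - sim_threshold)
      clusters <- lapply(split(seq_along(ord), memb), function(g) ord[g])
      names(clusters) <- NULL
    }
  }
  cs <- new("ClusterSet", key = key, clusters = clusters,
            representatives = integer(0))
  cs@representatives <- .pickRepresentatives(table, cs, config)
  cs
}

.pickRepresentatives <- function(table, cluster_set, config) {
  recs <- table@records
  n_rep <- config$representatives_per_cluster
  unlist(lapply(seq_along(cluster_set@clusters), function(ci) {
    members <- cluster_set@clusters[[ci]]
    k <- min(n_rep, length(members))
    if (config$selection_policy == "highest_affinity") {
      members[order(recs$affinity_nM[members],
                    recs$monomer_id[members])][seq_len(k)]
    } else {
      rng <- .seededSample(config$seed + ci, length(members), k)
      sort(members[rng])
    }
  }))
}

# seeded draw that leaves the caller's RNG state untouched
.seededSample <- function(seed, n, k) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv())
          else suppressWarnings(rm(".Random.seed", envir = globalenv())))
  set.seed(seed)
  sample.int(n, k)
}

#' Select cluster representatives
#'
#' Applies the configured policy to an existing \code{ClusterSet}:
#' "highest_affinity" keeps the lowest-affinity_nM records (ties broken
#' by monomer id); "random" draws uniformly with the configured seed.
#' Clusters smaller than the requested count contribute all members.
#'
#' @param table a \code{ReferenceTable}
#' @param cluster_set a \code{ClusterSet}
#' @param config a \code{\link{reductionConfig}}
#' @return integer record indices of the representatives
#' @export
selectRepresentatives <- function(table, cluster_set,
                                  config = reductionConfig()) {
  .pickRepresentatives(table, cluster_set, config)
}

#' Build a reduced reference table
#'
#' Groups records by target, clusters each group at the configured
#' threshold, keeps the representative records, and assembles a table
#' with the same schema as the input. Build metadata records the
#' reduction ratio and cluster counts.
#'
#' @param table a \code{ReferenceTable}
#' @param config a \code{\link{reductionConfig}}
#' @return a \code{ReferenceTable} containing only the representatives
#' @export
buildReducedTable <- function(table, config = reductionConfig()) {
  groups <- groupByTarget(table)
  keep <- integer(0)
  n_clusters <- 0L
  for (key in names(groups)) {
    cs <- clusterGroup(table, groups[[key]], config, key = key)
    n_clusters <- n_clusters + length(cs@clusters)
    keep <- c(keep, cs@representatives)
  }
  keep <- sort(keep)
  meta <- table@buildMeta
  meta$reduction <- list(
    full_records = nRecords(table),
    reduced_records = length(keep),
    n_clusters = n_clusters,
    cluster_threshold = config$cluster_threshold,
    threshold_is_distance = config$distance,
    policy = config$selection_policy,
    representatives_per_cluster = config$representatives_per_cluster)
  new("ReferenceTable",
      records = `rownames<-`(table@records[keep, , drop = FALSE], NULL),
      fingerprints = lapply(table@fingerprints, function(m)
        m[keep, , drop = FALSE]),
      buildMeta = meta)
}
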