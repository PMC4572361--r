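# Per-target clustering and reference-set reduction.

test_that("target groups partition the table", {
  std <- standard_fixture()
  groups <- groupByTarget(std$table)
  expect_equal(length(groups), std$spec$n_targets)
  sizes <- lengths(groups)
  expect_equal(sum(sizes), nRecords(std$table))
  expect_true(all(sizes == std$spec$series_per_target *
                    std$spec$compounds_per_series))
  expect_false(anyDuplicated(unlist(groups)) > 0)
})

test_that("identical structures collapse to one cluster", {
  f <- tempfile(fileext = ".tsv")
  d <- defaultDialect()
  writeLines(c(paste(c(d$smiles, d$monomer_id, d$target_name, d$uniprot,
                       d$ki, d$ic50), collapse = "\t"),
               sprintf("CCOc1ccccc1\tM%d\tT\tP12345\t%d\t", 1:4, c(5, 2, 9, 4))),
             f)
  tab <- buildReferenceTable(f, families = "path", verbose = FALSE)
  cs <- clusterGroup(tab, 1:4, reductionConfig())
  expect_length(cs@clusters, 1)
})

test_that("planted series produce exactly one cluster each at 0.8", {
  std <- standard_fixture()
  groups <- groupByTarget(std$table)
  for (key in names(groups)) {
    cs <- clusterGroup(std$table, groups[[key]], reductionConfig(), key = key)
    expect_length(cs@clusters, std$spec$series_per_target)
  }
})

test_that("leader and agglomerative clustering agree on well-separated fixtures", {
  std <- standard_fixture()
  groups <- groupByTarget(std$table)
  idx <- groups[[1]]
  lead <- clusterGroup(std$table, idx, reductionConfig(method = "leader"))
  aggl <- clusterGroup(std$table, idx, reductionConfig(method = "agglomerative"))
  canon <- function(cs) sort(vapply(cs@clusters, function(x)
    paste(sort(x), collapse = ","), character(1)))
  expect_equal(canon(lead), canon(aggl))
})

test_that("mutually dissimilar singletons stay singletons", {
  # verified dissimilar by brute-force pairwise similarity below
  smis <- c("CCO", "c1ccc2[nH]ccc2c1", "C1CCNCC1", "CC(=O)OC")
  f <- tempfile(fileext = ".tsv")
  d <- defaultDialect()
  writeLines(c(paste(c(d$smiles, d$monomer_id, d$target_name, d$uniprot,
                       d$ki, d$ic50), collapse = "\t"),
               sprintf("%s\tM%d\tT\tP12345\t10\t", smis, seq_along(smis))), f)
  tab <- buildReferenceTable(f, families = "path", verbose = FALSE)
  pairs <- utils::combn(length(smis), 2)
  for (k in seq_len(ncol(pairs)))
    expect_lt(pathSimilarity(smis[pairs[1, k]], smis[pairs[2, k]]), 0.8)
  cs <- clusterGroup(tab, seq_along(smis), reductionConfig())
  expect_length(cs@clusters, length(smis))
})

test_that("the distance reading of the threshold merges far more", {
  std <- standard_fixture()
  groups <- groupByTarget(std$table)
  strict <- clusterGroup(std$table, groups[[1]], reductionConfig())
  loose <- clusterGroup(std$table, groups[[1]],
                        reductionConfig(distance = TRUE))
  expect_lte(length(loose@clusters), length(strict@clusters))
})

test_that("highest-affinity policy returns the argmin; random is seed-stable; size clamps", {
  std <- standard_fixture()
  groups <- groupByTarget(std$table)
  idx <- groups[[1]]
  cfg <- reductionConfig()
  cs <- clusterGroup(std$table, idx, cfg)
  recs <- records(std$table)
  for (ci in seq_along(cs@clusters)) {
    members <- cs@clusters[[ci]]
    rep_i <- intersect(cs@representatives, members)
    expect_length(rep_i, 1)
    expect_equal(recs$affinity_nM[rep_i], min(recs$affinity_nM[members]))
  }
  r1 <- selectRepresentatives(std$table, cs,
                              reductionConfig(selection_policy = "random",
                                              seed = 99))
  r2 <- selectRepresentatives(std$table, cs,
                              reductionConfig(selection_policy = "random",
                                              seed = 99))
  expect_identical(r1, r2)
  expect_true(all(r1 %in% unlist(cs@clusters)))
  all_of_it <- selectRepresentatives(
    std$table, cs, reductionConfig(representatives_per_cluster = 100))
  expect_setequal(all_of_it, unlist(cs@clusters))
})

test_that("the reduced table keeps one verbatim record per planted cluster", {
  std <- standard_fixture()
  red <- buildReducedTable(std$table)
  expect_equal(nRecords(red),
               std$spec$n_targets * std$spec$series_per_target)
  expect_lte(nRecords(red), nRecords(std$table))
  # every reduced record appears verbatim in the full table
  full_keys <- do.call(paste, records(std$table))
  red_keys <- do.call(paste, records(red))
  expect_true(all(red_keys %in% full_keys))
  expect_equal(buildMeta(red)$reduction$n_clusters, nRecords(red))
  # schema identical
  expect_identical(names(records(red)), names(records(std$table)))
  expect_identical(names(fingerprints(red)), names(fingerprints(std$table)))
})

test_that("recall: in-cluster queries survive reduction, between-cluster queries degrade", {
  std <- standard_fixture()
  red <- buildReducedTable(std$table)
  cfg <- queryConfig(similarity_threshold = 0.7)
  # planted in-cluster queries: recovered at rank 1 on both tables
  for (i in seq_len(nrow(std$fx$manifest$queries))) {
    q <- std$fx$manifest$queries[i, ]
    expect_equal(targetHits(predictTargets(q$query_smiles, std$table,
                                           cfg))$uniprot_primary[1],
                 q$expected_target)
    expect_equal(targetHits(predictTargets(q$query_smiles, red,
                                           cfg))$uniprot_primary[1],
                 q$expected_target)
  }
  # a query sitting near a non-representative member: similar enough to
  # that member, but not to the cluster representative, at a stringent
  # threshold -> found on the full table, lost on the reduced one
  recs <- records(std$table)
  member <- recs$smiles[recs$monomer_id == "M00003"]  # decorated, not the base
  probe <- fmct:::.insertAt(member, fmct:::.decorationPoints(member)[1], "I")
  strict <- queryConfig(similarity_threshold = 0.9)
  full_hits <- targetHits(predictTargets(probe, std$table, strict))
  red_hits <- targetHits(predictTargets(probe, red, strict))
  expect_gte(nrow(full_hits), 1)
  expect_lt(nrow(red_hits), nrow(full_hits))
})
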