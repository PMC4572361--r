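# The target-prediction engine.

test_that("an exact reference compound is the sole top hit at threshold 0.99", {
  tab <- small_fixture()$table
  q <- records(tab)$smiles[3]
  hits <- scanTable(q, tab, queryConfig(similarity_threshold = 0.99))
  expect_gte(nrow(hits), 1)
  expect_equal(hits$similarity[1], 1)
  expect_equal(hits$monomer_id[1], records(tab)$monomer_id[3])
})

test_that("scan equals the brute-force all-records oracle across random configs", {
  tab <- standard_fixture()$table
  qs <- standard_fixture()$fx$manifest$queries$query_smiles
  set.seed(1234)
  for (i in 1:10) {
    cfg <- queryConfig(similarity_threshold = stats::runif(1, 0.2, 0.95),
                       affinity_cutoff_nM = 10^stats::runif(1, 1, 4.5))
    q <- qs[(i %% length(qs)) + 1]
    got <- scanTable(q, tab, cfg)
    want <- oracle_scan(q, tab, cfg)
    expect_equal(got$monomer_id, want$monomer_id,
                 label = sprintf("config %d hit list", i))
    expect_equal(got$similarity, want$similarity, tolerance = 1e-12)
  }
})

test_that("threshold 1.0 with no exact match yields an empty, non-error result", {
  tab <- small_fixture()$table
  hits <- scanTable("c1ccc2[nH]ccc2c1", tab,
                    queryConfig(similarity_threshold = 1.0))
  expect_equal(nrow(hits), 0)
})

test_that("raising thresholds or tightening the cutoff never adds hits", {
  std <- standard_fixture()
  q <- std$fx$manifest$queries$query_smiles[1]
  loose <- scanTable(q, std$table, queryConfig(similarity_threshold = 0.3,
                                               affinity_cutoff_nM = 1e5))
  tight_sim <- scanTable(q, std$table, queryConfig(similarity_threshold = 0.8,
                                                   affinity_cutoff_nM = 1e5))
  tight_aff <- scanTable(q, std$table, queryConfig(similarity_threshold = 0.3,
                                                   affinity_cutoff_nM = 100))
  expect_true(all(tight_sim$monomer_id %in% loose$monomer_id))
  expect_true(all(tight_aff$monomer_id %in% loose$monomer_id))
})

test_that("unparsable queries are structure errors; empty tables are errors", {
  tab <- small_fixture()$table
  expect_error(scanTable("C1CC", tab), class = "fmct_structure_error")
})

test_that("uniprot merging groups, conserves and ranks supporters", {
  hits <- data.frame(
    smiles = sprintf("C%s", c("CO", "CN", "CC", "CCC")),
    monomer_id = sprintf("M%d", 1:4),
    target_name = c("H1", "H1", "H1", "5-HT1A"),
    uniprot_primary = c("P35367", "P35367", "P35367", "P08908"),
    affinity_type = "Ki", affinity_nM = c(10, 20, 30, 5),
    similarity = c(0.9, 0.8, 0.7, 0.95),
    mcs_similarity = NA_real_, stringsAsFactors = FALSE)
  merged <- mergeByUniprot(hits)
  th <- merged$target_hits
  expect_equal(nrow(th), 2)
  expect_equal(th$uniprot_primary[1], "P08908")  # best similarity first
  expect_equal(th$n_supporting[th$uniprot_primary == "P35367"], 3)
  expect_equal(sum(th$n_supporting), nrow(hits))  # conservation
  sup <- merged$supporting[[which(th$uniprot_primary == "P35367")]]
  expect_equal(sup$similarity, sort(sup$similarity, decreasing = TRUE))
  # empty input
  empty <- mergeByUniprot(hits[0, ])
  expect_equal(nrow(empty$target_hits), 0)
})

test_that("merging falls back to flagged target names when accessions are missing", {
  hits <- data.frame(
    smiles = "CCO", monomer_id = c("M1", "M2"),
    target_name = c("orphan A", "orphan A"),
    uniprot_primary = c(NA, ""),
    affinity_type = "Ki", affinity_nM = c(1, 2),
    similarity = c(0.9, 0.8), mcs_similarity = NA_real_,
    stringsAsFactors = FALSE)
  merged <- mergeByUniprot(hits)
  expect_equal(nrow(merged$target_hits), 1)
  expect_true(merged$target_hits$no_accession)
  expect_equal(merged$target_hits$n_supporting, 2)
})

test_that("supporting-hit group sizes match a hand tally on fixture hits", {
  std <- standard_fixture()
  q <- std$fx$manifest$queries$query_smiles[1]
  hits <- scanTable(q, std$table, queryConfig(similarity_threshold = 0.3))
  merged <- mergeByUniprot(hits)
  tally <- table(hits$uniprot_primary)
  for (i in seq_len(nrow(merged$target_hits))) {
    up <- merged$target_hits$uniprot_primary[i]
    expect_equal(merged$target_hits$n_supporting[i], unname(tally[up]))
  }
  expect_equal(sum(merged$target_hits$n_supporting), nrow(hits))
})

test_that("the planted query ranks its target first, matching the oracle", {
  std <- standard_fixture()
  for (i in seq_len(nrow(std$fx$manifest$queries))) {
    q <- std$fx$manifest$queries[i, ]
    rep <- predictTargets(q$query_smiles, std$table, queryConfig())
    th <- targetHits(rep)
    expect_equal(th$uniprot_primary[1], q$expected_target)
    want <- oracle_scan(q$query_smiles, std$table, queryConfig())
    expect_equal(th$best_similarity[1], max(want$similarity))
  }
})

test_that("a query with no neighbor above threshold reports empty with advice", {
  tab <- small_fixture()$table
  rep <- predictTargets("c1ccc2[nH]ccc2c1", tab, queryConfig())
  expect_equal(nrow(targetHits(rep)), 0)
  expect_output(show(rep), "lowering the similarity threshold")
})

test_that("MCS re-ranking preserves the hit set and populates every score", {
  std <- standard_fixture()
  q <- std$fx$manifest$queries$query_smiles[1]
  hits <- scanTable(q, std$table, queryConfig(similarity_threshold = 0.3))
  rr <- mcsRerank(hits, q)
  expect_setequal(rr$monomer_id, hits$monomer_id)
  expect_true(all(!is.na(rr$mcs_similarity)))
  expect_equal(rr$mcs_similarity, sort(rr$mcs_similarity, decreasing = TRUE))
  one <- mcsRerank(hits[1, ], q)
  expect_equal(one$monomer_id, hits$monomer_id[1])
})

test_that("fingerprint and MCS orderings can disagree, and re-ranking flips them", {
  # a linear alkane's subgraph classes are position-free, so decane and
  # cyclododecane both tie the dodecane query at fingerprint similarity
  # 1.0 -- but the ring cannot embed in the chain at all, while decane
  # embeds whole: 10 atoms + 9 bonds common, (10+9)/(23+19-19) = 19/23
  query <- "CCCCCCCCCCCC"     # dodecane
  a <- "C1CCCCCCCCCCC1"       # cyclododecane
  b <- "CCCCCCCCCC"           # decane
  hits <- data.frame(
    smiles = c(a, b), monomer_id = c("MA", "MB"),
    target_name = c("TA", "TB"), uniprot_primary = c("P11111", "P22222"),
    affinity_type = "Ki", affinity_nM = c(1, 1),
    similarity = c(pathSimilarity(query, a), pathSimilarity(query, b)),
    mcs_similarity = NA_real_, stringsAsFactors = FALSE)
  expect_equal(hits$similarity, c(1, 1))
  hits <- hits[order(-hits$similarity, hits$monomer_id), ]
  expect_equal(hits$monomer_id[1], "MA")  # fingerprint ranking (id tie-break)
  rr <- mcsRerank(hits, query)
  expect_equal(rr$monomer_id[1], "MB")    # substructure ranking
  expect_equal(rr$mcs_similarity[1], 19 / 23, tolerance = 1e-12)
  expect_equal(rr$mcs_similarity[2], 0)
})

test_that("the path+mcs variant ranks targets by substructure score", {
  std <- standard_fixture()
  q <- std$fx$manifest$queries$query_smiles[2]
  rep <- predictTargets(q, std$table,
                        queryConfig(variant = "path_then_mcs",
                                    similarity_threshold = 0.5))
  th <- targetHits(rep)
  expect_gte(nrow(th), 1)
  expect_equal(th$best_similarity, sort(th$best_similarity, decreasing = TRUE))
})

test_that("pure MCS scanning works on a compact table", {
  tab <- small_fixture()$table
  q <- small_fixture()$fx$manifest$queries$query_smiles[1]
  rep <- predictTargets(q, tab, queryConfig(variant = "pure_mcs",
                                            similarity_threshold = 0.5))
  th <- targetHits(rep)
  expect_equal(th$uniprot_primary[1],
               small_fixture()$fx$manifest$queries$expected_target[1])
})

test_that("batch rows equal the truncated single-query reports", {
  std <- standard_fixture()
  qs <- stats::setNames(std$fx$manifest$queries$query_smiles,
                        paste0("q", seq_len(nrow(std$fx$manifest$queries))))
  cfg <- queryConfig(similarity_threshold = 0.5)
  batch <- predictTargetsBatch(qs[1:3], std$table, cfg)
  expect_equal(nrow(batch), 3)
  for (i in 1:3) {
    th <- targetHits(predictTargets(qs[i], std$table, cfg))
    for (k in 1:min(3, nrow(th))) {
      expect_equal(batch[[sprintf("uniprot_%d", k)]][i], th$uniprot_primary[k])
      expect_equal(batch[[sprintf("similarity_%d", k)]][i],
                   th$best_similarity[k])
    }
  }
})

test_that("batch fills fewer columns when fewer hits exist and honors top_n", {
  std <- standard_fixture()
  q <- std$fx$manifest$queries$query_smiles[1]
  one_hit <- predictTargetsBatch(c(q1 = q), std$table,
                                 queryConfig(similarity_threshold = 0.9))
  expect_false(is.na(one_hit$target_1))
  expect_true(is.na(one_hit$target_2))
  wide <- predictTargetsBatch(c(q1 = q), std$table,
                              queryConfig(similarity_threshold = 0.3,
                                          top_n_per_compound = 10))
  expect_true("target_10" %in% names(wide))
})

test_that("unparsable batch entries are reported per row; all-bad input errors", {
  std <- standard_fixture()
  q <- std$fx$manifest$queries$query_smiles[1]
  mixed <- predictTargetsBatch(c(ok = q, bad = "C1CC"), std$table,
                               queryConfig())
  expect_true(is.na(mixed$error[1]))
  expect_false(is.na(mixed$error[2]))
  expect_error(predictTargetsBatch(c(bad = "C1CC"), std$table, queryConfig()),
               "no query compound")
})

test_that("reports write fixed-column CSV", {
  std <- standard_fixture()
  rep <- predictTargets(std$fx$manifest$queries$query_smiles[1], std$table,
                        queryConfig(similarity_threshold = 0.5))
  f <- tempfile(fileext = ".csv")
  writeReport(rep, f)
  out <- utils::read.csv(f)
  expect_equal(names(out)[1:3], c("target_name", "uniprot", "best_similarity"))
  expect_equal(nrow(out), nrow(targetHits(rep)))
})
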