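# TSV ingestion, measurement filtering, sanitization and persistence.

write_tsv_lines <- function(rows) {
  d <- defaultDialect()
  header <- paste(c(d$smiles, d$monomer_id, d$target_name, d$uniprot,
                    d$ki, d$ic50), collapse = "\t")
  f <- tempfile(fileext = ".tsv")
  writeLines(c(header, rows), f)
  f
}

test_that("a toy TSV yields one raw row per data line", {
  f <- write_tsv_lines(c(
    "CCO\tM1\tT one\tP12345\t10\t",
    "CCN\tM2\tT one\tP12345\t\t20",
    "CCC\tM3\tT two\tP23456\t5.5\t",
    "CCCC\tM4\tT two\tP23456\t\t1e3"))
  rows <- loadBindingTsv(f)
  expect_equal(nrow(rows), 4)
  expect_equal(rows$affinity_type, c("Ki", "IC50", "Ki", "IC50"))
  expect_equal(rows$affinity_text, c("10", "20", "5.5", "1e3"))
})

test_that("empty SMILES passes through loading untouched (filtered later)", {
  f <- write_tsv_lines("\tM1\tT\tP12345\t10\t")
  rows <- loadBindingTsv(f)
  expect_equal(nrow(rows), 1)
  expect_identical(rows$smiles, "")
})

test_that("a row with both Ki and IC50 becomes two measurement rows", {
  f <- write_tsv_lines("CCO\tM1\tT\tP12345\t10\t200")
  rows <- loadBindingTsv(f)
  expect_equal(nrow(rows), 2)
  expect_setequal(rows$affinity_type, c("Ki", "IC50"))
})

test_that("missing required columns name the column; missing file is an I/O error", {
  f <- tempfile(); writeLines("a\tb\tc", f)
  expect_error(loadBindingTsv(f), "Ligand SMILES")
  expect_error(loadBindingTsv(tempfile()), "cannot read")
})

test_that("generator TSV round-trips its planted fields", {
  fx <- small_fixture()$fx
  rows <- loadBindingTsv(fx$path)
  expect_equal(nrow(rows), nrow(fx$manifest$rows))
  expect_equal(rows$smiles, fx$manifest$rows$smiles)
  expect_equal(rows$monomer_id, fx$manifest$rows$monomer_id)
})

test_that("measurement filter drops qualifiers and non-measurements per the hand count", {
  # 10 toy rows: 3 with '>' qualifiers, 2 without any measurement, 5 clean
  f <- write_tsv_lines(c(
    "CCO\tM01\tT\tP12345\t10\t",
    "CCN\tM02\tT\tP12345\t>50\t",
    "CCC\tM03\tT\tP12345\t\t>100",
    "CCCC\tM04\tT\tP12345\t<0.5\t",
    "CCCCC\tM05\tT\tP12345\t\t",
    "CCCCCC\tM06\tT\tP12345\t\t",
    "CCOC\tM07\tT\tP12345\t1\t",
    "CCNC\tM08\tT\tP12345\t\t2",
    "CCCN\tM09\tT\tP12345\t3\t",
    "CCCO\tM10\tT\tP12345\t\t4"))
  rows <- loadBindingTsv(f)
  expect_equal(nrow(rows), 10)
  kept <- filterMeasurements(rows)
  expect_equal(nrow(kept), 5)
  expect_setequal(kept$monomer_id, c("M01", "M07", "M08", "M09", "M10"))
  drops <- attr(kept, "drop_counts")
  expect_equal(unname(drops["qualifier"]), 3)
  expect_equal(unname(drops["no_measurement"]), 2)
})

test_that("the filter is a pure idempotent filter", {
  rows <- loadBindingTsv(standard_fixture()$fx$path)
  once <- filterMeasurements(rows)
  twice <- filterMeasurements(once)
  expect_equal(nrow(once), nrow(twice))
  expect_equal(once$monomer_id, twice$monomer_id)
  empty <- filterMeasurements(rows[0, ])
  expect_equal(nrow(empty), 0)
})

test_that("affinity parsing accepts '=' and scientific notation, rejects junk", {
  parse <- fmct:::.parseAffinity
  expect_equal(parse(" =12.5 "), 12.5)
  expect_equal(parse("1e3"), 1000)
  expect_true(is.na(parse("-5")))
  expect_true(is.na(parse("0")))
  expect_true(is.na(parse("NaN")))
  expect_true(is.na(parse("abc")))
})

test_that("sanitization drops invalid structures, keeps count, fingerprints survivors", {
  rows <- data.frame(
    smiles = c("C1CC1", "C1CC", "CCO", "%%%", "c1ccccc1"),
    monomer_id = sprintf("M%d", 1:5), target_name = "T",
    uniprot_ids = "P12345", affinity_type = "Ki",
    affinity_text = "10", stringsAsFactors = FALSE)
  san <- sanitizeAndFingerprint(rows, families = "path")
  expect_equal(nrow(san$records), 3)
  expect_equal(san$n_failed, 2)
  expect_true(all(rowSums(san$fingerprints$path) > 0))
  expect_equal(san$records$affinity_nM, rep(10, 3))
  # retained affinity equals the numeric parse of its verbatim text
  expect_equal(san$records$affinity_nM,
               fmct:::.parseAffinity(san$records$affinity_text))
})

test_that("unknown fingerprint families are configuration errors listing valid ids", {
  rows <- data.frame(smiles = "CCO", monomer_id = "M1", target_name = "T",
                     uniprot_ids = "P12345", affinity_type = "Ki",
                     affinity_text = "1", stringsAsFactors = FALSE)
  expect_error(sanitizeAndFingerprint(rows, families = "nope"),
               "unknown fingerprint family")
  expect_error(sanitizeAndFingerprint(rows, families = "avalon"),
               "not available")
})

test_that("the full build composes the stages with monotone counts", {
  std <- standard_fixture()
  tab <- std$table
  sc <- unlist(buildMeta(tab)$stage_counts)
  exp <- std$fx$manifest$expected
  expect_equal(unname(sc), c(exp$n_raw, exp$n_after_measurement_filter,
                             exp$n_after_sanitize))
  expect_true(all(diff(sc) <= 0))
  expect_equal(nRecords(tab), exp$n_after_sanitize)
})

test_that("the fast build carries only the path family", {
  tab <- small_fixture()$table
  expect_equal(names(fingerprints(tab)), "path")
})

test_that("save/load is the identity, fingerprints bit-exact", {
  tab <- standard_fixture()$table
  f <- tempfile(fileext = ".table")
  writeReferenceTable(tab, f)
  tab2 <- readReferenceTable(f)
  expect_identical(records(tab2), records(tab))
  expect_identical(fingerprints(tab2), fingerprints(tab))
  expect_equal(buildMeta(tab2)$stage_counts, buildMeta(tab)$stage_counts)
  # popcounts unchanged record-by-record
  for (fam in names(fingerprints(tab)))
    expect_equal(rowSums(fingerprints(tab2)[[fam]]),
                 rowSums(fingerprints(tab)[[fam]]))
})

test_that("corrupt or alien files fail loudly, never partially", {
  tab <- small_fixture()$table
  f <- tempfile(); writeReferenceTable(tab, f)
  lines <- readLines(f)
  trunc <- tempfile(); writeLines(lines[1:(length(lines) - 2)], trunc)
  expect_error(readReferenceTable(trunc), "truncated")
  alien <- tempfile(); writeLines(c("not a table", "x"), alien)
  expect_error(readReferenceTable(alien), "magic")
  versioned <- tempfile()
  writeLines(c(sub("\t1$", "\t99", lines[1]), lines[-1]), versioned)
  expect_error(readReferenceTable(versioned), "version")
})

test_that("dialect overrides map alternative headers", {
  f <- tempfile(fileext = ".tsv")
  writeLines(c("SMI\tID\tTGT\tUP\tKI\tIC",
               "CCO\tM1\tT\tP12345\t10\t"), f)
  dj <- tempfile(fileext = ".json")
  jsonlite::write_json(list(smiles = "SMI", monomer_id = "ID",
                            target_name = "TGT", uniprot = "UP",
                            ki = "KI", ic50 = "IC"), dj, auto_unbox = TRUE)
  rows <- loadBindingTsv(f, readDialect(dj))
  expect_equal(rows$smiles, "CCO")
  bad <- tempfile(); jsonlite::write_json(list(bogus = "x"), bad,
                                          auto_unbox = TRUE)
  expect_error(readDialect(bad), "unknown dialect field")
})
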