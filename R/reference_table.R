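# Reference-table construction: TSV ingestion, measurement filtering,
# sanitization + fingerprinting, and persistence.

#' Column dialect for bioactivity TSV dumps
#'
#' Column headers of the public BindingDB full-download TSV drift across
#' releases, so logical fields are mapped to header names through a
#' dialect. The default matches the current public dump; a JSON file with
#' the same keys overrides it.
#'
#' @return named list mapping logical field -> header name
#' @export
defaultDialect <- function() {
  list(smiles = "Ligand SMILES",
       monomer_id = "BindingDB MonomerID",
       target_name = "Target Name",
       uniprot = "UniProt (SwissProt) Primary ID of Target Chain",
       ki = "Ki (nM)",
       ic50 = "IC50 (nM)")
}

#' @param path JSON file with dialect overrides
#' @rdname defaultDialect
#' @export
readDialect <- function(path) {
  d <- defaultDialect()
  o <- jsonlite::read_json(path, simplifyVector = TRUE)
  unknown <- setdiff(names(o), names(d))
  if (length(unknown))
    stop(sprintf("unknown dialect field(s): %s", paste(unknown, collapse = ", ")),
         call. = FALSE)
  utils::modifyList(d, as.list(o))
}

#' Read a bioactivity TSV into raw measurement rows
#'
#' One output row per populated measurement (a line carrying both a Ki
#' and an IC50 value yields two rows; a line carrying neither yields one
#' row with affinity_type "none" so later stages can count it). Affinity
#' text is preserved verbatim. Malformed lines (wrong field count) are
#' counted and skipped, not fatal.
#'
#' @param path TSV file (UTF-8, one header row)
#' @param dialect column dialect, see \code{\link{defaultDialect}}
#' @return data.frame of raw rows with attributes "n_lines" and
#'   "n_malformed"
#' @export
loadBindingTsv <- function(path, dialect = defaultDialect()) {
  if (!file.exists(path)) stop(sprintf("cannot read '%s'", path), call. = FALSE)
  lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
  if (length(lines) == 0) stop("empty file: no header row", call. = FALSE)
  header <- strsplit(lines[1], "\t", fixed = TRUE)[[1]]
  col <- function(field) {
    i <- match(dialect[[field]], header)
    if (is.na(i))
      stop(sprintf("required column '%s' (field '%s') missing from header",
                   dialect[[field]], field), call. = FALSE)
    i
  }
  idx <- vapply(c("smiles", "monomer_id", "target_name", "uniprot",
                  "ki", "ic50"), col, integer(1))
  body <- lines[-1]
  body <- body[nzchar(body)]
  fields <- strsplit(body, "\t", fixed = TRUE)
  nf <- lengths(fields)
  # trailing empty fields are dropped by the splitter: pad them back;
  # lines with MORE fields than the header are malformed
  ok <- nf <= length(header)
  n_malformed <- sum(!ok)
  fields <- lapply(fields[ok], function(f)
    c(f, character(length(header) - length(f))))
  get <- function(f, i) if (i <= length(f)) f[[i]] else ""
  rows <- lapply(fields, function(f) {
    ki <- get(f, idx["ki"]); ic50 <- get(f, idx["ic50"])
    base <- list(smiles = get(f, idx["smiles"]),
                 monomer_id = get(f, idx["monomer_id"]),
                 target_name = get(f, idx["target_name"]),
                 uniprot_ids = get(f, idx["uniprot"]))
    out <- list()
    if (nzchar(trimws(ki)))
      out <- c(out, list(c(base, affinity_type = "Ki", affinity_text = ki)))
    if (nzchar(trimws(ic50)))
      out <- c(out, list(c(base, affinity_type = "IC50", affinity_text = ic50)))
    if (!length(out))
      out <- list(c(base, affinity_type = "none", affinity_text = ""))
    out
  })
  rows <- unlist(rows, recursive = FALSE)
  df <- do.call(rbind, lapply(rows, function(r)
    as.data.frame(r, stringsAsFactors = FALSE)))
  if (is.null(df))
    df <- data.frame(smiles = character(), monomer_id = character(),
                     target_name = character(), uniprot_ids = character(),
                     affinity_type = character(), affinity_text = character(),
                     stringsAsFactors = FALSE)
  rownames(df) <- NULL
  attr(df, "n_lines") <- length(body)
  attr(df, "n_malformed") <- n_malformed
  df
}

# parse an affinity field: optional '=' prefix, scientific notation and
# surrounding whitespace accepted; anything else (including range
# qualifiers) yields NA
.parseAffinity <- function(text) {
  t <- trimws(text)
  t <- sub("^=", "", t)
  suppressWarnings(v <- as.numeric(t))
  v[!is.finite(v) | v <= 0] <- NA_real_
  v
}

.hasQualifier <- function(text) grepl("[<>]", text)

#' Filter raw rows to clean Ki / IC50 measurements
#'
#' Keeps rows whose affinity type is Ki or IC50 and whose affinity text
#' parses as a plain positive number; any occurrence of '<' or '>'
#' anywhere in the affinity field marks a range measurement and drops the
#' row. A pure filter: idempotent, never errors.
#'
#' @param rows data.frame from \code{\link{loadBindingTsv}}
#' @return filtered data.frame with attribute "drop_counts"
#' @export
filterMeasurements <- function(rows) {
  if (nrow(rows) == 0) {
    attr(rows, "drop_counts") <- c(no_measurement = 0L, qualifier = 0L,
                                   unparsable = 0L)
    return(rows)
  }
  is_meas <- rows$affinity_type %in% c("Ki", "IC50")
  has_qual <- .hasQualifier(rows$affinity_text)
  parses <- !is.na(.parseAffinity(rows$affinity_text))
  keep <- is_meas & !has_qual & parses
  out <- rows[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "drop_counts") <- c(
    no_measurement = sum(!is_meas),
    qualifier = sum(is_meas & has_qual),
    unparsable = sum(is_meas & !has_qual & !parses))
  out
}

#' Sanitize structures and attach fingerprints
#'
#' Rows whose SMILES fails parsing/sanitization (or fingerprint
#' generation) are dropped and counted; survivors become curated binding
#' records carrying a canonical SMILES, a numeric affinity in nM, and one
#' fingerprint per requested family.
#'
#' @param rows measurement-filtered rows
#' @param families fingerprint families to attach
#' @return list(records = data.frame, fingerprints = list of matrices,
#'   n_failed = count of dropped rows)
#' @export
sanitizeAndFingerprint <- function(rows, families = availableFamilies()) {
  .checkFamilies(families)
  mols <- .parseBatch(rows$smiles)
  ok <- !vapply(mols, is.null, logical(1))
  recs <- rows[ok, , drop = FALSE]
  rownames(recs) <- NULL
  n_failed <- sum(!ok)
  can <- canonicalSmiles(recs$smiles)
  bad_canon <- is.na(can)
  if (any(bad_canon)) {   # parsed but refused canonicalization: drop too
    n_failed <- n_failed + sum(bad_canon)
    recs <- recs[!bad_canon, , drop = FALSE]
    can <- can[!bad_canon]
    mols <- mols[ok][!bad_canon]
  } else mols <- mols[ok]
  uni <- trimws(recs$uniprot_ids)
  primary <- vapply(strsplit(uni, "[;,]"), function(x) {
    x <- trimws(x); x <- x[nzchar(x)]
    if (length(x)) x[1] else NA_character_
  }, character(1))
  records <- data.frame(
    smiles = recs$smiles,
    smiles_canonical = can,
    monomer_id = recs$monomer_id,
    target_name = recs$target_name,
    uniprot_primary = primary,
    uniprot_ids = recs$uniprot_ids,
    affinity_type = recs$affinity_type,
    affinity_nM = .parseAffinity(recs$affinity_text),
    affinity_text = recs$affinity_text,
    stringsAsFactors = FALSE)
  fps <- if (nrow(records))
    computeFingerprints(records$smiles, families, mols = mols)
  else stats::setNames(
    lapply(families, function(f) matrix(FALSE, 0, .familyNbits(f))), families)
  list(records = records, fingerprints = fps, n_failed = n_failed)
}

#' Build a curated reference table from a bioactivity TSV
#'
#' The full curation pipeline: read the TSV, keep clean Ki/IC50
#' measurements, drop unsanitizable structures, attach fingerprints.
#' Per-stage row counts are logged to stderr and recorded in the build
#' metadata. \code{families = "path"} gives the fast build (path
#' fingerprint only).
#'
#' @param path TSV file
#' @param dialect column dialect
#' @param families fingerprint families to attach
#' @param verbose log stage counts to stderr
#' @return a \code{\linkS4class{ReferenceTable}}
#' @export
buildReferenceTable <- function(path, dialect = defaultDialect(),
                                families = availableFamilies(),
                                verbose = TRUE) {
  raw <- loadBindingTsv(path, dialect)
  filt <- filterMeasurements(raw)
  san <- sanitizeAndFingerprint(filt, families)
  meta <- list(
    source = path,
    format_version = 1L,
    stage_counts = list(raw = nrow(raw), measurement_filtered = nrow(filt),
                        sanitized = nrow(san$records)),
    drop_counts = c(as.list(attr(filt, "drop_counts")),
                    list(malformed_lines = attr(raw, "n_malformed"),
                         sanitize_failed = san$n_failed)),
    families = families,
    built = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"),
    toolkit = c(fmct = as.character(utils::packageVersion("fmct")),
                ChemmineOB = as.character(utils::packageVersion("ChemmineOB"))))
  if (verbose)
    message(sprintf("reference table: %d raw -> %d measurement-filtered -> %d sanitized",
                    nrow(raw), nrow(filt), nrow(san$records)))
  new("ReferenceTable", records = san$records, fingerprints = san$fingerprints,
      buildMeta = meta)
}

# ---------------------------------------------------------------------------
# persistence: versioned plain-text format. Line 1: magic + format
# version; line 2: JSON metadata (including the record count, so
# truncation is detectable); then a TSV with fingerprints as fixed-width
# hex strings.

.bitsToHex <- function(bits) {
  paste(format(as.hexmode(as.integer(packBits(as.logical(bits), "raw")))),
        collapse = "")
}

.hexToBits <- function(hex) {
  raw <- as.raw(strtoi(substring(hex, seq(1, nchar(hex), 2),
                                 seq(2, nchar(hex), 2)), 16L))
  as.logical(rawToBits(raw))
}

#' Save / load a reference table
#'
#' A versioned plain-text columnar format: a magic+version line, a JSON
#' metadata line, then tab-separated records with fingerprints as hex
#' bitstrings of declared length. The round trip is the identity,
#' bit-exact on fingerprints.
#'
#' @param table a \code{ReferenceTable}
#' @param path file path
#' @export
writeReferenceTable <- function(table, path) {
  stopifnot(is(table, "ReferenceTable"))
  recs <- table@records
  meta <- table@buildMeta
  meta$n_records <- nrow(recs)
  meta$fingerprint_nbits <- lapply(table@fingerprints, ncol)
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines("#fmct-reference-table\t1", con)
  writeLines(as.character(jsonlite::toJSON(meta, auto_unbox = TRUE, digits = NA,
                                           null = "null")), con)
  out <- recs
  out$affinity_nM <- sprintf("%.17g", recs$affinity_nM)
  for (fam in names(table@fingerprints)) {
    m <- table@fingerprints[[fam]]
    out[[paste0("fp_", fam)]] <- vapply(seq_len(nrow(m)), function(i)
      .bitsToHex(m[i, ]), character(1))
  }
  writeLines(paste(names(out), collapse = "\t"), con)
  if (nrow(out))
    writeLines(do.call(paste, c(lapply(out, as.character), sep = "\t")), con)
  invisible(path)
}

#' @rdname writeReferenceTable
#' @export
readReferenceTable <- function(path) {
  lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
  if (length(lines) < 3 || !startsWith(lines[1], "#fmct-reference-table"))
    stop("not a reference-table file (missing magic line)", call. = FALSE)
  ver <- strsplit(lines[1], "\t", fixed = TRUE)[[1]][2]
  if (!identical(ver, "1"))
    stop(sprintf("unsupported reference-table format version '%s'", ver),
         call. = FALSE)
  meta <- jsonlite::fromJSON(lines[2], simplifyVector = TRUE)
  header <- strsplit(lines[3], "\t", fixed = TRUE)[[1]]
  body <- lines[-(1:3)]
  body <- body[nzchar(body)]
  if (length(body) != meta$n_records)
    stop(sprintf("truncated or corrupt table: %d records expected, %d found",
                 meta$n_records, length(body)), call. = FALSE)
  fields <- strsplit(body, "\t", fixed = TRUE)
  if (length(fields) && any(lengths(fields) != length(header)))
    stop("truncated or corrupt table: ragged record lines", call. = FALSE)
  df <- as.data.frame(do.call(rbind, fields), stringsAsFactors = FALSE)
  if (nrow(df) == 0)
    df <- as.data.frame(matrix(character(), 0, length(header)),
                        stringsAsFactors = FALSE)
  names(df) <- header
  fp_cols <- grep("^fp_", header, value = TRUE)
  fps <- list()
  for (colname in fp_cols) {
    fam <- sub("^fp_", "", colname)
    nbits <- meta$fingerprint_nbits[[fam]]
    m <- matrix(FALSE, nrow(df), nbits)
    for (i in seq_len(nrow(df))) m[i, ] <- .hexToBits(df[[colname]][i])
    fps[[fam]] <- m
    df[[colname]] <- NULL
  }
  df$affinity_nM <- as.numeric(df$affinity_nM)
  meta$n_records <- NULL
  meta$fingerprint_nbits <- NULL
  # JSON round trip flattens some list structure; restore names
  meta$stage_counts <- as.list(meta$stage_counts)
  new("ReferenceTable", records = df, fingerprints = fps,
      buildMeta = meta)
}
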