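# Thin client for the BindingDB-style RESTful endpoints. All network
# traffic goes through a pluggable transport function so the test suite
# runs entirely against canned XML fixtures; the XML element names are
# mapped through a dialect, mirroring the TSV dialect approach, because
# the service schema is versioned independently of this package.

.UNIPROT_RE <- "^[A-NR-Z][0-9][A-Z0-9]{3}[0-9]$|^[OPQ][0-9][A-Z0-9]{3}[0-9]$"

#' XML element dialect for the web service responses
#'
#' @return named list mapping logical field -> XML element local-name
#' @export
defaultXmlDialect <- function() {
  list(hit = "affinities",
       monomer_id = "monomerid",
       smiles = "smiles",
       target_name = "target",
       uniprot = "uniprot",
       affinity_type = "affinity_type",
       affinity = "affinity",
       similarity = "similarity")
}

#' Construct a web-service query
#'
#' Exactly one of \code{uniprot} / \code{smiles} must be set, matching
#' the endpoint: ligands-by-UniProt takes an accession,
#' targets-by-compound takes a SMILES.
#'
#' @param endpoint "ligands_by_uniprot" or "targets_by_compound"
#' @param uniprot UniProt primary accession (regex-checked)
#' @param smiles query compound SMILES (parsed locally before dispatch)
#' @param similarity_cutoff chemical similarity cutoff on the 0-1 scale;
#'   1.0 (the default) means exact-structure search
#' @param affinity_cutoff_nM maximum affinity in nM, default 10000
#' @return query list
#' @export
serviceQuery <- function(endpoint = c("ligands_by_uniprot",
                                      "targets_by_compound"),
                         uniprot = NULL, smiles = NULL,
                         similarity_cutoff = 1.0,
                         affinity_cutoff_nM = 10000) {
  endpoint <- match.arg(endpoint)
  if (sum(!is.null(uniprot), !is.null(smiles)) != 1L)
    stop("exactly one of 'uniprot' or 'smiles' must be given", call. = FALSE)
  if (endpoint == "ligands_by_uniprot") {
    if (is.null(uniprot)) stop("ligands_by_uniprot needs a UniProt accession",
                               call. = FALSE)
    if (!grepl(.UNIPROT_RE, uniprot))
      stop(sprintf("'%s' is not a syntactically valid UniProt accession",
                   uniprot), call. = FALSE)
  } else {
    if (is.null(smiles)) stop("targets_by_compound needs a SMILES", call. = FALSE)
    molFromSmiles(smiles)  # validate locally before dispatch
  }
  stopifnot(similarity_cutoff >= 0, similarity_cutoff <= 1,
            affinity_cutoff_nM > 0)
  list(endpoint = endpoint, uniprot = uniprot, smiles = smiles,
       similarity_cutoff = similarity_cutoff,
       affinity_cutoff_nM = affinity_cutoff_nM)
}

#' HTTP transport with timeout and retries
#'
#' Returns a function(url) -> character XML payload. The default
#' transport reads over HTTP(S) with a timeout and retry-with-backoff
#' policy; tests substitute \code{fileTransport} or
#' \code{literalTransport} so no network is touched.
#'
#' @param timeout seconds per attempt
#' @param retries additional attempts after the first failure
#' @param backoff seconds between attempts (doubled each retry)
#' @export
httpTransport <- function(timeout = 30, retries = 2, backoff = 1) {
  force(timeout); force(retries); force(backoff)
  function(url) {
    attempt <- 0
    repeat {
      out <- tryCatch({
        old <- options(timeout = timeout); on.exit(options(old), add = TRUE)
        paste(readLines(url, warn = FALSE), collapse = "\n")
      }, error = function(e) e)
      if (!inherits(out, "error")) return(out)
      attempt <- attempt + 1
      if (attempt > retries)
        stop(sprintf("transport failure after %d attempt(s): %s",
                     attempt, conditionMessage(out)), call. = FALSE)
      Sys.sleep(backoff * 2^(attempt - 1))
    }
  }
}

#' @param path XML file served in place of the network
#' @rdname httpTransport
#' @export
fileTransport <- function(path) {
  force(path)
  function(url) paste(readLines(path, warn = FALSE), collapse = "\n")
}

#' @param text literal XML payload
#' @rdname httpTransport
#' @export
literalTransport <- function(text) {
  force(text)
  function(url) text
}

.serviceUrl <- function(query,
                        base = "https://bindingdb.org/axis2/services/BDBService") {
  if (query$endpoint == "ligands_by_uniprot")
    sprintf("%s/getLigandsByUniprot?uniprot=%s", base, query$uniprot)
  else
    sprintf("%s/getTargetByCompound?smiles=%s&cutoff=%s", base,
            utils::URLencode(canonicalSmiles(query$smiles), reserved = TRUE),
            format(query$similarity_cutoff))
}

# parse a service response into raw measurement rows (same shape the TSV
# loader emits, so one validation path covers both sources)
.parseServiceXml <- function(xml_text, dialect = defaultXmlDialect()) {
  doc <- tryCatch(xml2::read_xml(xml_text), error = function(e) e)
  if (inherits(doc, "error")) {
    excerpt <- substr(gsub("\\s+", " ", xml_text), 1, 120)
    stop(sprintf("malformed XML response: %s [payload: %s]",
                 conditionMessage(doc), excerpt), call. = FALSE)
  }
  hits <- xml2::xml_find_all(doc, sprintf("//*[local-name()='%s']", dialect$hit))
  field <- function(hit, name) {
    node <- xml2::xml_find_first(hit, sprintf(".//*[local-name()='%s']",
                                              dialect[[name]]))
    if (inherits(node, "xml_missing")) "" else xml2::xml_text(node)
  }
  df <- do.call(rbind, lapply(hits, function(h) data.frame(
    smiles = field(h, "smiles"),
    monomer_id = field(h, "monomer_id"),
    target_name = field(h, "target_name"),
    uniprot_ids = field(h, "uniprot"),
    affinity_type = field(h, "affinity_type"),
    affinity_text = field(h, "affinity"),
    similarity = field(h, "similarity"),
    stringsAsFactors = FALSE)))
  if (is.null(df))
    df <- data.frame(smiles = character(), monomer_id = character(),
                     target_name = character(), uniprot_ids = character(),
                     affinity_type = character(), affinity_text = character(),
                     similarity = character(), stringsAsFactors = FALSE)
  df
}

.serviceRecords <- function(query, transport, dialect) {
  xml_text <- transport(.serviceUrl(query))
  rows <- .parseServiceXml(xml_text, dialect)
  # normalize affinity type spellings ("KI" -> "Ki")
  rows$affinity_type <- ifelse(toupper(rows$affinity_type) == "KI", "Ki",
                               ifelse(toupper(rows$affinity_type) == "IC50",
                                      "IC50", rows$affinity_type))
  filt <- filterMeasurements(rows[names(rows) != "similarity"])
  filt$similarity <- suppressWarnings(
    as.numeric(rows$similarity[match(filt$monomer_id, rows$monomer_id)]))
  keep <- .parseAffinity(filt$affinity_text) <= query$affinity_cutoff_nM
  out <- filt[keep, , drop = FALSE]
  out$affinity_nM <- .parseAffinity(out$affinity_text)
  rownames(out) <- NULL
  out
}

#' Retrieve known ligands of a protein target
#'
#' Queries the ligands-by-UniProt endpoint and returns curated
#' measurement rows (same schema as the TSV path, so the records feed
#' directly into \code{\link{sanitizeAndFingerprint}}).
#'
#' @param query a \code{\link{serviceQuery}} with endpoint
#'   "ligands_by_uniprot"
#' @param transport transport function (default: live HTTP)
#' @param dialect XML element dialect
#' @return data.frame of measurement rows within the affinity cutoff
#' @export
getLigandsByUniprot <- function(query, transport = httpTransport(),
                                dialect = defaultXmlDialect()) {
  stopifnot(identical(query$endpoint, "ligands_by_uniprot"))
  .serviceRecords(query, transport, dialect)
}

#' Retrieve known protein targets of a compound
#'
#' Queries the targets-by-compound endpoint. With the default similarity
#' cutoff of 1.0 every returned record refers to the exact structure
#' (similarity = 1). The query SMILES is canonicalized for the URL but
#' never otherwise modified.
#'
#' @param query a \code{\link{serviceQuery}} with endpoint
#'   "targets_by_compound"
#' @param transport transport function
#' @param dialect XML element dialect
#' @return data.frame of measurement rows with target names, affinity
#'   data and the reported match similarity
#' @export
getTargetsByCompound <- function(query, transport = httpTransport(),
                                 dialect = defaultXmlDialect()) {
  stopifnot(identical(query$endpoint, "targets_by_compound"))
  .serviceRecords(query, transport, dialect)
}
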