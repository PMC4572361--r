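#' @import methods
NULL

#' BitFingerprint: a fixed-length binary chemical fingerprint
#'
#' Two fingerprints are comparable only when they come from the same
#' family and have equal length.
#'
#' @slot family fingerprint family identifier
#' @slot bits logical vector
#' @export
setClass("BitFingerprint",
         representation(family = "character", bits = "logical"),
         validity = function(object) {
           if (length(object@family) != 1L) return("family must be length 1")
           if (anyNA(object@bits)) return("bits must not contain NA")
           TRUE
         })

#' @param family family id
#' @param bits logical vector
#' @rdname BitFingerprint-class
#' @export
bitFingerprint <- function(bits, family = "path")
  new("BitFingerprint", family = family, bits = as.logical(bits))

#' @export
setMethod("show", "BitFingerprint", function(object) {
  cat(sprintf("BitFingerprint<%s>: %d bits, popcount %d\n",
              object@family, length(object@bits), sum(object@bits)))
})

#' ReferenceTable: a curated, fingerprint-annotated bioactivity table
#'
#' The local stand-in for a BindingDB snapshot: one affinity measurement
#' per record, with per-family fingerprint matrices aligned row-wise to
#' the records, plus build metadata (per-stage filter counts).
#'
#' @slot records data.frame, one curated measurement per row
#' @slot fingerprints named list of logical matrices (rows = records)
#' @slot buildMeta list of build provenance: stage counts, families, source
#' @export
setClass("ReferenceTable",
         representation(records = "data.frame", fingerprints = "list",
                        buildMeta = "list"),
         validity = function(object) {
           n <- nrow(object@records)
           for (fam in names(object@fingerprints)) {
             m <- object@fingerprints[[fam]]
             if (!is.matrix(m) || nrow(m) != n)
               return(sprintf("fingerprint matrix '%s' does not align with records", fam))
           }
           sc <- object@buildMeta$stage_counts
           if (!is.null(sc) && is.unsorted(rev(unlist(sc))))
             return("stage counts must be non-increasing")
           if (n > 0) {
             if (any(!object@records$affinity_type %in% c("Ki", "IC50")))
               return("affinity_type must be Ki or IC50")
             aff <- object@records$affinity_nM
             if (any(!is.finite(aff)) || any(aff <= 0))
               return("affinity_nM must be positive and finite")
           }
           TRUE
         })

#' @export
setMethod("show", "ReferenceTable", function(object) {
  cat(sprintf("ReferenceTable: %d records, %d target(s)\n",
              nrow(object@records),
              length(unique(object@records$uniprot_primary))))
  cat("  fingerprint families:",
      paste(names(object@fingerprints), collapse = ", "), "\n")
  sc <- object@buildMeta$stage_counts
  if (!is.null(sc))
    cat("  stage counts:", paste(unlist(sc), collapse = " -> "), "\n")
})

#' @param object,x a ReferenceTable
#' @rdname ReferenceTable-class
#' @export
setGeneric("records", function(x) standardGeneric("records"))
#' @rdname ReferenceTable-class
#' @export
setMethod("records", "ReferenceTable", function(x) x@records)

#' @rdname ReferenceTable-class
#' @export
setGeneric("buildMeta", function(x) standardGeneric("buildMeta"))
#' @rdname ReferenceTable-class
#' @export
setMethod("buildMeta", "ReferenceTable", function(x) x@buildMeta)

#' @rdname ReferenceTable-class
#' @export
setGeneric("fingerprints", function(x) standardGeneric("fingerprints"))
#' @rdname ReferenceTable-class
#' @export
setMethod("fingerprints", "ReferenceTable", function(x) x@fingerprints)

#' @rdname ReferenceTable-class
#' @export
setGeneric("nRecords", function(x) standardGeneric("nRecords"))
#' @rdname ReferenceTable-class
#' @export
setMethod("nRecords", "ReferenceTable", function(x) nrow(x@records))

#' MetricCatalog: the fingerprint-family x comparison-formula enumeration
#'
#' @slot families data.frame of fingerprint families (see
#'   \code{\link{fingerprintFamilies}})
#' @slot formulas the bit-vector comparison formulas
#' @slot metrics data.frame: full cross product with availability flags
#' @export
setClass("MetricCatalog",
         representation(families = "data.frame", formulas = "character",
                        metrics = "data.frame"),
         validity = function(object) {
           if (nrow(object@metrics) !=
               nrow(object@families) * length(object@formulas))
             return("metrics must be the families x formulas cross product")
           TRUE
         })

#' @export
setMethod("show", "MetricCatalog", function(object) {
  cat(sprintf("MetricCatalog: %d families x %d formulas = %d metrics (%d available)\n",
              nrow(object@families), length(object@formulas),
              nrow(object@metrics), sum(object@metrics$available)))
})

#' MetricSelection: least-redundant similarity metrics
#'
#' Result of the correlation filter: the k retained metrics, the Pearson
#' correlation matrix over the calibration pair panel, and a description
#' of the panel itself.
#'
#' @slot selected data.frame of retained metrics (family_id, formula)
#' @slot correlation symmetric Pearson correlation matrix over all
#'   candidate metrics
#' @slot panel list describing the compound-pair panel used
#' @export
setClass("MetricSelection",
         representation(selected = "data.frame", correlation = "matrix",
                        panel = "list"),
         validity = function(object) {
           cm <- object@correlation
           if (nrow(cm) != ncol(cm)) return("correlation matrix must be square")
           if (nrow(cm) > 0 && max(abs(cm - t(cm))) > 1e-8)
             return("correlation matrix must be symmetric")
           TRUE
         })

#' @export
setMethod("show", "MetricSelection", function(object) {
  cat(sprintf("MetricSelection: %d of %d metrics retained\n",
              nrow(object@selected), nrow(object@correlation)))
  print(object@selected, row.names = FALSE)
})

#' @param x a MetricSelection
#' @rdname MetricSelection-class
#' @export
setGeneric("selectedMetrics", function(x) standardGeneric("selectedMetrics"))
#' @rdname MetricSelection-class
#' @export
setMethod("selectedMetrics", "MetricSelection", function(x) x@selected)

#' McsResult: a maximum-common-substructure comparison
#'
#' @slot nMcs heavy-atom count of the maximum common substructure
#' @slot nBonds bond count of the maximum common substructure
#' @slot nA,nB heavy-atom counts of the two molecules
#' @slot nBondsA,nBondsB bond counts of the two molecules
#' @slot similarity similarity on the 0-1 scale under \code{normalization}
#' @slot normalization one of "atoms_bonds", "atoms", "min_atoms"
#' @slot timedOut TRUE when the search exhausted its budget (value is
#'   then a lower bound, not an error)
#' @export
setClass("McsResult",
         representation(nMcs = "integer", nBonds = "integer",
                        nA = "integer", nB = "integer",
                        nBondsA = "integer", nBondsB = "integer",
                        similarity = "numeric", normalization = "character",
                        timedOut = "logical"),
         validity = function(object) {
           if (object@nMcs > min(object@nA, object@nB))
             return("nMcs cannot exceed the smaller molecule")
           if (object@similarity < 0 || object@similarity > 1 + 1e-12)
             return("similarity must lie in [0,1]")
           TRUE
         })

#' @export
setMethod("show", "McsResult", function(object) {
  cat(sprintf("McsResult: %d atoms / %d bonds common (molecules %d/%d atoms); similarity %.4f [%s]%s\n",
              object@nMcs, object@nBonds, object@nA, object@nB,
              object@similarity, object@normalization,
              if (object@timedOut) " (budget exhausted; best-so-far)" else ""))
})

#' PredictionReport: ranked target hypotheses for one query compound
#'
#' @slot query input SMILES
#' @slot canonical canonical form of the query
#' @slot config the query configuration used
#' @slot targetHits data.frame of merged target hits, best first
#' @slot supporting list of data.frames of supporting compound hits,
#'   parallel to \code{targetHits}
#' @slot similarityRange c(max, min) similarity over all reported hits
#' @export
setClass("PredictionReport",
         representation(query = "character", canonical = "character",
                        config = "list", targetHits = "data.frame",
                        supporting = "list", similarityRange = "numeric"))

#' @export
setMethod("show", "PredictionReport", function(object) {
  n <- nrow(object@targetHits)
  cat(sprintf("PredictionReport for %s (%s variant)\n", object@query,
              object@config$variant))
  if (n == 0) {
    cat("  no targets found above threshold",
        object@config$similarity_threshold,
        "- consider lowering the similarity threshold\n")
  } else {
    cat(sprintf("  %d target(s); similarity range %.3f-%.3f\n", n,
                object@similarityRange[1], object@similarityRange[2]))
    print(utils::head(object@targetHits, 10), row.names = FALSE)
  }
})

#' @param x a PredictionReport
#' @rdname PredictionReport-class
#' @export
setGeneric("targetHits", function(x) standardGeneric("targetHits"))
#' @rdname PredictionReport-class
#' @export
setMethod("targetHits", "PredictionReport", function(x) x@targetHits)

#' @rdname PredictionReport-class
#' @export
setGeneric("supportingHits", function(x) standardGeneric("supportingHits"))
#' @rdname PredictionReport-class
#' @export
setMethod("supportingHits", "PredictionReport", function(x) x@supporting)

#' ClusterSet: per-target compound clusters and their representatives
#'
#' @slot key the target grouping key (UniProt accession, or flagged
#'   target-name fallback)
#' @slot clusters list of integer vectors: record indices per cluster
#'   (indices into the parent table)
#' @slot representatives integer vector of chosen representative indices
#' @export
setClass("ClusterSet",
         representation(key = "character", clusters = "list",
                        representatives = "integer"),
         validity = function(object) {
           all_idx <- unlist(object@clusters)
           if (anyDuplicated(all_idx))
             return("clusters must partition the group")
           if (!all(object@representatives %in% all_idx))
             return("representatives must be members of their clusters")
           TRUE
         })

#' @export
setMethod("show", "ClusterSet", function(object) {
  cat(sprintf("ClusterSet[%s]: %d records in %d cluster(s), %d representative(s)\n",
              object@key, length(unlist(object@clusters)),
              length(object@clusters), length(object@representatives)))
})
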