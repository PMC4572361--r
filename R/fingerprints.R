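# Fingerprint family registry and batch computation.
#
# The canonical catalog enumerates the 14 binary fingerprint families of
# the two KNIME cheminformatics toolkits; this toolchain implements seven
# of them (three in-package, four via OpenBabel/ChemmineR) and registers
# the remainder as unavailable, so the 3 x 14 metric enumeration stays
# intact while live computation uses 3 x N.

.FP_FAMILIES <- data.frame(
  family_id = c("standard", "extended", "estate", "pubchem", "maccs",
                "morgan", "feat_morgan", "atom_pair", "torsion", "path",
                "avalon", "layered", "pattern", "maccs_keys"),
  provider  = c("openbabel", NA, NA, NA, "openbabel",
                "fmct", NA, "chemminer", "fmct", "fmct",
                NA, NA, "openbabel", NA),
  nbits     = c(1024L, NA, NA, NA, 256L,
                1024L, NA, 1024L, 1024L, 2048L,
                NA, NA, 512L, NA),
  stringsAsFactors = FALSE
)
.FP_FAMILIES$available <- !is.na(.FP_FAMILIES$provider)

#' Fingerprint family registry
#'
#' The 14 canonical binary fingerprint families (hashed-path, circular,
#' key-based, pair/torsion and pattern fingerprints), with the provider
#' and bit length of each family this installation can compute.
#'
#' @return data.frame with columns family_id, provider, nbits, available
#' @export
fingerprintFamilies <- function() .FP_FAMILIES

#' @rdname fingerprintFamilies
#' @export
availableFamilies <- function() .FP_FAMILIES$family_id[.FP_FAMILIES$available]

.checkFamilies <- function(families) {
  bad <- setdiff(families, .FP_FAMILIES$family_id)
  if (length(bad))
    stop(sprintf("unknown fingerprint family: %s (valid: %s)",
                 paste(bad, collapse = ", "),
                 paste(.FP_FAMILIES$family_id, collapse = ", ")),
         call. = FALSE)
  unav <- setdiff(families, availableFamilies())
  if (length(unav))
    stop(sprintf("fingerprint family not available in this toolchain: %s (available: %s)",
                 paste(unav, collapse = ", "),
                 paste(availableFamilies(), collapse = ", ")),
         call. = FALSE)
  invisible(families)
}

.familyNbits <- function(family) {
  .FP_FAMILIES$nbits[match(family, .FP_FAMILIES$family_id)]
}

.fpFromMol <- function(mol, family) {
  switch(family,
    path = cpp_path_fp(mol$natoms, mol$z, mol$aromatic, mol$bond_u,
                       mol$bond_v, mol$bond_order, mol$bond_ring,
                       mol$bond_aromatic, 2048L, 7L, 2L),
    morgan = cpp_morgan_fp(mol$natoms, mol$z, mol$aromatic, mol$bond_u,
                           mol$bond_v, mol$bond_order, mol$bond_ring,
                           mol$bond_aromatic, 1024L, 2L),
    torsion = cpp_torsion_fp(mol$natoms, mol$z, mol$aromatic, mol$bond_u,
                             mol$bond_v, mol$bond_order, mol$bond_ring,
                             mol$bond_aromatic, 1024L),
    stop("internal: .fpFromMol only handles in-package families"))
}

# OpenBabel / ChemmineR families need an SDFset; built once per batch
.obFpBatch <- function(smiles, family) {
  sdf <- suppressWarnings(ChemmineR::smiles2sdf(
    stats::setNames(smiles, sprintf("m%d", seq_along(smiles)))))
  if (length(sdf) != length(smiles))
    stop("internal: batch SDF conversion dropped molecules that passed sanitization")
  if (family == "atom_pair") {
    # atom-pair descriptors folded modulo the bit length (classic folded
    # AP fingerprint)
    ap <- ChemmineR::ap(ChemmineR::sdf2ap(sdf))
    if (!is.list(ap)) ap <- list(ap)
    m <- matrix(FALSE, length(ap), 1024L)
    for (i in seq_along(ap))
      m[i, (unique(ap[[i]] %% 1024L)) + 1L] <- TRUE
  } else {
    ob_name <- c(standard = "FP2", pattern = "FP4", maccs = "MACCS")[family]
    m <- methods::slot(ChemmineR::fingerprintOB(sdf, ob_name), "fpma")
  }
  m <- m == 1
  dimnames(m) <- NULL
  m
}

#' Compute fingerprints for a batch of (already validated) SMILES
#'
#' @param smiles character vector of valid SMILES
#' @param families subset of \code{availableFamilies()}
#' @param mols optional pre-parsed \code{fmctMol} list matching
#'   \code{smiles} (saves re-parsing)
#' @return named list of logical matrices (one row per molecule)
#' @export
computeFingerprints <- function(smiles, families = availableFamilies(),
                                mols = NULL) {
  .checkFamilies(families)
  n <- length(smiles)
  own <- intersect(families, c("path", "morgan", "torsion"))
  ext <- setdiff(families, own)
  out <- list()
  if (length(own)) {
    if (is.null(mols)) mols <- lapply(smiles, molFromSmiles)
    for (fam in own) {
      m <- matrix(FALSE, n, .familyNbits(fam))
      for (i in seq_len(n)) m[i, ] <- .fpFromMol(mols[[i]], fam)
      out[[fam]] <- m
    }
  }
  for (fam in ext) out[[fam]] <- .obFpBatch(smiles, fam)
  out[families]
}
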