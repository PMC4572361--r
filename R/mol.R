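#' @useDynLib fmct, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

# atomic numbers for elements BindingDB-scale organic chemistry needs
.ELEMENTS <- c(
  H = 1L, He = 2L, Li = 3L, Be = 4L, B = 5L, C = 6L, N = 7L, O = 8L,
  F = 9L, Ne = 10L, Na = 11L, Mg = 12L, Al = 13L, Si = 14L, P = 15L,
  S = 16L, Cl = 17L, Ar = 18L, K = 19L, Ca = 20L, Fe = 26L, Cu = 29L,
  Zn = 30L, As = 33L, Se = 34L, Br = 35L, I = 53L, Pt = 78L, Hg = 80L
)

.structure_error <- function(msg, smiles = NULL) {
  stop(structure(
    class = c("fmct_structure_error", "error", "condition"),
    list(message = if (is.null(smiles)) msg else
      sprintf("%s [SMILES: %s]", msg, smiles), call = NULL)))
}

#' Parse a SMILES string into an annotated molecular graph
#'
#' Parsing and kekulization are delegated to OpenBabel (via ChemmineOB);
#' ring-bond membership and aromaticity are then perceived on the graph
#' (aromatic rings: 5-7-membered rings whose atoms are all sp2-eligible
#' with a Hueckel 4n+2 pi count). The result is the internal molecule
#' representation used by every fingerprint and MCS routine.
#'
#' @param smiles single SMILES string
#' @return an object of class \code{fmctMol}: heavy-atom graph with atomic
#'   numbers, aromaticity flags and a bond table
#' @examples
#' m <- molFromSmiles("c1ccccc1O")
#' m$natoms
#' @export
molFromSmiles <- function(smiles) {
  if (!is.character(smiles) || length(smiles) != 1L || is.na(smiles) ||
      !nzchar(trimws(smiles)))
    .structure_error("empty or non-character SMILES input")
  smiles <- trimws(smiles)
  sdf <- tryCatch(
    suppressWarnings(ChemmineR::smiles2sdf(stats::setNames(smiles, "q"))),
    error = function(e) NULL)
  if (is.null(sdf) || length(sdf) != 1L)
    .structure_error("SMILES failed to parse/sanitize", smiles)
  mol <- .molFromSdfItem(sdf[[1]], smiles)
  if (is.null(mol)) {
    # the SDF reader cannot represent bond-less molecules; a bare atom
    # that still canonicalizes is built directly
    can <- canonicalSmiles(smiles)
    sym <- sub("^\\[([A-Za-z][a-z]?).*\\]$", "\\1", can)
    if (!is.na(can) && grepl("^(\\[[^]]+\\]|[A-Za-z][a-z]?)$", can) &&
        (sym %in% names(.ELEMENTS) || can %in% names(.ELEMENTS))) {
      z <- .ELEMENTS[[if (sym %in% names(.ELEMENTS)) sym else can]]
      return(structure(list(
        smiles = smiles, natoms = 1L, z = z, aromatic = 0L,
        bond_u = integer(0), bond_v = integer(0), bond_order = integer(0),
        bond_ring = integer(0), bond_aromatic = integer(0), nbonds = 0L),
        class = "fmctMol"))
    }
    .structure_error("SMILES produced an empty molecule", smiles)
  }
  mol
}

.molFromSdfItem <- function(sdf_item, smiles = NA_character_) {
  ab <- ChemmineR::atomblock(sdf_item)
  if (is.null(ab) || nrow(ab) == 0L) return(NULL)
  if (!all(grepl("^[A-Za-z]+_\\d+$", rownames(ab)))) return(NULL)
  elem <- sub("_\\d+$", "", rownames(ab))
  z <- .ELEMENTS[elem]
  if (anyNA(z))
    .structure_error(sprintf("unknown element(s): %s",
                             paste(unique(elem[is.na(z)]), collapse = ", ")),
                     smiles)
  bb <- ChemmineR::bondblock(sdf_item)
  if (is.null(bb) || nrow(bb) == 0L) {
    bu <- integer(0); bv <- integer(0); border <- integer(0)
  } else {
    bu <- as.integer(bb[, 1]); bv <- as.integer(bb[, 2])
    border <- as.integer(bb[, 3])
  }
  per <- cpp_perceive(length(z), as.integer(z), bu, bv,
                      ifelse(border == 4L, 1L, border))
  barom <- as.integer(per$aromatic_bond | border == 4L)
  structure(list(
    smiles = smiles,
    natoms = length(z),
    z = unname(as.integer(z)),
    aromatic = as.integer(per$aromatic_atom),
    bond_u = bu, bond_v = bv,
    bond_order = ifelse(border == 4L, 1L, border),
    bond_ring = as.integer(per$ring_bond),
    bond_aromatic = barom,
    nbonds = length(bu)
  ), class = "fmctMol")
}

#' @export
print.fmctMol <- function(x, ...) {
  cat(sprintf("fmctMol: %d heavy atoms, %d bonds (%d aromatic)\n",
              x$natoms, x$nbonds, sum(x$bond_aromatic)))
  invisible(x)
}

#' Canonicalize SMILES strings
#'
#' Returns the OpenBabel canonical SMILES for each input; unparsable
#' inputs yield \code{NA}. Exact-structure matching in the package always
#' compares canonical forms, never raw input strings.
#'
#' @param smiles character vector of SMILES
#' @return character vector of canonical SMILES (NA where invalid)
#' @export
canonicalSmiles <- function(smiles) {
  vapply(smiles, function(s) {
    if (is.na(s) || !nzchar(trimws(s))) return(NA_character_)
    out <- tryCatch(
      ChemmineOB::convertFormat("SMI", "CAN", paste0(trimws(s), "\n")),
      error = function(e) NA_character_)
    if (is.na(out) || !nzchar(out)) return(NA_character_)
    can <- strsplit(out, "[\t\n]")[[1]][1]
    if (is.na(can) || !nzchar(can)) NA_character_ else can
  }, character(1), USE.NAMES = FALSE)
}

# parse a batch, returning list with NULL for failures (quiet bookkeeping
# for the sanitization gate)
.parseBatch <- function(smiles) {
  lapply(smiles, function(s) tryCatch(molFromSmiles(s),
                                      error = function(e) NULL))
}
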