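# Maximum common substructure similarity.

#' Options for the MCS search
#'
#' The search finds the maximum common edge subgraph of two heavy-atom
#' molecular graphs: atoms match by element, bonds by order with aromatic
#' bonds as their own type, and (by default) ring bonds only match ring
#' bonds. By default the common substructure may be disconnected
#' (fragment-tolerant matching); \code{connected = TRUE} restricts it to
#' a single connected fragment. The search maximizes the common bond
#' count, with the common atom count as tie-break.
#'
#' Normalizations to the 0-1 scale (n = common, A/B = the molecules):
#' \describe{
#'   \item{atoms_bonds}{Tanimoto over atoms+bonds:
#'     (n_atoms+n_bonds) / (sizeA + sizeB - (n_atoms+n_bonds)) with
#'     size = atoms+bonds. The default: this is the variant calibrated
#'     against the known high-MCS drug pair shipped with the package.}
#'   \item{atoms}{heavy-atom Tanimoto: n_atoms / (nA + nB - n_atoms).}
#'   \item{min_atoms}{n_atoms / min(nA, nB).}
#' }
#'
#' @param connected require a single connected common fragment
#' @param ring_matches_ring ring bonds may only match ring bonds
#' @param normalization similarity normalization, see Details
#' @param timeout wall-clock budget in seconds per pair
#' @param max_nodes deterministic search-node budget (takes effect before
#'   the wall clock on any machine fast enough; keeps results
#'   machine-independent)
#' @return options list for \code{\link{mcsSimilarity}}
#' @export
mcsOpts <- function(connected = FALSE, ring_matches_ring = TRUE,
                    normalization = c("atoms_bonds", "atoms", "min_atoms"),
                    timeout = 60, max_nodes = 2e6) {
  list(connected = isTRUE(connected),
       ring_matches_ring = isTRUE(ring_matches_ring),
       normalization = match.arg(normalization),
       timeout = timeout, max_nodes = max_nodes)
}

#' Maximum-common-substructure similarity between two compounds
#'
#' @param smiles_a,smiles_b SMILES strings (heavy-atom counts >= 1)
#' @param opts search options from \code{\link{mcsOpts}}
#' @return an \code{\linkS4class{McsResult}}; if the search budget is
#'   exhausted the best substructure found so far is returned with
#'   \code{timedOut = TRUE} (not an error)
#' @examples
#' mcsSimilarity("CC", "CCC", mcsOpts(normalization = "atoms"))
#' @export
mcsSimilarity <- function(smiles_a, smiles_b, opts = mcsOpts()) {
  ma <- molFromSmiles(smiles_a)
  mb <- molFromSmiles(smiles_b)
  res <- cpp_mcs(ma$natoms, ma$z, ma$aromatic, ma$bond_u, ma$bond_v,
                 ma$bond_order, ma$bond_ring, ma$bond_aromatic,
                 mb$natoms, mb$z, mb$aromatic, mb$bond_u, mb$bond_v,
                 mb$bond_order, mb$bond_ring, mb$bond_aromatic,
                 opts$connected, opts$ring_matches_ring,
                 opts$max_nodes, opts$timeout)
  n_at <- res$n_atoms; n_bd <- res$n_bonds
  sim <- switch(opts$normalization,
    atoms = if (ma$natoms + mb$natoms - n_at == 0) 1
            else n_at / (ma$natoms + mb$natoms - n_at),
    min_atoms = n_at / min(ma$natoms, mb$natoms),
    atoms_bonds = {
      sa <- ma$natoms + ma$nbonds; sb <- mb$natoms + mb$nbonds
      nn <- n_at + n_bd
      if (sa + sb - nn == 0) 1 else nn / (sa + sb - nn)
    })
  new("McsResult", nMcs = as.integer(n_at), nBonds = as.integer(n_bd),
      nA = as.integer(ma$natoms), nB = as.integer(mb$natoms),
      nBondsA = as.integer(ma$nbonds), nBondsB = as.integer(mb$nbonds),
      similarity = min(1, sim), normalization = opts$normalization,
      timedOut = isTRUE(res$timed_out))
}
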