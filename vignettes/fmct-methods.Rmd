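---
title: "Ligand-based target prediction with fmct: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Ligand-based target prediction with fmct}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The method

`fmct` implements "Find My Compound's Targets": given a query compound,
compute its chemical similarity to every compound in a curated
bioactivity reference table, keep the reference compounds above a
similarity threshold whose measured affinity beats a potency cutoff,
and transfer the protein annotations of those neighbors to the query as
ranked target hypotheses. The scientific premise is the similarity
principle of medicinal chemistry: compounds that look alike tend to
bind alike. The method makes no statistical claim — it reports raw
similarity evidence, not E-values — so the similarity metric and the
two gates (similarity threshold, affinity cutoff) carry all of the
method's behavior.

Four similarity variants are provided, differing only in the metric:

1. **`path_tanimoto`** — Tanimoto over a Daylight-style topological
   path fingerprint. Fast; the default.
2. **`avg5`** — the unweighted mean of five fingerprint metrics chosen
   by a correlation filter to be minimally redundant (below).
3. **`pure_mcs`** — similarity from the maximum common substructure
   (MCS), scaled to [0, 1]. Slow but sees shared scaffolds that hashed
   fingerprints dilute.
4. **`path_then_mcs`** — a fingerprint scan re-ranked by MCS score:
   near-MCS quality at fingerprint cost.

## The reference table

The table builder ingests a BindingDB-style TSV (one compound–target
measurement per row) and applies three curation stages, each counted in
the build metadata:

1. **Load**: header-dialect resolution (column names drift across
   database releases, so logical fields map to header names through a
   configurable dialect). A line carrying both a Ki and an IC50 value
   becomes two measurement rows. Malformed lines are counted, not fatal.
2. **Measurement filter**: keep rows whose affinity type is Ki or IC50
   and whose affinity text parses as a plain positive number in nM.
   Any `<` or `>` anywhere in the affinity field marks a range
   measurement and drops the row. A leading `=` is stripped;
   scientific notation is accepted. The filter is pure and idempotent.
3. **Sanitization**: structures that fail SMILES parsing or
   canonicalization are dropped and counted. Survivors get one bit
   fingerprint per configured family.

Rows are deliberately **not** deduplicated: each measurement is
independent evidence, and repeated (compound, target) pairs simply
yield more supporting hits after merging. Affinities are used in nM
throughout; no unit conversion is attempted.

Persistence is a versioned plain-text columnar format with
fingerprints as fixed-width hex strings; the declared record count
makes truncation detectable, and a load of a saved table reproduces
records and fingerprints bit-exactly.

## Fingerprints

No installed R package provides the Daylight/RDKit-style subgraph-hash
fingerprint this method leans on, so the package implements it
directly, along with circular and torsion fingerprints:

* **path** (2048 bits): enumerate every connected bond subgraph of 1–7
  bonds (branched subgraphs included), hash an invariant built from the
  sorted multiset of typed-bond codes — bond order with aromatic as its
  own type, endpoint element + aromaticity, and endpoint degrees within
  the subgraph — and set 2 bits per subgraph from a deterministic
  64-bit mixer. Against the reference toolkit's path fingerprint the
  resulting Tanimoto values agree to about ±0.02 on a ten-pair drug
  battery (asserted in the test suite at ±0.06).
* **morgan** (1024 bits, radius 2): iterated neighborhood hashing from
  atom invariants (element, degree, implicit-H count, aromaticity, ring
  membership).
* **torsion** (1024 bits): hashed linear four-atom paths.

Four further families come from the installed toolkits: OpenBabel FP2
(registered as the "standard" hashed-path family), FP4 ("pattern"
keys), MACCS keys, and a folded ChemmineR atom-pair fingerprint. The
catalog registers the full canonical set of 14 families; the 7 without
a provider here are enumerable but not computable, so the 3 × 14 = 42
metric grid carries 21 live metrics. Aromaticity is perceived
in-package (5–7-membered rings, sp2-eligible atoms, Hückel 4n+2 count)
because the SDF interchange format arrives kekulized.

Bit-vector comparison uses the three standard formulas — with `a`, `b`
set bits and `c` shared bits: Tanimoto `c/(a+b-c)`, Dice `2c/(a+b)`,
Cosine `c/sqrt(ab)`. Two all-zero fingerprints compare as 1 and a
single all-zero fingerprint as 0 by convention (the formulas are 0/0
there); Tanimoto ≤ Dice always.

## Metric selection for the averaged variant

The `avg5` variant needs five metrics that are informative *and*
non-redundant. Profiles of all live metrics are computed over a panel
of compound pairs; the Pearson correlation matrix of the metric columns
is then thinned greedily: repeatedly find the metric pair with the
highest |r| and drop the member with the larger mean |r| against the
survivors (ties: the later catalog index goes), until `k = 5` remain.
Zero-variance metrics get correlation 0 with a warning.

Greedy pairwise elimination is a heuristic. On redundancy structure
with clear clusters — which is what real fingerprint families produce —
it coincides with the exhaustive minimax-|r| subset (verified against a
brute-force subset search on catalogs of ≤ 6 metrics for k = 2–4 in
the tests); on near-degenerate panels where all metrics correlate
above ~0.97 the greedy and exhaustive optima can differ in the third
decimal. Both a frozen selection (JSON round trip) and per-dataset
re-derivation are supported, since either policy is defensible and the
original calibration pairs are not redistributable.

The package's stand-in panel is generated by the fixtures module (all
within-series plus sampled cross-series pairs over twelve scaffold
series); it reproduces the *shape* of a receptor-ligand pair panel —
a bimodal mix of similar and dissimilar pairs — not the chemistry of
any particular receptor's ligands.

## MCS similarity

The MCS engine finds a maximum common edge subgraph: a pairing of
bonds, consistent with an injective atom mapping, matching atoms by
element, bonds by order (aromatic as its own type), and — by default —
ring bonds only to ring bonds. Two search modes share one codebase:

* **fragment-tolerant (default)**: the common substructure may be
  disconnected. Implemented as maximum clique on the bond-compatibility
  graph (Tomita-style branch and bound with a greedy coloring bound and
  a greedy seed clique).
* **connected**: a single common fragment, grown McGregor-style.

The objective is lexicographic: common bond count first, atom count as
tie-break. The search honors a deterministic node budget (default
2×10⁶ nodes, so results do not depend on machine speed) plus a
wall-clock timeout (default 60 s per pair); exhaustion returns the
best-so-far substructure with a `timedOut` flag rather than an error,
and re-ranking sorts such hits by their best-so-far value.

Three normalizations map the common substructure to [0, 1] (`n` =
common atoms/bonds, `A`, `B` the molecules):

| normalization | formula | default |
|---|---|---|
| `atoms_bonds` | (nAtoms+nBonds) / (sizeA+sizeB−(nAtoms+nBonds)), size = atoms+bonds | yes |
| `atoms` | nAtoms / (nA+nB−nAtoms) | |
| `min_atoms` | nAtoms / min(nA, nB) | |

The default was **calibrated on the cloperastine panel** shipped with
the package (`exampleCompounds()`): cloperastine and a known
leukotriene A4 hydrolase inhibitor are fingerprint-dissimilar
(path Tanimoto ≈ 0.36 here) yet famously substructure-similar — one
can cut cloperastine at its ether and reassemble the inhibitor. A
*connected* MCS caps at 13–14 atoms for this pair (atom-Tanimoto
≈ 0.41–0.44) and cannot express that likeness; the fragment-tolerant
match embeds all 22 inhibitor atoms and 23 of its 24 bonds, giving
45/49 ≈ 0.918 under `atoms_bonds`, 22/23 ≈ 0.957 under `atoms`, and
1.0 under `min_atoms`. `atoms_bonds` with disconnected matching is the
option that best reproduces the published likeness score for this pair
(≈ 0.92) and is therefore the default; the others remain selectable,
and the acceptance script reports the calibrated value.

## Prediction, merging and reporting

A scan computes the query's similarity to every record, applies the
affinity cutoff and then the similarity threshold, and sorts hits by
(similarity desc, affinity asc, monomer id asc) — ties are fully
specified so reports are byte-reproducible. Design points:

* The similarity threshold is **inclusive** (≥), so a threshold of 1.0
  returns exact matches instead of nothing. Default 0.7 — high enough
  that hits stay interpretable, low enough to surface analogs; the
  discussed hit ranges in published use of this method sit between
  ~0.6 and 1.0. Configurable per query.
* The affinity cutoff (default 10 000 nM = 10 µM, the customary
  potency bound) applies per measurement row; a compound passes if any
  of its measurements for a target passes. The affinity gate runs
  before the similarity gate purely for speed — the result set is
  identical either way.
* Duplicate protein hits are merged on the UniProt primary accession;
  records lacking an accession merge under their target name with a
  `no_accession` flag instead of being dropped, because unannotated
  rows still carry signal. Supporting compound hits are conserved
  (their counts sum to the scan's hit count) and ordered within each
  target.
* Batch mode emits one row per query with the top N targets (default
  3); each row equals the truncation of the corresponding single-query
  report, and unparsable queries are reported per row, not fatally.
* In the hybrid variant the re-rank happens before merging and target
  ranking follows the MCS score.

## Reference-set reduction

For many-query workloads the table can be condensed: group records by
target, cluster each group on path-fingerprint Tanimoto, and keep
representative high-affinity compounds per cluster. Choices:

* The clustering gate is parameterized as a threshold of 0.8 **on the
  similarity scale**: a literal Tanimoto-*distance* threshold of 0.8
  (similarity ≥ 0.2) merges nearly everything and is restored, for
  completeness, by `distance = TRUE`.
* The default algorithm is leader (sphere-exclusion) clustering over
  records visited in (affinity asc, monomer id asc) order —
  deterministic and O(nk). A complete-linkage agglomerative option
  serves as an exact cross-check on small groups; both produce the
  planted partition on well-separated test data.
* Representatives: `highest_affinity` (argmin affinity_nM, ties by
  monomer id; default) or `random` (seeded draw), both per the two
  behaviors described for this workflow; requesting more
  representatives than a cluster holds returns the whole cluster.

Reduction trades recall for speed by construction: a query that lands
inside a cluster is still found via the representative, while a query
resembling a non-representative member can drop below threshold
against the representative and vanish. The tests assert exactly this
direction (equal recall for in-cluster probes, strictly lower for a
probe built next to a non-representative member) rather than any
numeric recall, which would require the original million-row snapshot.

## The synthetic-data generator

All tests run offline against generated fixtures. The generator plants
twelve mutually diverse drug-like scaffolds (~18–26 heavy atoms), each
written with a terminal aliphatic tail; series members decorate the
tail end with single-atom substituents (F, Cl, Br, C, N, O — iodine is
reserved for query compounds so probes never duplicate a reference
structure). Because a decoration only *adds* heavy atoms at the
sparsest part of the graph, every member keeps ≥ ~0.85 path-Tanimoto
to its series siblings while distinct scaffolds stay below ~0.4 — so a
0.8 clustering threshold recovers exactly one cluster per series, and
the manifest can predict every downstream count (post-filter rows,
group sizes, cluster count, the top target of each planted query).
Affinities are drawn log-uniformly over the configured range, with the
series base forced to the series minimum so it anchors its cluster and
wins representative selection; qualifier rows carry `>`-prefixed
affinities; invalid rows carry unparsable SMILES. Generation is a pure
function of the spec: a fixed seed gives a byte-identical TSV.

What the fixtures do **not** emulate: real BindingDB chemistry (size
and scaffold distributions, measurement noise, inconsistent UniProt
annotation), so green tests demonstrate the machinery's correctness on
separable data, not predictive performance on real pharmacology. The
default test sizes (4 targets × 3 series × 5 compounds, plus 5 invalid
and 5 qualifier rows) keep the full suite comfortably inside a couple
of minutes; the pipeline itself is size-agnostic.

## Degenerate inputs and numerical corners

* Single-heavy-atom molecules bypass the SDF interchange (which cannot
  represent bond-less molecules) and are built directly; their MCS
  against anything reduces to a shared-element check.
* Empty scan results, empty groups and header-only TSVs flow through
  without error; empty *input files* and missing columns fail with
  configuration errors naming the problem.
* All similarity computations are symmetric, bounded in [0, 1], and 1
  on self-comparison; these are asserted as properties over generated
  cases, alongside exact agreement of the bit formulas with a
  position-by-position enumeration oracle.

## Known limitations

* The 7 unavailable fingerprint families are enumerated but not
  computable here; an installation with more providers raises the live
  metric count without code changes.
* The in-package path fingerprint tracks, but is not bit-identical to,
  the reference toolkit's; published similarity values are reproduced
  to ±0.05.
* MCS search is exact only within its node budget; pathological pairs
  (large, highly symmetric) may return flagged lower bounds.
* No significance statistics are attached to target hypotheses, by
  design; ranking is raw similarity.
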