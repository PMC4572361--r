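# fmct — ligand-based protein target prediction from bioactivity data

`fmct` implements **Find My Compound's Targets**: given a query
compound, it finds chemically similar compounds in a curated
bioactivity reference table (a local, fingerprint-annotated distillate
of a BindingDB-style dump) and transfers their annotated protein
targets to the query as ranked hypotheses. It is aimed at medicinal
chemists and chemical biologists asking "what might this compound
bind?" — for mechanism-of-action hypotheses, off-target/side-effect
flags, or repurposing leads.

The core quantity is chemical similarity. With `a`, `b` the set-bit
counts of two fingerprints and `c` their shared bits, the package
provides Tanimoto `c/(a+b−c)`, Dice `2c/(a+b)` and Cosine `c/√(ab)`
over a catalog of 14 fingerprint families (3 × 14 = 42 enumerable
metrics; 21 computable with the families this toolchain provides), and
a maximum-common-substructure similarity: for a common substructure of
`n` atoms and `m` bonds between molecules A and B,

    s = (n + m) / (|A| + |B| − (n + m)),   |X| = atoms + bonds of X

with heavy-atom-only alternatives selectable. Four prediction variants
use these metrics: single path-fingerprint Tanimoto (fast default),
the mean of five minimally redundant metrics chosen by a correlation
filter, pure MCS, and a fingerprint scan re-ranked by MCS. Hits pass
two gates — similarity ≥ threshold (default 0.7, inclusive) and
affinity ≤ cutoff (default 10 000 nM = 10 µM) — and are merged per
protein on UniProt accessions.

Alongside the predictor: a reference-table builder with the standard
curation filters (Ki/IC50 only, no `<`/`>` range qualifiers, structure
sanitization), clustering-based reference reduction (leader clustering
at similarity 0.8 per target, representative selection by affinity or
seeded draw), a thin client for the BindingDB-style RESTful endpoints,
a seeded synthetic-fixture generator, and a command-line wrapper.

## Worked example

Cloperastine is a cough suppressant derived from the antihistamine
diphenhydramine. Scanning it against a tiny reference table in which
diphenhydramine is annotated to the histamine H1 receptor:

```r
library(fmct)
cmp <- exampleCompounds()     # cloperastine, diphenhydramine, an LTA4H inhibitor

d <- defaultDialect()
tsv <- tempfile(fileext = ".tsv")
writeLines(c(
  paste(c(d$smiles, d$monomer_id, d$target_name, d$uniprot, d$ki, d$ic50),
        collapse = "\t"),
  paste(c(cmp["diphenhydramine"], "6510", "Histamine H1 receptor",
          "P35367", "15", ""), collapse = "\t"),
  paste(c("CN(C)CCOC(c1ccc(C)cc1)c1ccccc1", "6511", "Histamine H1 receptor",
          "P35367", "", "40"), collapse = "\t"),
  paste(c("OC(=O)c1ccccc1OC(C)=O", "9001", "Prostaglandin G/H synthase 1",
          "P23219", "", "1700"), collapse = "\t")), tsv)

tab <- buildReferenceTable(tsv, families = "path")
#> reference table: 3 raw -> 3 measurement-filtered -> 3 sanitized

predictTargets(cmp["cloperastine"], tab, queryConfig(similarity_threshold = 0.7))
#> PredictionReport for Clc1ccc(cc1)C(c1ccccc1)OCCN1CCCCC1 (path_tanimoto variant)
#>   1 target(s); similarity range 0.718-0.718
#>  uniprot_primary           target_name best_similarity n_supporting no_accession
#>           P35367 Histamine H1 receptor       0.7181009            1        FALSE
```

The H1 receptor is proposed because cloperastine's path-fingerprint
Tanimoto to diphenhydramine is 0.718 — at or above the 0.7 threshold —
while the methylated analog (0.68) and aspirin (0.17) fall below it.
The `n_supporting` column counts the reference measurements backing
each target; `writeReport()` exports the full table as CSV.

The third example compound, a leukotriene A4 hydrolase inhibitor,
shows why the MCS variant exists: its path-fingerprint similarity to
cloperastine is only 0.36, but the fragment-tolerant maximum common
substructure covers 22 of its 23 heavy atoms:

```r
mcsSimilarity(cmp["cloperastine"], cmp["lta4h_inhibitor"])
#> McsResult: 22 atoms / 23 bonds common (molecules 23/22 atoms); similarity 0.9184 [atoms_bonds]
```

A fingerprint-only scan would never surface this neighbor; the
`pure_mcs` and `path_then_mcs` variants do.

## Command line

```sh
fmct=$(Rscript -e 'cat(system.file("scripts","fmct",package="fmct"))')
Rscript $fmct build-table --tsv bindingdb.tsv --out ref.table --fast
Rscript $fmct predict --table ref.table --query 'CCOc1ccccc1' --threshold 0.7 --out report.csv
Rscript $fmct reduce-table --table ref.table --out reduced.table --threshold 0.8
Rscript $fmct sim --metric mcs --a 'CCO' --b 'CCCO'
```

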