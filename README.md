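# rccnet

Cell-type-resolved classification of disease risk genes and anatomy-layered
protein–protein interaction (PPI) subnetworks for the retina–choroid complex
(RCC).

## The problem

For complex age-related eye disease, genetics delivers hundreds of candidate
risk genes, but most of them are expressed in nearly every body tissue, so the
list alone says little about *where* — in which tissue layer and which cell
type — each gene can plausibly act.  `rccnet` is for computational biologists
who want to combine three frozen inputs — (1) gene–disease association scores
in [0, 1], (2) averaged per-cell-type expression matrices (e.g. a 10-cell-type
choroid/RPE dataset and a 7-cell-type neural-retina dataset), and (3) a
protein-coding gene universe annotated with a one-gene-one-class functional
ontology, subcellular localization and cross-tissue distribution classes —
into anatomy-resolved candidate gene sets and seed-centric PPI subnetworks.

## The method in brief

Per cell type, present genes are binned into expression groups

- **A** — a fixed quota of `round(top_frac · N_universe)` top expressed genes
  (193 for the default 1 % of 19,300),
- **B / C / D** — upper 25 % / middle 50 % / lower 25 % of the remaining
  expressed genes,
- **E** — present but zero, **F** — absent from the dataset,

and a gene's *best* group is its minimum across all cell types.  Cell-type
specificity is the z-score `z = (x − mean)/sd` across the cell types of one
dataset (sample sd; `z ≥ 2` flags restricted expression).  The association
list is pruned (universe-resolvable → exclusion sets removed → bottom 5 % of
scores dropped), genes with best group A–C form the high-confidence list, and
each is assigned a tissue-specificity group: **1a** RCC-restricted and
disease-private, **1b** restricted but shared with other age-related diseases,
**2** intermediate, **3** generic.  Gene sets are tested for class enrichment
with the one-sided Fisher's exact test,

> p = P(X ≥ k), X ~ Hypergeometric(N, K, n),

with Benjamini–Hochberg q-values reported alongside.  Subnetworks grow from
group-1a/highly-expressed seeds: first-shell partners at confidence ≥ 0.5 from
experiments/databases channels, filtered to highly expressed, non-ubiquitous
partners, pruned for compartment-incompatible contacts (e.g.
extracellular–cytosol), and stratified into anatomical layers AL1–AL6 by an
ordered rule engine with explicit overrides.

A seeded synthetic-data generator (`generate_bundle()`) emulates the complete
input bundle at study scale with planted ground truth, so the entire pipeline
is testable offline.

## Worked example

```r
library(rccnet)

gen <- generate_bundle(synthetic_config(seed = 1), tempfile("bundle"))
b   <- load_bundle(gen$paths$bundle)

rw <- reproduce_workflow(b)
str(rw)
#> List of 7
#>  $ n_association_genes: int 418
#>  $ n_pruned           : int 373
#>  $ n_high_confidence  : int 352
#>  $ group_sizes        : Named int [1:4] 42 56 84 170
#>   ..- attr(*, "names")= chr [1:4] "1a" "1b" "2" "3"
#>  $ overlap_fraction   : num 0.676
#>  $ n_seeds            : int 42
#>  $ n_interactors      : int 178
```

Reading: of 418 raw association entries, 373 survive pruning and 352 are
highly expressed (best group A–C) in at least one of the 17 cell types; the
four specificity groups partition them (42 are RCC-restricted and
disease-private); 67.6 % overlap with at least one other age-related disease
set; 42 genes qualify as network seeds, whose deduplicated first shells retain
178 interactors after the expression and ubiquity filters.

The same chain runs stage-by-stage from the shell:

```sh
Rscript scripts/rccnet.R all --outdir out --seed 1
```

which writes per-stage TSVs (`groups_*.tsv`, `risk_genes.tsv`,
`enrichment_sysgo_set2.tsv`, `network.graphml`, …) and a run manifest with
parameters, seed, input checksums and row counts.

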