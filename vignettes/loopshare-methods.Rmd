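---
title: "Share statistics and mutation-accumulation analysis: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Share statistics and mutation-accumulation analysis: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(loopshare)
```

## The measurement model

A synthetic long-read single-cell experiment yields one assembled molecule
per (cell barcode, molecule UMI) pair, with a gene and isoform assignment
and, for every catalogued somatic site the molecule covers, a ref/alt allele
call. `loopshare` treats that per-molecule table as its entry format: the
upstream steps (assembly, alignment, isoform annotation, variant calling on
the matched exomes) are established external tools whose outputs are modeled
as input columns. All counting is done on UMI-deduplicated molecules, not
reads — a deliberate choice, since molecule counts are the quantity the
barcoding scheme is designed to make reliable.

The core statistic is the **share**: the fraction of a feature's molecules
in a cell that carry the mutation (gene or isoform level), or, for a fusion,
the fraction of the locus pair's output that is chimeric,
$f/(f + h + t)$. Shares live in $[0,1]$ and are **NA where the denominator
is zero**. Unexpressed is not the same as wild type: a cell that does not
express the gene gives no evidence about its genotype. The NA mask is kept
in every share matrix; for SD computation and clustering NA is imputed as 0,
which matches the observed behaviour that non-expressing cells co-locate
with wild-type cells in the embedding. Reported shares are never imputed.

Chimeric molecules have no single-gene identity: at gene level they are
counted once under their 5' (head) gene, at isoform level they are excluded,
and they re-enter only in fusion shares. This keeps isoform counts per gene
summing to the gene's non-chimeric count.

## Filter funnel and thresholds

| parameter | default | meaning |
|---|---|---|
| `valid_cell_min_molecules` | 1000 | a cell is valid when it has **strictly more** molecules than this |
| `min_cells_per_mutation` | 3 | a site must be observed (alt) in at least this many distinct cells |
| `mutation_sd_threshold` | 0.4 | share features kept at population SD ≥ threshold |
| `expression_sd_thresholds` | 0.5, 0.8, 1.0, 1.4 | screening ladder for expression features |
| `cluster_support_min_cells` | 5 | cluster-specific mutations: cells required in the owning cluster (and zero elsewhere) |
| `fusion_min_cells` | 2 | distinct cells supporting a kept fusion |
| `fusion_cis_distance_bp` | 40000 | same-chromosome, same-strand pairs closer than this are read-throughs |
| `fusion_max_partners` | 2 | promiscuity bound for head/tail genes |
| `exon_edge_tolerance_bp` | 0 | slack when matching breakpoints to exon edges |

Conventions worth making explicit:

* **SD is the population SD** (denominator $n$): the feature screen is a
  descriptive dispersion cutoff over the full observed cohort, not an
  estimator of a super-population variance, and the convention is frozen by
  the desk check that a $\{0,1\}$ feature over two cells has SD 0.5.
* **Threshold comparisons are inclusive** (≥). Sources for this kind of
  screen alternate freely between "> 0.4" and "≥ 0.4"; one convention is
  used everywhere and documented here.
* Expression is normalised per cell to a fixed library size of $10^4$ and
  log1p-transformed before SDs are computed; in the integrated feature
  matrix the expression block is additionally standardised per feature,
  while share blocks stay on their native $[0,1]$ scale so that a share of
  0.5 means the same thing in every column.
* **Cis-direction** (fusion rule 1) is interpreted as same chromosome *and*
  same annotated strand, with the gap measured between nearest gene
  boundaries (0 for overlapping genes). Anti-sense neighbours within 40 kb
  are therefore *not* eliminated. Partner counts for the promiscuity rules
  are computed on the raw candidate universe, before any elimination.

## Clustering

Cells are clustered by Leiden community detection (modularity objective) on
a k-nearest-neighbour graph built in the selected feature space, not on the
2-D embedding; UMAP supplies coordinates for visualisation only. Edges are
weighted by the Jaccard overlap of the two cells' neighbourhoods (the
shared-nearest-neighbour construction standard in single-cell toolkits).
This matters more here than for expression data: share profiles are
near-discrete (a clone either carries a site or it does not), so many
cell–cell distances tie exactly, and an unweighted small-k graph fragments a
homogeneous population into arbitrary bands. For the same reason the default
neighbourhood is comparatively large (`knn_k = 30`): with cohorts of a few
hundred cells and clusters of tens to low hundreds, neighbourhoods must span
a meaningful fraction of a cluster for the graph to be denser inside
clusters than between them. The default was calibrated on synthetic cohorts
with known labels, where the correct partition is unambiguous.

Cluster labels are reassigned deterministically (A, B, C, … by decreasing
size, ties broken by the lexicographically smallest member barcode), and the
whole pipeline is reproducible under `random_seed`: Leiden and UMAP run
under one seed, UMAP single-threaded with deterministic SGD.

Cluster enrichment of a binary cell property uses the two-sided Fisher exact
test on the (flag × in-cluster) table — an exact hypergeometric summation,
appropriate at these sample sizes; degenerate margins return p = 1 with a
warning rather than an error so that screening loops do not abort.

## Mutation-accumulation graphs

Long reads expose the exact set of somatic alt alleles on each molecule (its
*genotype*). Under the single assumption that **mutation is irreversible**,
observed genotypes of a gene are partially ordered by strict set inclusion,
and the package reports the covering relations of that order — the Hasse
diagram. This formalisation is deliberately assumption-minimal: any curated
step-by-step pathway consistent with irreversibility is a subgraph of the
Hasse diagram, so the graph is a superset of whatever pathway a human
annotator would draw, and it is unique and reproducible. Roots (minimal
non-empty genotypes) are the isolated founder mutations; the summary layer
reports the maximal-support genotype, the longest chain, and a per-edge
contiguity score (the fraction of newly gained mutations rank-adjacent, in
transcript coordinates, to a mutation already present — chains that grow
contiguously along the molecule score 1). Amino-acid mode collapses two
nucleotide changes in one codon to a single protein change, mirroring how
such "double single-nucleotide" codons are tallied at protein level.
Genotypes supported by a single molecule are flagged rather than dropped:
with a low but non-zero per-molecule error rate they are the most likely
artifacts, but dropping them silently would bias the graph's leaves.

## The synthetic cohort generator

`simulate_cohort()` emulates the structure of a two-sample liver cohort with
everything the analysis assumes, and returns the full ground truth. Defaults:

* **162 benign and 285 tumor cells** — the published cohort's cell counts;
* molecules per cell drawn negative-binomially (mean 120, size 4), with a
  5% subpopulation at mean 15 so the validity filter has work to do; the
  desk-scale validity cutoff for synthetic runs is 50 molecules (the
  real-data default of 1000 stays in `run_config()`);
* genes with 1–5 isoforms, lognormal abundance weights, and a configurable
  tumor/benign log2 fold-change on half the genes (±2 by default) to give
  expression-level clustering its signal;
* two clone trees: a deep, mostly linear chain with a rare isolated clone
  and a double-nucleotide codon change (the hypermutated-HLA-like case) and
  a branching diamond; cells are assigned clones per sample with the tree's
  cell fractions, and every molecule of a clone gene carries exactly the
  clone's mutation set, minus per-site allele dropout (default 0.01, the
  unstated observation noise of real calls);
* decoy catalog sites (synonymous somatic, germline, benign-only,
  germline-only) that the somatic and min-cell filters must remove;
* two true fusions with exon-edge breakpoints in ≥ 2 valid tumor cells, and
  one labelled artifact chimera family per fusion rule, each violating
  exactly that rule, plus a low rate of random mid-exon chimeras.

The generator is deterministic given its seed. It does **not** simulate
sequence-level error profiles, barcode collisions, ambient RNA or doublets;
passing tests therefore demonstrate the correctness of the downstream logic
under the stated generative model, not robustness to those upstream
artifacts.

Test and acceptance runs use reduced problem sizes (15–60 cells per sample,
4–8 genes, 50–150 molecules per cell) chosen so that every scenario remains
populated — e.g. high enough per-cell depth that clone genes are expressed
in essentially every cell when a test's premise is that each cell carries
its population's profile.

## Numerical and degenerate-input choices

* Share matrices serialise with 17 significant digits and parse through
  `strtod`, so expressed values round-trip bit-exactly; the NA mask uses the
  literal `NA` token.
* Zero-feature share matrices, empty molecule tables, empty candidate sets
  and empty graphs are all representable and round-trip as header-only /
  empty documents.
* `filter_valid_cells` is idempotent; fusion filtering is idempotent and
  monotone (survivors only shrink, rule by rule), with a complete
  per-candidate × per-rule audit trail.
* Candidate-level fusion breakpoints are the modal per-molecule breakpoints,
  ties broken toward the smaller coordinate.
* With fewer than two selected features, clustering refuses to run and says
  which threshold to lower; a single-cell matrix is an error for SD
  selection (an SD across one cell is not meaningful).

## Known limitations

* Shares are computed from molecule counts; if upstream deduplication is
  imperfect, shares inherit that bias.
* The accumulation graph enumerates *potential* pathways; it cannot choose
  among several covering chains without a rate model, which no part of this
  analysis supplies.
* Leiden resolution and `knn_k` are cohort-scale dependent; very large
  cohorts (tens of thousands of cells) would need the usual PCA reduction
  first, which this package does not implement.
* The enrichment p-values are per-cluster and unadjusted; with many clusters
  apply your preferred multiplicity correction downstream
  (`p.adjust`).
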