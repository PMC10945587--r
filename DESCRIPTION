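Package: loopshare
Title: Share Statistics, Clustering and Mutation-Accumulation Analysis for
    Single-Cell Long-Read Transcriptomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Downstream analysis of single-cell synthetic long-read
    transcriptome data, where every sequenced molecule carries a cell barcode,
    a molecule barcode (UMI) and per-site allele calls. Implements the
    per-cell "share" statistics (mutated transcripts over total transcripts of
    a gene or isoform, and fusion molecules over fusion plus partner-gene
    molecules), somatic-site and standard-deviation based feature filtering,
    UMAP embedding with graph-based cell clustering and cluster-specific
    mutation extraction, rule-based fusion-transcript filtering, and
    reconstruction of per-molecule mutation-accumulation graphs under the
    assumption that mutations are irreversible. A synthetic-cohort generator
    with known ground truth (clone tree, cell labels, true fusions, artifact
    chimeras) drives examples and tests so no external data are required.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    tibble,
    readr,
    rlang,
    jsonlite,
    igraph,
    uwot,
    FNN,
    vcfR,
    withr,
    ggplot2,
    generics,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    mclust,
    optparse
Config/testthat/edition: 3
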