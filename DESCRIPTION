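Package: cellsnv
Title: Quantification, Classification and Visualization of Expressed SNVs
    in Barcoded Single-Cell RNA-Seq Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for exploring expressed single-nucleotide variants (SNVs)
    in cell-barcoded single-cell RNA sequencing data. Reads per-cell variant
    and reference read-count tables, builds a layered cells-by-SNVs matrix
    that distinguishes absence of variant expression (reference-only
    coverage) from absence of gene expression (no reads), computes per-cell
    and per-cluster expressed variant allele fraction (VAF_RNA) metrics,
    infers the probable origin of each SNV (germline homozygous or
    heterozygous, somatic-like, RNA-level) from its cross-cell expression
    profile, flags random monoallelic expression consistent with
    X-inactivation or transcriptional bursting, clusters SNVs by their
    expression profiles across cells (the transposed SNV matrix), embeds
    cells with PCA, UMAP or t-SNE, integrates multiple samples into a shared
    embedding, and renders interactive HTML and static scatter plots colored
    by any of these quantities. A seed-deterministic synthetic-data generator
    with planted ground truth supports validation of every inference.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    igraph,
    jsonlite,
    ggplot2,
    uwot,
    Rtsne,
    optparse,
    stats,
    utils,
    grDevices,
    grid,
    tools,
    methods
Suggests:
    testthat (>= 3.0.0),
    png
Config/testthat/edition: 3
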