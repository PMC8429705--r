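Package: ipsgenome
Title: Assembly QC, Genome-Size Estimation and Gene-Family Expansion
    Statistics for Bark Beetle Genomics
Version: 1.0.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Reimplements, as one tested workflow, the core computations of a
    bark beetle (Ips typographus) genome project: assembly contiguity and
    composition statistics (N50/L50, GC content, size classes), gene-model
    annotation summaries, terminal telomere-motif scanning, canonical k-mer
    histograms with peak-based haploid genome-size estimation, a
    gene-total-normalised Fisher exact test for Pfam domain-family expansion
    with Benjamini-Hochberg FDR control and z-score heatmap matrices,
    Hedges g standardized effect sizes with noncentral-t confidence
    intervals, and TPM/log2/row-scaled expression matrix preparation. A
    synthetic-data module generates every input with known ground truth so
    the whole workflow is testable without external sequencing data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Biostrings,
    data.table,
    rtracklayer,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    pheatmap,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
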