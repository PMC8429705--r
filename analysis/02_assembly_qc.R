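#!/usr/bin/env Rscript
# Stage 2: assembly statistics, telomere scan (validated against the planted
# truth) and annotation statistics, including the published-table inputs.

suppressPackageStartupMessages(library(ipsgenome))

contigs <- Biostrings::readDNAStringSet("results/simulated/contigs.fasta")
truth <- utils::read.delim("results/simulated/telomere_truth.tsv")

st <- contig_stats(contigs, size_thresholds = c(1e4, 2e4, 5e4))
print(st)
utils::write.table(
  data.frame(statistic = c("total_length_bp", "n_contigs", "n50_bp", "l50",
                           "max_contig_bp", "min_contig_bp", "gc_percent"),
             value = c(st$total_length_bp, st$n_contigs, st$n50_bp, st$l50,
                       st$max_contig_bp, st$min_contig_bp,
                       round(st$gc_percent, 2))),
  "results/assembly_stats.tsv", sep = "\t", quote = FALSE, row.names = FALSE)

sc <- scan_telomeres(contigs, motif = "TTAGG", min_copies = 5,
                     window_bp = 1000)
print(sc)
utils::write.table(sc$hits, "results/telomere_hits.tsv", sep = "\t",
                   quote = FALSE, row.names = FALSE)
recovered <- paste(truth$contig_id, truth$terminus) %in%
  paste(sc$hits$contig_id, sc$hits$terminus)
cat(sprintf("planted telomere termini recovered: %d / %d\n",
            sum(recovered), nrow(truth)))

# annotation statistics from the published gene-model table inputs:
# 23,923 genes spanning 132,911,182 bp of a 236.82 Mb assembly
ann <- annotation_summary_stats(n_genes = 23923,
                                total_gene_length_bp = 132911182,
                                genome_length_bp = 236820000)
print(ann)
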