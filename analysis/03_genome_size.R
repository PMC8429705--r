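#!/usr/bin/env Rscript
# Stage 3: canonical k-mer histogram of the simulated survey reads and
# peak-based haploid genome-size estimation (truth: 500 kb).

suppressPackageStartupMessages(library(ipsgenome))

reads <- Biostrings::readDNAStringSet("results/simulated/reads.fasta")
hist <- count_kmers(reads, k = 19)
write_kmer_histogram(hist, "results/kmer_histogram.histo")

est <- estimate_genome_size(hist)
print(est)
cat(sprintf("relative error vs 500 kb truth: %.2f%%\n",
            100 * abs(est$estimated_size_bp - 5e5) / 5e5))
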