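#!/usr/bin/env Rscript
# Stage 1: generate every synthetic input the downstream stages consume,
# with known ground truth. One global seed drives named substreams so any
# stage can be re-run alone.

suppressPackageStartupMessages(library(ipsgenome))

seed <- 20210301L
dir.create("results/simulated", recursive = TRUE, showWarnings = FALSE)

# a 500 kb, 35% GC genome standing in for the 236.8 Mb assembly at desk scale
genome <- generate_genome(500000, gc_fraction = 0.352,
                          seed = substream_seed(seed, "genome"))
write_reads(genome, "results/simulated/genome.fasta")

# fragment into 25 contigs, planting TTAGG telomere blocks at random termini
fr <- fragment_genome(genome, 25, telomere_motif = "TTAGG",
                      telomere_copies = 10, min_contig_bp = 2000,
                      seed = substream_seed(seed, "fragment"))
write_reads(fr$contigs, "results/simulated/contigs.fasta")
utils::write.table(fr$truth, "results/simulated/telomere_truth.tsv",
                   sep = "\t", quote = FALSE, row.names = FALSE)

# a 60x error-bearing short-read survey for the k-mer analysis
rd <- simulate_reads(genome, coverage = 60, read_length_bp = 150,
                     error_rate = 0.005, seed = substream_seed(seed, "reads"))
write_reads(rd$reads, "results/simulated/reads.fasta")

# 12 species x 800 domains with 15 planted 6-fold expansions in species 1
exp_spec <- data.frame(domain = 1:15, species = 1, fold_change = 6)
dc <- simulate_domain_counts(12, 800, baseline_rate = 5,
                             expansions = exp_spec,
                             seed = substream_seed(seed, "domains"))
write_count_matrix(dc$matrix, "results/simulated/domain_counts.tsv")
utils::write.table(dc$truth, "results/simulated/expansion_truth.tsv",
                   sep = "\t", quote = FALSE, row.names = FALSE)

# a 2,000-gene x 12-sample expression survey
ex <- simulate_expression(2000, 12, seed = substream_seed(seed, "expression"))
write_matrix_tsv(ex$counts, "results/simulated/expression_counts.tsv")
utils::write.table(
  data.frame(gene_id = names(ex$lengths), length_bp = ex$lengths),
  "results/simulated/gene_lengths.tsv", sep = "\t", quote = FALSE,
  row.names = FALSE)

cat(sprintf(
  "simulated: genome 500 kb; %d contigs (%d planted telomere termini); %d reads; 12x800 domain counts (15 planted); 2000x12 expression counts\n",
  length(fr$contigs), nrow(fr$truth), length(rd$reads)))
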