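# Independent oracles used across test files.

# N50/L50 by literal definition: sort descending, cumulative scan.
oracle_n50 <- function(lens) {
  sl <- sort(lens, decreasing = TRUE)
  cum <- cumsum(as.numeric(sl))
  i <- which(cum >= sum(as.numeric(lens)) / 2)[1]
  list(n50 = sl[i], l50 = i)
}

# Two-sided Fisher exact p via R's hypergeometric density (dhyper), an
# implementation route independent of the package's log-factorial code.
oracle_fisher_p <- function(a, b, c, d) {
  m <- a + b; n <- c + d; k <- a + c
  xs <- max(0, k - n):min(k, m)
  probs <- dhyper(xs, m, n, k)
  pobs <- dhyper(a, m, n, k)
  min(1, sum(probs[probs <= pobs * (1 + 1e-7)]))
}

# A small flat-dialect gene/exon model table used by annotation tests.
example_gene_models <- function() {
  data.frame(
    seqid = "contig_001",
    type = c("gene", "exon", "exon", "gene", "exon"),
    id = c("g1", "g1.e1", "g1.e2", "g2", "g2.e1"),
    parent = c(NA, "g1", "g1", NA, "g2"),
    start = c(1L, 1L, 61L, 201L, 201L),
    end = c(100L, 40L, 100L, 300L, 300L),
    strand = "+",
    stringsAsFactors = FALSE)
}

scolytine_species <- function() c("Ityp", "Dpon", "Hham")

other_coleoptera <- function() {
  c("Agla", "Tcas", "Ldec", "Apla", "Cmac", "Dvir", "Otau", "Atum", "Nves")
}
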