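#' Generate a random genome sequence
#'
#' Draws an i.i.d. nucleotide sequence of the requested length and GC
#' composition. This is the root of the synthetic workflow: a genome of known
#' size and composition from which contigs and sequencing reads are derived,
#' emulating a compact, highly homozygous beetle genome at desk scale.
#'
#' @param length_bp positive integer, genome length in bp.
#' @param gc_fraction expected fraction of G+C bases, in \[0, 1\].
#' @param seed integer seed; equal seeds give bit-identical sequences.
#' @return a [Biostrings::DNAStringSet] with a single sequence named
#'   `"genome"`, alphabet restricted to A/C/G/T.
#' @examples
#' g <- generate_genome(1000, gc_fraction = 0.35, seed = 1)
#' Biostrings::width(g)
#' @export
generate_genome <- function(length_bp, gc_fraction = 0.35, seed = 1L) {
  .check(length(length_bp) == 1L && is.finite(length_bp) && length_bp >= 1,
         "length_bp must be a positive integer")
  .check(gc_fraction >= 0 && gc_fraction <= 1, "gc_fraction must be in [0, 1]")
  set.seed(seed)
  probs <- c(A = (1 - gc_fraction) / 2, C = gc_fraction / 2,
             G = gc_fraction / 2, T = (1 - gc_fraction) / 2)
  bases <- sample(names(probs), size = length_bp, replace = TRUE, prob = probs)
  out <- Biostrings::DNAStringSet(paste(bases, collapse = ""))
  names(out) <- "genome"
  out
}

#' Fragment a genome into contigs with planted telomeric repeats
#'
#' Splits a single-sequence genome at uniformly drawn breakpoints and, at a
#' random subset of contig termini, plants exact tandem copies of a telomeric
#' motif: the motif itself on 5' termini, its reverse complement on 3'
#' termini. The returned truth table records every planted terminus so the
#' telomere scanner can be validated round-trip.
#'
#' Contigs shorter than `min_contig_bp` (before planting) are rejected and the
#' breakpoints redrawn.
#'
#' @param genome single-sequence [Biostrings::DNAStringSet] (or character).
#' @param n_contigs number of contigs to produce (>= 1).
#' @param telomere_motif short A/C/G/T motif, default `"TTAGG"` (the ancestral
#'   insect telomere repeat).
#' @param telomere_copies exact tandem copies planted per chosen terminus
#'   (0 disables planting).
#' @param prob_telomere probability that any given terminus receives a planted
#'   repeat.
#' @param min_contig_bp minimum pre-planting contig length.
#' @param seed integer seed.
#' @return list with elements `contigs` (a named DNAStringSet) and `truth`
#'   (data.frame with columns `contig_id`, `terminus` (`"5p"`/`"3p"`),
#'   `motif`, `copies`).
#' @export
fragment_genome <- function(genome, n_contigs, telomere_motif = "TTAGG",
                            telomere_copies = 10L, prob_telomere = 0.5,
                            min_contig_bp = 100L, seed = 1L) {
  seqs <- .as_sequence_chr(genome)
  .check(length(seqs) == 1L, "genome must contain exactly one sequence")
  gl <- nchar(seqs)
  .check(n_contigs >= 1, "n_contigs must be >= 1")
  .check(n_contigs <= gl, "n_contigs exceeds genome length")
  .check(telomere_copies >= 0, "telomere_copies must be >= 0")
  .check(grepl("^[ACGT]+$", telomere_motif), "telomere_motif must be over {A,C,G,T}")
  set.seed(seed)

  min_contig_bp <- min(min_contig_bp, floor(gl / n_contigs))
  starts <- 1L
  if (n_contigs > 1L) {
    for (attempt in 1:1000) {
      bp <- sort(sample.int(gl - 1L, n_contigs - 1L))
      lens <- diff(c(0L, bp, gl))
      if (all(lens >= min_contig_bp)) break
      if (attempt == 1000)
        stop("could not draw breakpoints satisfying the minimum contig length",
             call. = FALSE)
    }
    starts <- c(1L, bp + 1L)
    ends <- c(bp, gl)
  } else {
    ends <- gl
  }
  cores <- substring(seqs, starts, ends)
  ids <- sprintf("contig_%03d", seq_len(n_contigs))

  truth <- data.frame(contig_id = character(0), terminus = character(0),
                      motif = character(0), copies = integer(0),
                      stringsAsFactors = FALSE)
  if (telomere_copies > 0) {
    rc <- .revcomp_chr(telomere_motif)
    fwd_block <- strrep(telomere_motif, telomere_copies)
    rev_block <- strrep(rc, telomere_copies)
    for (i in seq_len(n_contigs)) {
      if (stats::runif(1) < prob_telomere) {       # 5' terminus
        cores[i] <- paste0(fwd_block, cores[i])
        truth <- rbind(truth, data.frame(
          contig_id = ids[i], terminus = "5p", motif = telomere_motif,
          copies = as.integer(telomere_copies), stringsAsFactors = FALSE))
      }
      if (stats::runif(1) < prob_telomere) {       # 3' terminus
        cores[i] <- paste0(cores[i], rev_block)
        truth <- rbind(truth, data.frame(
          contig_id = ids[i], terminus = "3p", motif = telomere_motif,
          copies = as.integer(telomere_copies), stringsAsFactors = FALSE))
      }
    }
  }
  contigs <- Biostrings::DNAStringSet(cores)
  names(contigs) <- ids
  list(contigs = contigs, truth = truth)
}

#' Simulate shotgun reads from a genome
#'
#' Samples fixed-length reads uniformly from the forward strand (k-mer
#' counting downstream is canonical, so strand is irrelevant) and applies
#' i.i.d. per-base substitution errors. No indels and no quality model: reads
#' emulate a short-read genome survey used only for k-mer analysis.
#'
#' @param genome single-sequence DNAStringSet or character.
#' @param coverage fold coverage (> 0); the number of reads is
#'   `round(coverage * genome_length / read_length_bp)`.
#' @param read_length_bp read length (<= genome length).
#' @param error_rate per-base substitution probability in \[0, 1).
#' @param seed integer seed.
#' @return list with `reads` (named DNAStringSet) and `truth` (data.frame of
#'   `read_id`, `start`, `end`, 1-based origin on the genome).
#' @export
simulate_reads <- function(genome, coverage, read_length_bp = 100L,
                           error_rate = 0, seed = 1L) {
  seqs <- .as_sequence_chr(genome)
  .check(length(seqs) == 1L, "genome must contain exactly one sequence")
  gl <- nchar(seqs)
  .check(coverage > 0, "coverage must be > 0")
  .check(read_length_bp >= 1 && read_length_bp <= gl,
         "read_length_bp must be in [1, genome length]")
  .check(error_rate >= 0 && error_rate < 1, "error_rate must be in [0, 1)")
  set.seed(seed)

  n_reads <- round(coverage * gl / read_length_bp)
  .check(n_reads >= 1, "coverage too low: zero reads")
  starts <- sample.int(gl - read_length_bp + 1L, n_reads, replace = TRUE)

  gi <- utf8ToInt(seqs)
  idx <- rep(starts, each = read_length_bp) +
    rep.int(0:(read_length_bp - 1L), n_reads)
  rv <- gi[idx]

  if (error_rate > 0) {
    n_err <- stats::rbinom(1L, length(rv), error_rate)
    if (n_err > 0) {
      pos <- sample.int(length(rv), n_err)
      codes <- utf8ToInt("ACGT")
      cur <- match(rv[pos], codes)
      shift <- sample.int(3L, n_err, replace = TRUE)
      rv[pos] <- codes[((cur - 1L + shift) %% 4L) + 1L]
    }
  }

  big <- intToUtf8(rv)
  rs <- seq.int(1L, by = read_length_bp, length.out = n_reads)
  reads <- Biostrings::DNAStringSet(substring(big, rs, rs + read_length_bp - 1L))
  ids <- sprintf("read_%06d", seq_len(n_reads))
  names(reads) <- ids
  list(reads = reads,
       truth = data.frame(read_id = ids, start = starts,
                          end = starts + read_length_bp - 1L,
                          stringsAsFactors = FALSE))
}

#' Simulate a multi-species domain-count matrix with planted expansions
#'
#' Null cells are Poisson with a rate proportional to each species' gene
#' total: `baseline_rate * gene_total_s / mean(gene_totals)`. Cells listed in
#' `expansions` have their rate multiplied by a fold change > 1 in the named
#' species, giving ground-truth expanded families for validating the Fisher
#' expansion test. Counts are capped at the gene total (a protein contributes
#' at most once per domain).
#'
#' @param n_species number of species (>= 3).
#' @param n_domains number of domain families.
#' @param gene_totals per-species gene totals; default draws uniformly from
#'   13,000--24,000, the range spanned by published beetle proteomes.
#' @param baseline_rate expected null count per domain per (average) species.
#' @param expansions NULL, or a data.frame with columns `domain` (index or
#'   name), `species` (index or name), `fold_change` (> 1).
#' @param seed integer seed.
#' @return list with `matrix` (a [domain_count_matrix]) and `truth`
#'   (data.frame `domain`, `focal_species`, `fold_change`).
#' @export
simulate_domain_counts <- function(n_species, n_domains, gene_totals = NULL,
                                   baseline_rate = 5, expansions = NULL,
                                   seed = 1L) {
  .check(n_species >= 3, "n_species must be >= 3")
  .check(n_domains >= 1, "n_domains must be >= 1")
  .check(baseline_rate >= 0, "baseline_rate must be >= 0")
  set.seed(seed)
  if (is.null(gene_totals)) {
    gene_totals <- sample(13000:24000, n_species, replace = TRUE)
  }
  .check(length(gene_totals) == n_species && all(gene_totals >= 1),
         "gene_totals must give one positive total per species")
  species <- if (!is.null(names(gene_totals))) names(gene_totals) else
    sprintf("species_%02d", seq_len(n_species))
  names(gene_totals) <- species
  domains <- sprintf("dom_%04d", seq_len(n_domains))

  rate <- outer(gene_totals / mean(gene_totals), rep(baseline_rate, n_domains))
  dimnames(rate) <- list(species, domains)

  truth <- data.frame(domain = character(0), focal_species = character(0),
                      fold_change = numeric(0), stringsAsFactors = FALSE)
  if (!is.null(expansions) && nrow(expansions) > 0) {
    di <- if (is.numeric(expansions$domain)) domains[expansions$domain] else
      as.character(expansions$domain)
    si <- if (is.numeric(expansions$species)) species[expansions$species] else
      as.character(expansions$species)
    .check(all(di %in% domains), "expansion domain outside the domain universe")
    .check(all(si %in% species), "expansion species outside the species set")
    .check(all(expansions$fold_change > 1), "fold_change must be > 1")
    for (r in seq_along(di)) {
      rate[si[r], di[r]] <- rate[si[r], di[r]] * expansions$fold_change[r]
    }
    truth <- data.frame(domain = di, focal_species = si,
                        fold_change = expansions$fold_change,
                        stringsAsFactors = FALSE)
  }

  counts <- matrix(stats::rpois(length(rate), lambda = rate),
                   nrow = n_species, dimnames = dimnames(rate))
  counts <- pmin(counts, matrix(gene_totals, n_species, n_domains))
  list(matrix = domain_count_matrix(counts, gene_totals), truth = truth)
}

#' Simulate a gene-by-sample expression count table
#'
#' Gene baseline expression is log-normal, sample library-size factors are
#' log-normal, and counts are Poisson around their product — a deliberately
#' simple model feeding the TPM/log/scale transform chain.
#'
#' @param n_genes,n_samples table dimensions (>= 1).
#' @param seed integer seed.
#' @return list with `counts` (gene x sample integer matrix) and `lengths`
#'   (named per-gene transcript lengths in bp, >= 1).
#' @export
simulate_expression <- function(n_genes, n_samples, seed = 1L) {
  .check(n_genes >= 1 && n_samples >= 1, "n_genes and n_samples must be >= 1")
  set.seed(seed)
  genes <- sprintf("gene_%05d", seq_len(n_genes))
  samples <- sprintf("sample_%02d", seq_len(n_samples))
  lengths <- sample(500:5000, n_genes, replace = TRUE)
  names(lengths) <- genes
  mu <- stats::rlnorm(n_genes, meanlog = log(50), sdlog = 1.2)
  sf <- stats::rlnorm(n_samples, meanlog = 0, sdlog = 0.3)
  lam <- outer(mu * lengths / 1000, sf)
  counts <- matrix(stats::rpois(length(lam), lam), nrow = n_genes,
                   dimnames = list(genes, samples))
  list(counts = counts, lengths = lengths)
}
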