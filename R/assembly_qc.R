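#' Assembly contiguity and composition statistics
#'
#' Computes the standard single-assembly report: total length, contig count,
#' N50/L50 and the full Nx curve, extreme contig lengths, GC content and a
#' size-class summary (how many contigs, and what fraction of the assembly,
#' lie at or above each length threshold).
#'
#' N50 is the length of the contig at which the descending-sorted cumulative
#' length first reaches at least half the assembly; L50 is the number of
#' contigs needed to get there. GC% is `100 * (G + C) / (A + C + G + T)`;
#' ambiguous bases (N) are excluded from the denominator so the statistic
#' reflects composition only.
#'
#' @param contigs a [Biostrings::DNAStringSet] (or named character vector)
#'   with unique ids and non-empty sequences.
#' @param size_thresholds bp thresholds for the size-class summary.
#' @return an object of class `assembly_stats`: a list with
#'   `total_length_bp`, `n_contigs`, `n50_bp`, `l50`, `nx_curve`,
#'   `max_contig_bp`, `min_contig_bp`, `gc_percent`, `size_class_summary`
#'   (data.frame `threshold_bp`, `n_contigs`, `fraction_of_total`).
#' @examples
#' cs <- Biostrings::DNAStringSet(c(a = "ACGTACGT", b = "GGCC"))
#' contig_stats(cs)
#' @export
contig_stats <- function(contigs, size_thresholds = c(1e5, 1e6, 1e7)) {
  if (is.character(contigs)) contigs <- Biostrings::DNAStringSet(contigs)
  .check(length(contigs) >= 1, "contig set is empty")
  .check(all(Biostrings::width(contigs) > 0), "contigs must be non-empty")
  if (!is.null(names(contigs)))
    .check(!anyDuplicated(names(contigs)), "contig ids must be unique")

  lens <- Biostrings::width(contigs)
  total <- sum(as.numeric(lens))

  sl <- sort(lens, decreasing = TRUE)
  cum <- cumsum(as.numeric(sl))
  nx <- function(p) {
    i <- which(cum >= total * p / 100)[1]
    c(bp = sl[i], count = i)
  }
  n50 <- nx(50)
  curve <- vapply(seq(10, 90, 10), function(p) nx(p)[["bp"]], numeric(1))
  names(curve) <- paste0("N", seq(10, 90, 10))

  af <- Biostrings::alphabetFrequency(contigs, baseOnly = TRUE, collapse = TRUE)
  acgt <- sum(af[c("A", "C", "G", "T")])
  gc <- 100 * sum(af[c("G", "C")]) / acgt

  scs <- data.frame(
    threshold_bp = size_thresholds,
    n_contigs = vapply(size_thresholds, function(t) sum(lens >= t), integer(1)),
    fraction_of_total = vapply(size_thresholds,
                               function(t) sum(as.numeric(lens[lens >= t])) / total,
                               numeric(1)))

  structure(list(
    total_length_bp = total, n_contigs = length(contigs),
    n50_bp = unname(n50["bp"]), l50 = unname(n50["count"]),
    nx_curve = curve, max_contig_bp = max(lens), min_contig_bp = min(lens),
    gc_percent = gc, size_class_summary = scs), class = "assembly_stats")
}

#' @export
print.assembly_stats <- function(x, ...) {
  fmt <- function(label, value) cat(sprintf("%-28s %s\n", label, value))
  cat("Assembly statistics\n")
  fmt("Genome size (Mb)", sprintf("%.2f", x$total_length_bp / 1e6))
  fmt("Number of contigs", x$n_contigs)
  fmt("Contig N50 (Mb)", sprintf("%.2f", x$n50_bp / 1e6))
  fmt("Contig L50", x$l50)
  fmt("Max. contig length (Mb)", sprintf("%.2f", x$max_contig_bp / 1e6))
  fmt("Min. contig length (kb)", sprintf("%.2f", x$min_contig_bp / 1e3))
  fmt("GC (%)", sprintf("%.2f", x$gc_percent))
  for (i in seq_len(nrow(x$size_class_summary))) {
    r <- x$size_class_summary[i, ]
    fmt(sprintf("Contigs >= %g bp", r$threshold_bp),
        sprintf("%d (%.1f%% of assembly)", r$n_contigs,
                100 * r$fraction_of_total))
  }
  invisible(x)
}

#' Scan contig termini for tandem telomeric motifs
#'
#' A hit is a run of at least `min_copies` exact tandem copies of the motif
#' (strand `"forward"`) or of its reverse complement (strand `"reverse"`)
#' whose terminus-proximal end starts within `window_bp` of a contig end.
#' At most one hit is reported per (contig, terminus): the one with the most
#' copies, ties broken by smaller offset. Telomeric repeats at contig termini
#' indicate contigs approaching chromosome scale.
#'
#' @param contigs DNAStringSet or named character vector.
#' @param motif telomeric repeat unit over A/C/G/T, default `"TTAGG"` (the
#'   ancestral insect telomere repeat); length >= 2.
#' @param min_copies minimum exact tandem copies, default 5.
#' @param window_bp how far from a terminus a run may start, default 1000.
#' @return object of class `telomere_scan`: list with `hits` (data.frame
#'   `contig_id`, `terminus`, `strand`, `motif`, `tandem_copies`,
#'   `offset_bp`), and the summary counts `n_contigs_with_hits`,
#'   `n_forward`, `n_reverse`.
#' @export
scan_telomeres <- function(contigs, motif = "TTAGG", min_copies = 5L,
                           window_bp = 1000L) {
  if (is.character(contigs)) {
    nm <- names(contigs)
    contigs <- Biostrings::DNAStringSet(contigs)
    names(contigs) <- nm
  }
  .check(grepl("^[ACGT]+$", motif), "motif must be over {A,C,G,T}")
  ml <- nchar(motif)
  .check(ml >= 2, "motif length must be >= 2")
  .check(window_bp >= min_copies * ml,
         "window_bp must be >= min_copies * motif length")
  ids <- names(contigs)
  if (is.null(ids)) ids <- sprintf("contig_%03d", seq_along(contigs))
  rc <- .revcomp_chr(motif)

  # runs can extend well past the window; scan a terminus region long enough
  # to hold the window plus a generous run allowance
  slack <- window_bp + 500L * ml
  seqs <- as.character(contigs)
  lens <- nchar(seqs)

  find_runs <- function(region, pattern) {
    m <- gregexpr(paste0("(?:", pattern, ")+"), region)[[1]]
    if (m[1] == -1) return(NULL)
    data.frame(start = as.integer(m),
               len = attr(m, "match.length"))
  }

  rows <- list()
  for (i in seq_along(seqs)) {
    L <- lens[i]
    for (term in c("5p", "3p")) {
      region <- if (term == "5p") substr(seqs[i], 1L, min(L, slack)) else
        substr(seqs[i], max(1L, L - slack + 1L), L)
      rl <- nchar(region)
      best <- NULL
      for (strand in c("forward", "reverse")) {
        pat <- if (strand == "forward") motif else rc
        runs <- find_runs(region, pat)
        if (is.null(runs)) next
        copies <- runs$len %/% ml
        # offset: distance from the terminus to the terminus-proximal run end
        offset <- if (term == "5p") runs$start - 1L else
          rl - (runs$start + copies * ml - 1L)
        keep <- copies >= min_copies & offset < window_bp & offset >= 0L
        if (!any(keep)) next
        for (j in which(keep)) {
          cand <- data.frame(contig_id = ids[i], terminus = term,
                             strand = strand, motif = motif,
                             tandem_copies = copies[j], offset_bp = offset[j],
                             stringsAsFactors = FALSE)
          if (is.null(best) || cand$tandem_copies > best$tandem_copies ||
              (cand$tandem_copies == best$tandem_copies &&
               cand$offset_bp < best$offset_bp)) best <- cand
        }
      }
      if (!is.null(best)) rows[[length(rows) + 1L]] <- best
    }
  }
  hits <- if (length(rows)) do.call(rbind, rows) else
    data.frame(contig_id = character(0), terminus = character(0),
               strand = character(0), motif = character(0),
               tandem_copies = integer(0), offset_bp = integer(0),
               stringsAsFactors = FALSE)
  structure(list(hits = hits,
                 n_contigs_with_hits = length(unique(hits$contig_id)),
                 n_forward = sum(hits$strand == "forward"),
                 n_reverse = sum(hits$strand == "reverse")),
            class = "telomere_scan")
}

#' @export
print.telomere_scan <- function(x, ...) {
  cat(sprintf(
    "Telomeric motifs at the ends of %d contig(s) (%d forward strand(s), %d reverse strand(s))\n",
    x$n_contigs_with_hits, x$n_forward, x$n_reverse))
  if (nrow(x$hits)) print(x$hits, row.names = FALSE)
  invisible(x)
}

#' Gene-model annotation statistics
#'
#' Summarises a gene/exon annotation the way genome reports tabulate it:
#' gene counts and lengths, exon and intron averages, exons/introns per gene,
#' and the percentage of the genome covered by gene spans. Gene length is
#' `end - start + 1` (1-based inclusive coordinates); introns are the
#' inter-exon gaps within a gene. All averages are rounded to the nearest
#' integer, half away from zero, to match printed annotation tables.
#'
#' @param gene_models either a path to a GFF3 file or a data.frame as
#'   returned by [read_gene_models()] (columns `type`, `id`, `parent`,
#'   `start`, `end`).
#' @param genome_length_bp assembly length used for the coverage percentage.
#' @return object of class `annotation_stats` (see
#'   [annotation_summary_stats()] for the aggregate-only constructor).
#' @export
annotation_stats <- function(gene_models, genome_length_bp) {
  gm <- if (is.character(gene_models)) read_gene_models(gene_models) else
    gene_models
  genes <- gm[gm$type == "gene", , drop = FALSE]
  exons <- gm[gm$type == "exon", , drop = FALSE]
  .check(nrow(genes) >= 1, "no gene records found")

  gene_len <- genes$end - genes$start + 1
  gidx <- match(exons$parent, genes$id)
  bad <- which(is.na(gidx) | exons$start < genes$start[gidx] |
                 exons$end > genes$end[gidx])
  if (length(bad)) {
    stop(sprintf("exon '%s' (%d-%d) lies outside its gene span",
                 exons$id[bad[1]], exons$start[bad[1]], exons$end[bad[1]]),
         call. = FALSE)
  }

  exon_len <- exons$end - exons$start + 1
  intron_len <- numeric(0)
  n_introns <- 0L
  if (nrow(exons)) {
    sp <- split(exons[order(exons$start), c("start", "end")], gidx[order(exons$start)])
    for (e in sp) {
      if (nrow(e) > 1) {
        gaps <- e$start[-1] - e$end[-nrow(e)] - 1
        intron_len <- c(intron_len, gaps)
        n_introns <- n_introns + length(gaps)
      }
    }
  }

  annotation_summary_stats(
    n_genes = nrow(genes),
    total_gene_length_bp = sum(as.numeric(gene_len)),
    genome_length_bp = genome_length_bp,
    longest_gene_bp = max(gene_len),
    avg_exon_length_bp = if (length(exon_len)) mean(exon_len) else NA_real_,
    avg_intron_length_bp = if (length(intron_len)) mean(intron_len) else 0,
    n_exons = nrow(exons), n_introns = n_introns)
}

#' Annotation statistics from aggregate inputs
#'
#' The arithmetic core of [annotation_stats()], exposed directly so printed
#' annotation-table inputs (gene count, total gene length, genome size) can
#' be turned into the derived averages without the underlying GFF3.
#'
#' @param n_genes number of genes.
#' @param total_gene_length_bp summed gene-span length in bp.
#' @param genome_length_bp assembly length in bp (for percent covered).
#' @param longest_gene_bp,avg_exon_length_bp,avg_intron_length_bp,n_exons,n_introns
#'   optional detail fields, NA when unknown.
#' @return object of class `annotation_stats`.
#' @examples
#' annotation_summary_stats(23923, 132911182, 236820000)
#' @export
annotation_summary_stats <- function(n_genes, total_gene_length_bp,
                                     genome_length_bp = NA_real_,
                                     longest_gene_bp = NA_real_,
                                     avg_exon_length_bp = NA_real_,
                                     avg_intron_length_bp = NA_real_,
                                     n_exons = NA_integer_,
                                     n_introns = NA_integer_) {
  .check(n_genes >= 1, "n_genes must be >= 1")
  .check(total_gene_length_bp >= 0, "total_gene_length_bp must be >= 0")
  pct <- if (is.na(genome_length_bp)) NA_real_ else
    round_half_away(100 * total_gene_length_bp / genome_length_bp)
  structure(list(
    n_genes = n_genes,
    total_gene_length_bp = total_gene_length_bp,
    longest_gene_bp = longest_gene_bp,
    avg_gene_length_bp = round_half_away(total_gene_length_bp / n_genes),
    avg_exon_length_bp = if (is.na(avg_exon_length_bp)) NA_real_ else
      round_half_away(avg_exon_length_bp),
    avg_intron_length_bp = if (is.na(avg_intron_length_bp)) NA_real_ else
      round_half_away(avg_intron_length_bp),
    pct_genome_covered = pct,
    avg_exons_per_gene = if (is.na(n_exons)) NA_real_ else
      round_half_away(n_exons / n_genes),
    avg_introns_per_gene = if (is.na(n_introns)) NA_real_ else
      round_half_away(n_introns / n_genes)), class = "annotation_stats")
}

#' @export
print.annotation_stats <- function(x, ...) {
  fmt <- function(label, value) {
    if (length(value) == 1 && !is.na(value))
      cat(sprintf("%-32s %s\n", label, format(value, big.mark = ",")))
  }
  cat("Gene-model statistics\n")
  fmt("Number of genes", x$n_genes)
  fmt("Total gene length (bp)", x$total_gene_length_bp)
  fmt("Longest gene (bp)", x$longest_gene_bp)
  fmt("Average gene length (bp)", x$avg_gene_length_bp)
  fmt("Average exon length (bp)", x$avg_exon_length_bp)
  fmt("Average intron length (bp)", x$avg_intron_length_bp)
  fmt("% of genome covered by genes", x$pct_genome_covered)
  fmt("Average exons per gene", x$avg_exons_per_gene)
  fmt("Average introns per gene", x$avg_introns_per_gene)
  invisible(x)
}
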