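test_that("contig_stats reproduces hand-computed contiguity and composition", {
  expect_error(contig_stats(Biostrings::DNAStringSet()), "empty")

  one <- contig_stats(Biostrings::DNAStringSet(c(x = strrep("A", 100))))
  expect_identical(one$n50_bp, 100L)
  expect_identical(one$l50, 1L)

  cs <- Biostrings::DNAStringSet(stats::setNames(
    strrep("A", c(5, 4, 3, 2, 1)), paste0("c", 1:5)))
  st <- contig_stats(cs)
  expect_identical(st$total_length_bp, 15)
  expect_identical(st$n50_bp, 4L)
  expect_identical(st$l50, 2L)
  expect_identical(st$max_contig_bp, 5L)
  expect_identical(st$min_contig_bp, 1L)

  gc <- contig_stats(Biostrings::DNAStringSet(c(a = "GGCC", b = "ATAT")))
  expect_equal(gc$gc_percent, 50.0)

  # N excluded from the GC denominator
  withN <- contig_stats(Biostrings::DNAStringSet(c(a = "GGCCNNNN")))
  expect_equal(withN$gc_percent, 100)
})

test_that("N50/L50 match the brute-force oracle on random length multisets", {
  set.seed(101)
  for (i in 1:200) {
    lens <- sample.int(5000, sample(1:40, 1), replace = TRUE)
    cs <- Biostrings::DNAStringSet(stats::setNames(
      strrep("A", lens), paste0("c", seq_along(lens))))
    st <- contig_stats(cs)
    o <- oracle_n50(lens)
    expect_identical(st$n50_bp, o$n50)
    expect_identical(st$l50, o$l50)
  }
})

test_that("size-class counts are monotone non-increasing in the threshold", {
  set.seed(7)
  lens <- sample.int(10000, 50, replace = TRUE)
  cs <- Biostrings::DNAStringSet(strrep("A", lens))
  st <- contig_stats(cs, size_thresholds = c(10, 100, 1000, 5000, 10000))
  expect_true(all(diff(st$size_class_summary$n_contigs) <= 0))
  expect_true(all(st$size_class_summary$fraction_of_total >= 0 &
                    st$size_class_summary$fraction_of_total <= 1))
})

test_that("annotation statistics reproduce hand-computed gene/exon/intron summaries", {
  gm <- example_gene_models()
  # g1: 1-100 with exons 1-40 and 61-100 (one intron of 20); g2: single exon
  st <- annotation_stats(gm, genome_length_bp = 1000)
  expect_identical(st$n_genes, 2L)
  expect_identical(st$total_gene_length_bp, 200)
  expect_identical(st$avg_gene_length_bp, 100)
  expect_identical(st$avg_intron_length_bp, 20)
  expect_identical(st$avg_exons_per_gene, 2)   # 3 exons / 2 genes -> 1.5 -> 2
  expect_identical(st$pct_genome_covered, 20)

  single <- annotation_stats(gm[gm$id %in% c("g2", "g2.e1"), ], 1000)
  expect_identical(single$avg_gene_length_bp, 100)
  expect_identical(single$avg_exon_length_bp, 100)
  expect_identical(single$avg_introns_per_gene, 0)

  bad <- gm
  bad$end[bad$id == "g1.e2"] <- 150L
  expect_error(annotation_stats(bad, 1000), "g1\\.e2")
})

test_that("annotation stats survive a GFF3 write/read round trip", {
  gm <- example_gene_models()
  path <- withr::local_tempfile(fileext = ".gff3")
  write_gene_models(gm, path)
  back <- read_gene_models(path)
  expect_identical(annotation_stats(back, 1000), annotation_stats(gm, 1000))
})

test_that("aggregate annotation inputs yield the printed-table averages", {
  st <- annotation_summary_stats(23923, 132911182, 236820000)
  expect_identical(st$avg_gene_length_bp, 5556)
  expect_identical(st$pct_genome_covered, 56)
})

test_that("scan_telomeres finds planted tandem runs with the documented semantics", {
  expect_error(scan_telomeres(c(x = "ACGT"), motif = "TTNGG"), "motif")

  none <- scan_telomeres(c(x = strrep("ACGT", 300)))
  expect_identical(nrow(none$hits), 0L)

  # forward motif at the 3' end
  contig <- c(x = paste0(strrep("C", 200), strrep("TTAGG", 10)))
  sc <- scan_telomeres(contig, min_copies = 5, window_bp = 100)
  expect_identical(nrow(sc$hits), 1L)
  expect_identical(sc$hits$terminus, "3p")
  expect_identical(sc$hits$strand, "forward")
  expect_identical(sc$hits$tandem_copies, 10L)
  expect_identical(sc$hits$offset_bp, 0L)

  # reverse-complementing moves the hit to 5p, strand reverse, same copies
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(contig)))
  sc2 <- scan_telomeres(c(x = rc), min_copies = 5, window_bp = 100)
  expect_identical(sc2$hits$terminus, "5p")
  expect_identical(sc2$hits$strand, "reverse")
  expect_identical(sc2$hits$tandem_copies, 10L)

  # runs with too few copies or starting outside the window are not hits
  weak <- c(x = paste0(strrep("TTAGG", 4), strrep("C", 200)))
  expect_identical(nrow(scan_telomeres(weak, min_copies = 5,
                                       window_bp = 100)$hits), 0L)
  far <- c(x = paste0(strrep("C", 150), strrep("TTAGG", 6), strrep("C", 150)))
  expect_identical(nrow(scan_telomeres(far, min_copies = 5,
                                       window_bp = 100)$hits), 0L)
})

test_that("telomere scan mirrors exactly under reverse complement", {
  g <- generate_genome(20000, seed = 21)
  fr <- fragment_genome(g, 8, telomere_copies = 12, min_contig_bp = 200,
                        seed = 22)
  sc <- scan_telomeres(fr$contigs, min_copies = 5, window_bp = 1000)
  scr <- scan_telomeres(Biostrings::reverseComplement(fr$contigs),
                        min_copies = 5, window_bp = 1000)
  flip <- c("5p" = "3p", "3p" = "5p")
  swap <- c(forward = "reverse", reverse = "forward")
  a <- sc$hits
  a$terminus <- unname(flip[a$terminus])
  a$strand <- unname(swap[a$strand])
  key <- function(h) {
    h <- h[order(h$contig_id, h$terminus), ]
    rownames(h) <- NULL
    h
  }
  expect_identical(key(a), key(scr$hits))
})
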