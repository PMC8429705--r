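test_that("generate_genome validates input, is deterministic and hits its GC target", {
  expect_error(generate_genome(0), "positive")

  g1 <- generate_genome(10000, 0.35, seed = 1)
  g2 <- generate_genome(10000, 0.35, seed = 1)
  expect_identical(as.character(g1), as.character(g2))
  expect_identical(Biostrings::width(g1), 10000L)
  expect_true(grepl("^[ACGT]+$", as.character(g1)[[1]]))

  # binomial 3-SE bound: 0.352 +/- 3*sqrt(.352*.648/1e5) ~ 0.352 +/- 0.0045
  g <- generate_genome(100000, 0.352, seed = 7)
  af <- Biostrings::alphabetFrequency(g, baseOnly = TRUE, collapse = TRUE)
  gc <- sum(af[c("G", "C")]) / 100000
  expect_gt(gc, 0.352 - 3 * sqrt(0.352 * 0.648 / 1e5))
  expect_lt(gc, 0.352 + 3 * sqrt(0.352 * 0.648 / 1e5))
})

test_that("fragment_genome conserves sequence and plants telomeres only at recorded termini", {
  g <- generate_genome(1000, seed = 4)

  ident <- fragment_genome(g, 1, telomere_copies = 0, seed = 1)
  expect_identical(as.character(ident$contigs)[[1]], as.character(g)[[1]])
  expect_identical(nrow(ident$truth), 0L)

  expect_error(fragment_genome(g, 2000, seed = 1), "exceeds")

  fr <- fragment_genome(g, 4, telomere_motif = "TTAGG", telomere_copies = 10,
                        min_contig_bp = 50, seed = 3)
  expect_length(fr$contigs, 4L)
  # length accounting: planted bases = copies * motif_len * termini
  expect_identical(sum(Biostrings::width(fr$contigs)),
                   as.integer(1000 + 10 * 5 * nrow(fr$truth)))

  # stripping planted blocks and concatenating reconstructs the genome
  seqs <- as.character(fr$contigs)
  for (i in seq_len(nrow(fr$truth))) {
    id <- fr$truth$contig_id[i]
    block_len <- fr$truth$copies[i] * nchar(fr$truth$motif[i])
    if (fr$truth$terminus[i] == "5p") {
      expect_identical(substr(seqs[[id]], 1, block_len),
                       strrep(fr$truth$motif[i], fr$truth$copies[i]))
      seqs[[id]] <- substring(seqs[[id]], block_len + 1)
    } else {
      L <- nchar(seqs[[id]])
      rc <- as.character(Biostrings::reverseComplement(
        Biostrings::DNAString(fr$truth$motif[i])))
      expect_identical(substring(seqs[[id]], L - block_len + 1),
                       strrep(rc, fr$truth$copies[i]))
      seqs[[id]] <- substr(seqs[[id]], 1, L - block_len)
    }
  }
  expect_identical(paste(seqs, collapse = ""), as.character(g)[[1]])
})

test_that("simulate_reads honours the count formula, origin truth and error rate", {
  g <- generate_genome(1000, seed = 2)
  expect_error(simulate_reads(g, coverage = 0), "coverage")

  rd <- simulate_reads(g, coverage = 1, read_length_bp = 100, seed = 5)
  expect_length(rd$reads, 10L)   # round(1 * 1000 / 100)

  # error-free reads match the genome at their origin
  gs <- as.character(g)[[1]]
  for (i in seq_len(10)) {
    expect_identical(as.character(rd$reads[[i]]),
                     substr(gs, rd$truth$start[i], rd$truth$end[i]))
  }

  # 3-SE binomial bound on the realised substitution fraction
  g2 <- generate_genome(100000, seed = 8)
  rd2 <- simulate_reads(g2, coverage = 50, read_length_bp = 100,
                        error_rate = 0.01, seed = 11)
  gs2 <- as.character(g2)[[1]]
  origin <- substring(gs2, rd2$truth$start, rd2$truth$end)
  mm <- sum(mapply(function(r, o) {
    sum(utf8ToInt(r) != utf8ToInt(o))
  }, as.character(rd2$reads), origin))
  frac <- mm / (length(rd2$reads) * 100)
  expect_gt(frac, 0.007)
  expect_lt(frac, 0.013)
})

test_that("simulate_domain_counts follows its Poisson null and plants expansions", {
  z <- simulate_domain_counts(4, 50, baseline_rate = 0, seed = 1)
  expect_true(all(z$matrix$counts == 0))

  sim <- simulate_domain_counts(5, 200, baseline_rate = 5, seed = 2)
  expect_identical(nrow(sim$truth), 0L)
  # grand mean within a Poisson SE bound of the rate
  expect_gt(mean(sim$matrix$counts), 4.0)
  expect_lt(mean(sim$matrix$counts), 6.0)

  expect_error(
    simulate_domain_counts(5, 100, expansions = data.frame(
      domain = 1, species = 1, fold_change = 0.5), seed = 1),
    "fold_change")

  exp_spec <- data.frame(domain = 1:10, species = 1, fold_change = 8)
  se <- simulate_domain_counts(5, 500, baseline_rate = 5,
                               expansions = exp_spec, seed = 9)
  expect_identical(nrow(se$truth), 10L)
  focal <- se$matrix$species[1]
  planted <- se$matrix$counts[focal, se$truth$domain]
  background <- colMeans(se$matrix$counts[-1, se$truth$domain, drop = FALSE])
  expect_gt(mean(planted), mean(background))
})

test_that("simulate_expression is reproducible and round-trips through TPM", {
  tiny <- simulate_expression(1, 1, seed = 1)
  expect_identical(dim(tiny$counts), c(1L, 1L))

  a <- simulate_expression(100, 12, seed = 5)
  b <- simulate_expression(100, 12, seed = 5)
  expect_identical(a$counts, b$counts)
  expect_identical(a$lengths, b$lengths)
  expect_true(all(a$counts >= 0) && all(a$lengths >= 1))

  tpm <- tpm_from_counts(a$counts, a$lengths)
  expect_true(all(abs(colSums(tpm) - 1e6) < 1e-3))
})

test_that("named substreams decouple the workflow stages", {
  s1 <- substream_seed(42, "reads")
  expect_identical(s1, substream_seed(42, "reads"))
  expect_false(s1 == substream_seed(42, "genome"))
  expect_false(s1 == substream_seed(43, "reads"))
  expect_lt(s1, 2^31)
})
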