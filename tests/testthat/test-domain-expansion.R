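test_that("build_count_matrix counts each protein once per domain", {
  totals <- c(spA = 100, spB = 100)

  # one protein with 3 hits to the same domain counts once
  ann <- data.frame(species = "spA", protein_id = "p1",
                    domain_accession = rep("PF001", 3))
  m <- build_count_matrix(ann, totals)
  expect_identical(m$counts["spA", "PF001"], 1L)

  # empty table -> all-zero matrix
  empty <- build_count_matrix(ann[0, ], totals)
  expect_true(all(empty$counts == 0))

  # 2 proteins x 2 shared domains + 1 protein with 1 domain
  ann2 <- data.frame(
    species = "spA",
    protein_id = c("p1", "p1", "p2", "p2", "p3"),
    domain_accession = c("d1", "d2", "d1", "d2", "d1"))
  m2 <- build_count_matrix(ann2, totals)
  expect_identical(m2$counts["spA", "d1"], 3L)
  expect_identical(m2$counts["spA", "d2"], 2L)

  # idempotent under row duplication
  m3 <- build_count_matrix(rbind(ann2, ann2, ann2), totals)
  expect_identical(m2$counts, m3$counts)

  expect_error(build_count_matrix(ann2, c(spB = 100)), "spA")
})

test_that("domain_count_matrix enforces count <= gene total", {
  counts <- matrix(c(5L, 200L), 1, 2,
                   dimnames = list("spA", c("d1", "d2")))
  expect_error(domain_count_matrix(counts, c(spA = 100)), "exceeds")
})

test_that("fisher_exact_2x2 matches the hypergeometric enumeration oracle", {
  expect_equal(fisher_exact_2x2(5, 95, 1, 99)$p_value,
               oracle_fisher_p(5, 95, 1, 99), tolerance = 1e-12)

  set.seed(202)
  for (i in 1:100) {
    tot <- sample(4:200, 1)
    a <- sample(0:tot, 1); b <- sample(0:(tot - a), 1)
    c <- sample(0:(tot - a - b), 1); d <- tot - a - b - c
    mine <- fisher_exact_2x2(a, b, c, d)$p_value
    expect_lt(abs(mine - oracle_fisher_p(a, b, c, d)), 1e-12)
  }

  # odds-ratio conventions
  expect_identical(fisher_exact_2x2(0, 10, 0, 10)$odds_ratio, 1)
  expect_identical(fisher_exact_2x2(5, 5, 0, 10)$odds_ratio, Inf)
  expect_identical(fisher_exact_2x2(0, 10, 5, 5)$odds_ratio, 0)
})

test_that("fisher_expansion_test builds the normalised 2x2 tables correctly", {
  counts <- matrix(c(10L, 10L, 10L,
                     0L,  5L,  5L,
                     0L,  0L,  0L),
                   nrow = 3, byrow = FALSE,
                   dimnames = list(c("focal", "bg1", "bg2"),
                                   c("same", "diff", "zero")))
  m <- domain_count_matrix(counts, c(focal = 100, bg1 = 100, bg2 = 100))
  res <- fisher_expansion_test(m, "focal")

  # identical focal and background rows with equal totals
  same <- res[res$domain == "same", ]
  expect_equal(same$odds_ratio, 1)
  expect_equal(same$p_value, 1)
  expect_identical(same$direction, "none")

  # all-zero domain
  zero <- res[res$domain == "zero", ]
  expect_equal(zero$p_value, 1)
  expect_identical(zero$direction, "none")

  # focal 0 vs background mean 5: a depletion
  diff <- res[res$domain == "diff", ]
  expect_identical(diff$direction, "down")
  expect_equal(diff$p_value, oracle_fisher_p(0, 100, 5, 95), tolerance = 1e-12)

  expect_error(fisher_expansion_test(m, "nope"), "focal")
})

test_that("bh_fdr reproduces the hand step-up calculation", {
  expect_equal(bh_fdr(0.03), 0.03)
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_fdr(rep(1, 5)), rep(1, 5))
  expect_error(bh_fdr(c(0.1, 1.2)), "\\[0, 1\\]")

  # monotone non-decreasing along sorted p, never above 1
  set.seed(44)
  p <- runif(200)
  q <- bh_fdr(p)
  o <- order(p)
  expect_true(all(diff(q[o]) >= -1e-15))
  expect_true(all(q <= 1))
})

test_that("call_expansions applies the q-threshold and direction gate", {
  res <- data.frame(domain = c("up_sig", "down_sig", "up_ns"),
                    focal_count = c(50L, 1L, 10L),
                    background_mean_count = c(10, 20, 9),
                    odds_ratio = c(5, 0.05, 1.1),
                    p_value = c(1e-6, 1e-6, 0.5),
                    direction = c("up", "down", "up"))
  called <- call_expansions(res, alpha = 0.05)
  expect_true(called$expanded[called$domain == "up_sig"])
  expect_false(called$expanded[called$domain == "down_sig"])  # contraction
  expect_false(called$expanded[called$domain == "up_ns"])
  expect_error(call_expansions(res, alpha = 1.5), "alpha")
})

test_that("planted 8-fold expansions are recovered by the full test chain", {
  exp_spec <- data.frame(domain = 1:10, species = 1, fold_change = 8)
  sim <- simulate_domain_counts(5, 500, baseline_rate = 5,
                                expansions = exp_spec, seed = 77)
  focal <- sim$matrix$species[1]
  called <- test_domain_expansion(sim$matrix, focal, alpha = 0.05)
  hits <- called$domain[called$expanded]
  expect_gte(length(intersect(hits, sim$truth$domain)), 8)
  expect_lte(length(setdiff(hits, sim$truth$domain)), 2)
})

test_that("domain_zscores standardises rows and is permutation-equivariant", {
  counts <- matrix(c(1L, 2L, 3L, 4L, 4L, 4L), nrow = 3,
                   dimnames = list(c("s1", "s2", "s3"), c("varying", "flat")))
  m <- domain_count_matrix(counts, c(s1 = 10, s2 = 10, s3 = 10))
  z <- domain_zscores(m)
  expect_equal(unname(z["varying", ]), c(-1, 0, 1))
  expect_equal(unname(z["flat", ]), c(0, 0, 0))
  expect_true(all(abs(rowMeans(z[c("varying"), , drop = FALSE])) < 1e-9))

  perm <- c("s3", "s1", "s2")
  z_perm <- domain_zscores(
    domain_count_matrix(counts[perm, ], c(s1 = 10, s2 = 10, s3 = 10)))
  expect_equal(z_perm, z[, perm])
})
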