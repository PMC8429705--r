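#' Species-by-domain count matrix
#'
#' Container for the expansion test: an ordered species set, per-species
#' total gene counts, and non-negative integer counts of proteins carrying
#' each domain. Because a protein contributes at most once per domain, every
#' count is bounded by its species' gene total; the constructor enforces
#' this invariant.
#'
#' @param counts species x domain integer matrix with row and column names.
#' @param gene_totals named positive integers, one per species (row).
#' @return object of class `domain_count_matrix` with fields `species`,
#'   `gene_totals`, `counts`.
#' @export
domain_count_matrix <- function(counts, gene_totals) {
  .check(is.matrix(counts) && !is.null(rownames(counts)) &&
           !is.null(colnames(counts)), "counts must be a named matrix")
  .check(all(counts >= 0), "counts must be non-negative")
  species <- rownames(counts)
  .check(all(species %in% names(gene_totals)),
         "every species needs a gene_total")
  gene_totals <- gene_totals[species]
  .check(all(gene_totals >= 1), "gene totals must be positive")
  over <- counts > matrix(gene_totals, nrow(counts), ncol(counts))
  if (any(over)) {
    w <- which(over, arr.ind = TRUE)[1, ]
    stop(sprintf("count for species '%s', domain '%s' exceeds its gene total",
                 species[w[1]], colnames(counts)[w[2]]), call. = FALSE)
  }
  structure(list(species = species, gene_totals = gene_totals,
                 counts = counts), class = "domain_count_matrix")
}

#' @export
print.domain_count_matrix <- function(x, ...) {
  cat(sprintf("domain_count_matrix: %d species x %d domains (gene totals %s-%s)\n",
              length(x$species), ncol(x$counts), min(x$gene_totals),
              max(x$gene_totals)))
  invisible(x)
}

#' Build a domain-count matrix from per-protein annotations
#'
#' A domain occurring multiple times within one protein is counted only
#' once: `count(species, domain)` is the number of distinct proteins of that
#' species containing the domain at least once. Duplicated annotation rows
#' are therefore harmless (the operation is idempotent under row
#' duplication).
#'
#' @param annotations data.frame with columns `species`, `protein_id`,
#'   `domain_accession` (e.g. from [read_domain_annotations()]).
#' @param gene_totals named per-species total gene counts; must cover every
#'   annotated species.
#' @return a [domain_count_matrix]. Species absent from the annotation but
#'   present in `gene_totals` get all-zero rows.
#' @export
build_count_matrix <- function(annotations, gene_totals) {
  .check(all(c("species", "protein_id", "domain_accession") %in%
               names(annotations)),
         "annotations needs columns species, protein_id, domain_accession")
  missing <- setdiff(unique(annotations$species), names(gene_totals))
  if (length(missing)) {
    stop("species missing from gene_totals: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  species <- names(gene_totals)
  domains <- sort(unique(annotations$domain_accession))
  m <- matrix(0L, length(species), max(length(domains), 1L),
              dimnames = list(species,
                              if (length(domains)) domains else "none"))
  if (nrow(annotations) && length(domains)) {
    u <- unique(annotations[, c("species", "protein_id", "domain_accession")])
    tab <- table(factor(u$species, levels = species),
                 factor(u$domain_accession, levels = domains))
    m <- matrix(as.integer(tab), nrow = length(species),
                dimnames = list(species, domains))
  }
  domain_count_matrix(m, gene_totals)
}

# ---- Fisher exact test for a 2x2 table, two-sided, log-space --------------

# cumulative log-factorial table, grown lazily and cached
.lfact_env <- new.env(parent = emptyenv())
.lfact <- function(n_max) {
  cur <- .lfact_env$table
  if (is.null(cur) || length(cur) < n_max + 1L) {
    .lfact_env$table <- cumsum(c(0, log(seq_len(max(n_max, 1024L)))))
  }
  .lfact_env$table
}

#' Two-sided Fisher exact test for a 2x2 table
#'
#' Direct implementation from the hypergeometric distribution: with fixed
#' margins, the probability of each admissible table is a ratio of
#' factorials, computed here from a cached cumulative log-factorial table so
#' the arithmetic stays exact-to-double for margins up to proteome scale
#' (~1e5). The two-sided p-value sums the probabilities of all tables no
#' more likely than the observed one (the standard `1 + 1e-7` relative
#' tolerance guards the equality comparison against rounding).
#'
#' @param a,b,c,d the 2x2 cell counts, rows = (focal, background),
#'   columns = (with domain, without domain).
#' @return list with `p_value` (in (0, 1\]) and `odds_ratio` (the sample
#'   odds ratio `ad/bc`, with 0/0 -> 1, x/0 -> Inf, 0/x -> 0).
#' @export
fisher_exact_2x2 <- function(a, b, c, d) {
  .check(all(c(a, b, c, d) >= 0) && all(c(a, b, c, d) == floor(c(a, b, c, d))),
         "cells must be non-negative integers")
  m <- a + b; n <- c + d; kk <- a + c; tot <- m + n
  lf <- .lfact(tot)
  lchoose2 <- function(nn, x) lf[nn + 1] - lf[x + 1] - lf[nn - x + 1]
  denom <- lchoose2(tot, kk)
  support <- max(0, kk - n):min(kk, m)
  logp <- lchoose2(m, support) + lchoose2(n, kk - support) - denom
  obs <- logp[support == a]
  sel <- logp <= obs + log(1 + 1e-7)
  mx <- max(logp[sel])
  p <- exp(mx + log(sum(exp(logp[sel] - mx))))
  p <- min(p, 1)

  or <- if (a * d == 0 && b * c == 0) 1 else if (b * c == 0) Inf else
    (a / b) * (d / c)
  list(p_value = p, odds_ratio = or)
}

#' Gene-total-normalised Fisher expansion test
#'
#' For each domain, the focal species' repertoire is compared against the
#' background, defined as the average of the remaining species. Gene totals
#' provide the normalisation by forming the margins of the 2x2 table:
#'
#' \preformatted{ [ focal count        , focal genes - focal count ]
#'  [ round(bg mean count), round(bg mean genes) - round(bg mean count) ]}
#'
#' with a two-sided Fisher exact p-value per domain. `background = "pooled"`
#' uses summed (rather than rounded mean) background counts and gene totals.
#' Direction compares the unrounded per-gene rates: `up` when the focal rate
#' exceeds the background rate, `down` when below, `none` when equal.
#'
#' @param matrix a [domain_count_matrix] with >= 2 species.
#' @param focal_species the species tested for expansion.
#' @param background `"rounded_mean"` (default) or `"pooled"`.
#' @return data.frame with one row per domain: `domain`, `focal_count`,
#'   `background_mean_count`, `odds_ratio`, `p_value`, `direction`.
#' @export
fisher_expansion_test <- function(matrix, focal_species,
                                  background = c("rounded_mean", "pooled")) {
  .check(inherits(matrix, "domain_count_matrix"),
         "matrix must be a domain_count_matrix")
  background <- match.arg(background)
  .check(length(matrix$species) >= 2, "need at least 2 species")
  .check(focal_species %in% matrix$species, "focal species not in matrix")

  cf <- matrix$counts[focal_species, ]
  Gf <- matrix$gene_totals[[focal_species]]
  bg_rows <- setdiff(matrix$species, focal_species)
  bg_counts <- matrix$counts[bg_rows, , drop = FALSE]
  mean_bg_count <- colMeans(bg_counts)
  mean_bg_genes <- mean(matrix$gene_totals[bg_rows])

  if (background == "rounded_mean") {
    bc <- round_half_away(mean_bg_count)
    bg <- round_half_away(mean_bg_genes)
  } else {
    bc <- colSums(bg_counts)
    bg <- sum(matrix$gene_totals[bg_rows])
  }

  nd <- ncol(matrix$counts)
  p <- numeric(nd); or <- numeric(nd)
  for (j in seq_len(nd)) {
    ft <- fisher_exact_2x2(cf[j], Gf - cf[j], bc[j], bg - bc[j])
    p[j] <- ft$p_value; or[j] <- ft$odds_ratio
  }
  focal_rate <- cf / Gf
  bg_rate <- mean_bg_count / mean_bg_genes
  direction <- ifelse(focal_rate > bg_rate, "up",
                      ifelse(focal_rate < bg_rate, "down", "none"))

  data.frame(domain = colnames(matrix$counts),
             focal_count = as.integer(cf),
             background_mean_count = as.numeric(mean_bg_count),
             odds_ratio = or, p_value = p, direction = direction,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjusted p-values (`q_(i) = min_{j >= i} min(1, p_(j) m / j)`),
#' returned in input order. Delegates to [stats::p.adjust()] after input
#' validation.
#'
#' @param p_values p-values in \[0, 1\].
#' @return q-values in input order.
#' @export
bh_fdr <- function(p_values) {
  .check(all(is.finite(p_values)) && all(p_values >= 0 & p_values <= 1),
         "p-values must lie in [0, 1]")
  stats::p.adjust(p_values, method = "BH")
}

#' Call expanded domain families at an FDR threshold
#'
#' A domain is called expanded when its BH-adjusted p-value is below `alpha`
#' AND its direction is `up` (significant depletions are contractions, not
#' expansions). Results are ordered by q-value, then descending odds ratio.
#'
#' @param test_results data.frame from [fisher_expansion_test()].
#' @param alpha FDR threshold in (0, 1), default 0.05.
#' @return the input with added columns `q_value` and `expanded`, reordered
#'   by (q_value, -odds_ratio).
#' @export
call_expansions <- function(test_results, alpha = 0.05) {
  .check(alpha > 0 && alpha < 1, "alpha must be in (0, 1)")
  out <- test_results
  out$q_value <- bh_fdr(out$p_value)
  out$expanded <- out$q_value < alpha & out$direction == "up"
  out[order(out$q_value, -out$odds_ratio), , drop = FALSE]
}

#' One-call expansion analysis
#'
#' Convenience wrapper chaining [fisher_expansion_test()], [bh_fdr()] (inside
#' [call_expansions()]) at the given threshold.
#'
#' @inheritParams fisher_expansion_test
#' @inheritParams call_expansions
#' @return see [call_expansions()].
#' @export
test_domain_expansion <- function(matrix, focal_species, alpha = 0.05,
                                  background = c("rounded_mean", "pooled")) {
  call_expansions(fisher_expansion_test(matrix, focal_species,
                                        background = match.arg(background)),
                  alpha = alpha)
}

#' Per-domain z-score matrix for heatmap display
#'
#' Each selected domain row is standardised across species — the number of
#' sample standard deviations each species' count lies from the row mean —
#' the quantity heatmap cell colours encode. Constant rows (zero SD) map to
#' all-zero rows.
#'
#' @param matrix a [domain_count_matrix] (or plain species x domain matrix).
#' @param domains subset of domain columns; default all.
#' @return domain x species numeric matrix; every non-constant row has mean
#'   0 and sample SD 1.
#' @export
domain_zscores <- function(matrix, domains = NULL) {
  counts <- if (inherits(matrix, "domain_count_matrix")) matrix$counts else
    matrix
  if (is.null(domains)) domains <- colnames(counts)
  .check(all(domains %in% colnames(counts)), "unknown domain selected")
  m <- t(counts[, domains, drop = FALSE])   # domain x species
  mu <- rowMeans(m)
  sdv <- apply(m, 1, stats::sd)
  z <- (m - mu) / ifelse(sdv == 0, 1, sdv)
  z[sdv == 0, ] <- 0
  z
}
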