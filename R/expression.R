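#' Transcripts-per-million normalisation
#'
#' Per sample: divide each gene's count by its effective length (here the
#' annotated transcript length, no fragment-length correction), then scale
#' the per-length rates so each sample column sums to one million. All-zero
#' samples stay all-zero, with a warning.
#'
#' @param counts gene x sample matrix of non-negative counts with row and
#'   column names.
#' @param effective_lengths named per-gene lengths in bp (> 0); must cover
#'   every gene in `counts`.
#' @return gene x sample TPM matrix (every non-degenerate column sums to
#'   1e6).
#' @examples
#' m <- matrix(c(10, 10), 2, 1, dimnames = list(c("g1", "g2"), "s1"))
#' tpm_from_counts(m, c(g1 = 1000, g2 = 2000))
#' @export
tpm_from_counts <- function(counts, effective_lengths) {
  .check(is.matrix(counts) && all(counts >= 0),
         "counts must be a non-negative matrix")
  missing <- setdiff(rownames(counts), names(effective_lengths))
  if (length(missing)) {
    stop("missing effective length for gene(s): ",
         paste(utils::head(missing, 3), collapse = ", "), call. = FALSE)
  }
  len <- effective_lengths[rownames(counts)]
  .check(all(len > 0), "effective lengths must be > 0")
  rate <- counts / len
  cs <- colSums(rate)
  zero <- cs == 0
  if (any(zero)) {
    warning("all-zero sample column(s): ",
            paste(colnames(counts)[zero], collapse = ", "))
    cs[zero] <- 1
  }
  sweep(rate, 2, cs, "/") * 1e6
}

#' Log-transform and row-scale a TPM matrix
#'
#' The heatmap-ready transform: `log2(TPM + 1)` per cell, then each gene row
#' centred and divided by its sample standard deviation across samples (the
#' behaviour of base R's `scale` applied gene-wise). Constant rows become
#' all zero.
#'
#' @param tpm gene x sample TPM matrix with at least 2 samples.
#' @return gene x sample matrix; non-constant rows have mean 0, sample SD 1.
#' @export
log_scale_matrix <- function(tpm) {
  .check(is.matrix(tpm) && all(tpm >= 0), "tpm must be a non-negative matrix")
  .check(ncol(tpm) >= 2, "row scaling needs at least 2 samples")
  l <- log2(tpm + 1)
  mu <- rowMeans(l)
  sdv <- apply(l, 1, stats::sd)
  z <- (l - mu) / ifelse(sdv == 0, 1, sdv)
  z[sdv == 0, ] <- 0
  z
}
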