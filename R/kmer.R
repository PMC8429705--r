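#' Construct a k-mer depth histogram object
#'
#' @param k odd k-mer size.
#' @param depth,count parallel vectors: depth (>= 1) and the number of
#'   distinct canonical k-mers observed at that depth.
#' @return object of class `kmer_histogram` with fields `k`, `depth`,
#'   `count`, `total_instances` (= sum of depth * count).
#' @export
kmer_histogram <- function(k, depth, count) {
  .check(length(depth) == length(count), "depth and count lengths differ")
  .check(all(depth >= 1), "depths must be >= 1")
  .check(all(count >= 0), "counts must be >= 0")
  o <- order(depth)
  structure(list(k = as.integer(k), depth = as.integer(depth[o]),
                 count = as.numeric(count[o]),
                 total_instances = sum(as.numeric(depth[o]) * count[o])),
            class = "kmer_histogram")
}

#' Count canonical k-mers in a read set
#'
#' Each length-k window is reduced to its canonical form — the
#' lexicographically smaller of the k-mer and its reverse complement — so
#' counting is strand-independent. Windows containing any non-ACGT base are
#' skipped. Returns the depth histogram (how many distinct canonical k-mers
#' were seen 1x, 2x, ...), the input for genome-size estimation.
#'
#' K-mers are 2-bit packed into IEEE doubles, which is exact for k <= 25;
#' the rolling window values are computed by convolution so counting a few
#' million windows stays fast in plain R.
#'
#' @param reads DNAStringSet or character vector of reads over {A,C,G,T,N}.
#' @param k odd integer in \[3, 25\] (odd so no k-mer equals its own reverse
#'   complement's position ambiguity at even k).
#' @param max_depth depths above this are collapsed into one overflow bin.
#' @return a `kmer_histogram`.
#' @examples
#' count_kmers(c("ACGTACGT"), k = 5)
#' @export
count_kmers <- function(reads, k, max_depth = 10000L) {
  seqs <- .as_sequence_chr(reads)
  .check(length(seqs) >= 1, "no reads supplied")
  .check(k >= 3 && k %% 2 == 1, "k must be odd and >= 3")
  .check(k <= 25, "k must be <= 25 (exact 2-bit packing in doubles)")

  # concatenate with 'N' separators: windows spanning read boundaries
  # contain N and are dropped automatically
  big <- paste(seqs, collapse = "N")
  code_of <- rep(NA_real_, 256)
  code_of[utf8ToInt("A")] <- 0; code_of[utf8ToInt("C")] <- 1
  code_of[utf8ToInt("G")] <- 2; code_of[utf8ToInt("T")] <- 3
  codes <- code_of[utf8ToInt(big)]
  if (length(codes) < k) {
    return(kmer_histogram(k, integer(0), numeric(0)))
  }

  # forward value of window ending at i: codes[i-k+1]*4^(k-1) + ... + codes[i]
  fwd <- stats::filter(codes, 4^(0:(k - 1)), method = "convolution", sides = 1)
  # reverse-complement value: (3-codes[i])*4^(k-1) + ... + (3-codes[i-k+1])
  rev <- stats::filter(3 - codes, 4^((k - 1):0), method = "convolution", sides = 1)
  canon <- pmin(as.numeric(fwd), as.numeric(rev))
  canon <- canon[!is.na(canon)]
  if (!length(canon)) return(kmer_histogram(k, integer(0), numeric(0)))

  kmer <- NULL; N <- NULL; depth <- NULL  # data.table NSE
  per_kmer <- data.table::data.table(kmer = canon)[, .N, by = kmer]
  per_kmer[, depth := pmin(N, max_depth)]
  hist <- per_kmer[, .N, by = depth]
  kmer_histogram(k, hist$depth, hist$N)
}

#' @export
print.kmer_histogram <- function(x, ...) {
  cat(sprintf("k-mer histogram (k = %d): %d distinct depths, %s k-mer instances\n",
              x$k, length(x$depth), format(x$total_instances, big.mark = ",")))
  invisible(x)
}

#' Estimate haploid genome size from a k-mer histogram
#'
#' The classic coverage-peak estimator: sequencing errors produce a spike of
#' low-depth k-mers, genuine genomic k-mers a peak at the k-mer coverage
#' depth. The error valley is the first local minimum of the (smoothed)
#' histogram; the peak is the raw-count argmax at or beyond the valley; and
#' the size estimate is the total k-mer mass beyond the valley divided by
#' the peak depth:
#'
#' `size = round( sum_{d >= valley} d * count[d] / peak_depth )`
#'
#' A single peak beyond the valley indicates a highly homozygous genome; a
#' second peak at roughly half the main depth indicates heterozygosity.
#'
#' @param hist a `kmer_histogram`.
#' @param smooth_window centred moving-average window (odd) used for valley
#'   and peak-count detection; suppresses shot-noise maxima.
#' @return object of class `genome_size_estimate`: list with `peak_depth`,
#'   `error_valley_depth`, `estimated_size_bp`, `n_peaks_detected`,
#'   `homozygosity_call` (`"homozygous-like"` iff exactly one peak).
#' @export
estimate_genome_size <- function(hist, smooth_window = 3L) {
  .check(inherits(hist, "kmer_histogram"), "hist must be a kmer_histogram")
  .check(length(hist$depth) >= 1, "histogram is empty")
  .check(smooth_window %% 2 == 1, "smooth_window must be odd")

  dmax <- max(hist$depth)
  dense <- numeric(dmax)
  dense[hist$depth] <- hist$count
  s <- as.numeric(stats::filter(dense, rep(1 / smooth_window, smooth_window),
                                sides = 2))
  s[is.na(s)] <- dense[is.na(s)]

  n <- length(s)
  valley <- NA_integer_
  for (v in seq_len(max(n - 1L, 1L))) {
    if (n == 1L) { valley <- 1L; break }
    if (s[v] <= s[v + 1L] && (v == 1L || s[v] <= s[v - 1L])) { valley <- v; break }
  }
  if (is.na(valley)) {
    stop("no error valley found before the histogram tail: the histogram is ",
         "monotone decreasing (error-dominated); cannot separate signal from error",
         call. = FALSE)
  }
  sel <- hist$depth >= valley
  if (!any(sel)) {
    stop("no k-mer mass at or beyond the error valley", call. = FALSE)
  }
  peak_depth <- hist$depth[sel][which.max(hist$count[sel])]
  # the signal peak must rise above the valley floor; a flat or still-falling
  # tail means the histogram is error-dominated
  if (n > 1L && max(s[valley:n]) <= s[valley] && valley > 1L) {
    stop("no peak rises above the error valley: error k-mers dominate; ",
         "increase coverage or filtering", call. = FALSE)
  }

  # local maxima of the smoothed curve at/beyond the valley; maxima below
  # 10% of the dominant peak are shot noise, not coverage components
  floor_h <- 0.10 * max(s[valley:n])
  n_peaks <- 0L
  for (i in valley:n) {
    left <- if (i == 1L) -Inf else s[i - 1L]
    right <- if (i == n) -Inf else s[i + 1L]
    if (s[i] > left && s[i] >= right && s[i] >= floor_h) n_peaks <- n_peaks + 1L
  }

  mass <- sum(as.numeric(hist$depth[sel]) * hist$count[sel])
  structure(list(
    peak_depth = peak_depth,
    error_valley_depth = valley,
    estimated_size_bp = round(mass / peak_depth),
    n_peaks_detected = n_peaks,
    homozygosity_call = if (n_peaks == 1L) "homozygous-like" else
      "heterozygous-like"), class = "genome_size_estimate")
}

#' @export
print.genome_size_estimate <- function(x, ...) {
  cat(sprintf(paste0(
    "Peak k-mer depth %d (error valley at depth %d), estimated haploid ",
    "genome length %s bp\n%d peak(s) detected: %s\n"),
    x$peak_depth, x$error_valley_depth,
    format(x$estimated_size_bp, big.mark = ","), x$n_peaks_detected,
    x$homozygosity_call))
  invisible(x)
}
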