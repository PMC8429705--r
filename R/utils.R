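#' Round half away from zero
#'
#' Rounds to the nearest integer with ties going away from zero, matching the
#' presentation of integer summary tables (base [round()] rounds half to even).
#'
#' @param x numeric vector.
#' @return numeric vector of rounded values.
#' @examples
#' round_half_away(c(0.5, -0.5, 2.5))
#' @export
round_half_away <- function(x) {
  sign(x) * floor(abs(x) + 0.5)
}

#' Derive a named substream seed from a global seed
#'
#' One global integer seed drives the whole workflow; each stochastic stage
#' draws from its own named substream so stages can be re-run independently
#' without perturbing each other.
#'
#' @param seed integer global seed.
#' @param stream character name of the substream (e.g. `"reads"`).
#' @return an integer seed below 2^31, deterministic in `(seed, stream)`.
#' @export
substream_seed <- function(seed, stream) {
  stopifnot(length(seed) == 1L, is.finite(seed), is.character(stream))
  ints <- utf8ToInt(stream)
  h <- sum(ints * seq_along(ints)) %% 65521
  as.integer((abs(as.numeric(seed)) * 48271 + h * 7919 + 1) %% 2147483629)
}

# internal: stop unless condition holds, with a caller-facing message
.check <- function(cond, msg) {
  if (!isTRUE(cond)) stop(msg, call. = FALSE)
}

# internal: coerce DNAStringSet/character to a character vector of sequences
.as_sequence_chr <- function(x) {
  if (inherits(x, "DNAStringSet") || inherits(x, "DNAString"))
    return(as.character(x))
  if (is.character(x)) return(x)
  stop("expected a DNAStringSet or character vector of sequences", call. = FALSE)
}

# internal: reverse complement of a plain character sequence
.revcomp_chr <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}
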