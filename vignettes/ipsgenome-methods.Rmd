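---
title: "Methods behind ipsgenome: assembly QC, k-mer genome size, and gene-family expansion statistics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods behind ipsgenome}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ipsgenome)
```

# Scope

`ipsgenome` packages, as one tested workflow, the statistical computations
that accompany a draft genome project for a bark beetle: summary statistics
of the assembly and its annotation, detection of telomeric repeats at contig
termini, k-mer-based estimation of the haploid genome size, a Fisher-exact
procedure for detecting expanded Pfam domain families against a multi-species
background, a standardized effect-size comparison of detoxification-gene
repertoires, and preparation of heatmap-ready expression matrices. Upstream
heavy lifting — long-read assembly, repeat masking, gene prediction,
orthology clustering, read alignment and quantification — is out of scope:
those tools' *outputs* (contigs, gene models, domain annotations, TPM tables)
are this package's *inputs*.

Because the real sequencing data are large and external, a synthetic-data
module generates every input with known ground truth. The test suite
validates each statistic either against published summary numbers whose
inputs are printed in full (the 12-species detoxification table), against
independent oracles (brute-force enumeration, closed forms), or against the
planted truth of simulations.

# The synthetic-data generator

`generate_genome()` draws an i.i.d. A/C/G/T sequence at a target GC fraction
(default 0.35, matching the beetle genome's composition). `fragment_genome()`
cuts it at uniform breakpoints, redrawing when a fragment falls below a
minimum length, and plants exact tandem telomere blocks — the motif on 5'
termini, its reverse complement on 3' termini — at each terminus
independently with probability 0.5, recording a truth table.
`simulate_reads()` samples fixed-length reads uniformly from the forward
strand (canonical k-mer counting makes strand irrelevant) with i.i.d.
substitution errors only: no indels and no quality model, because the only
consumer is the k-mer histogram.

`simulate_domain_counts()` draws null counts as Poisson with rate
`baseline_rate * gene_total_s / mean(gene_totals)`, so a species' expected
repertoire scales with its proteome size — the same normalisation the
expansion test undoes. Planted expansions multiply the rate of chosen
(species, domain) cells by a fold change > 1. Poisson, not negative binomial,
is a deliberate choice: it matches the implicit count model of a 2x2 exact
test on totals, and overdispersion is left as an extension. Default gene
totals are drawn from 13,000–24,000, the range spanned by published beetle
proteomes. `simulate_expression()` uses log-normal gene means, log-normal
library-size factors, and Poisson counts.

A single global seed feeds `substream_seed(seed, name)`, one named substream
per stage, so any stage can be re-run alone without perturbing the others.

What the generator does *not* emulate: repeats and heterozygosity in the
genome, read-length and error structure of real instruments, phylogenetic
correlation among species, and overdispersed domain counts. Passing tests
therefore demonstrate correctness of the *computations*, not robustness to
every property of real data.

# Assembly and annotation statistics

N50 is the length of the contig at which the descending-sorted cumulative
length first reaches at least half the assembly; L50 the number of contigs
needed to get there. When the cumulative sum lands exactly on half the total
at a contig boundary, that contig's length is the N50 (the `>=` convention of
common assembly tools). GC% excludes ambiguous bases from the denominator, so
it is a pure composition statistic; with N-free input the choice is
invisible, and with real assemblies it can move the second decimal.

Annotation statistics take 1-based inclusive gene/exon coordinates. Gene
length is `end - start + 1`; introns are the inter-exon gaps within a gene;
an exon outside its gene's span is a validation error naming the record. All
printed averages round to the nearest integer, half away from zero, matching
the convention of printed annotation tables (base R's `round()` would give
banker's rounding). `annotation_summary_stats()` exposes the same arithmetic
directly from aggregate inputs, so a printed table's gene count and total
gene length reproduce its derived averages without the GFF3.

The telomere scanner reports a terminus hit when at least `min_copies` exact
tandem copies of the motif (strand `forward`) or its reverse complement
(strand `reverse`) start within `window_bp` of a contig end, keeping the
single best run per terminus (most copies, then smallest offset). Defaults —
motif `TTAGG` (the ancestral insect telomeric repeat), `min_copies = 5`,
`window_bp = 1000` — are exposed as arguments; only exact copies count, with
degenerate-repeat tolerance deferred. The scan is exactly mirror-symmetric:
reverse-complementing the contigs swaps 5'/3' termini and forward/reverse
strands while preserving copies and offsets, a property the tests assert.

# K-mer histograms and genome size

`count_kmers()` reduces every length-k window to its canonical form (the
lexicographically smaller of the k-mer and its reverse complement) and skips
windows containing N. Implementation notes: k-mers are 2-bit packed into
doubles — exact for k <= 25, hence the cap — with the numeric order equal to
the lexicographic order, and the rolling window values are computed by
convolution, so counting millions of windows is fast without compiled code.
Reads are concatenated with `N` separators so boundary-spanning windows drop
out automatically. Depths are capped (default 10,000) into an overflow bin.

`estimate_genome_size()` is the transparent coverage-peak estimator, not a
mixture-model fit. The histogram is laid out densely over depth, smoothed
with a centred moving average (window 3) to suppress shot noise; the error
valley is the first local minimum of the smoothed curve; the peak depth is
the *raw* count argmax at or beyond the valley (raw, so that a degenerate
single-depth histogram returns that depth exactly); and

    size = round( sum_{d >= valley} d * count[d] / peak_depth ).

Peaks are counted on the smoothed curve beyond the valley, ignoring local
maxima below 10% of the dominant peak (shot-noise bins in the deep tail are
not coverage components); exactly one peak is called `homozygous-like`, more
than one `heterozygous-like`, the signature of a heterozygous k-mer
distribution being a companion peak near half the main depth. A histogram
that is still falling when it ends (error k-mers dominating) is an error
with a diagnostic, not a number.

This estimator deliberately omits what a genome-profiling mixture fit would
add (heterozygosity rate, repeat fraction); on simulated repeat-free genomes
at survey coverage it recovers the true size within a few percent, which the
tests assert at 50x with 0.5% error.

# The domain-expansion test

Per-protein domain annotations collapse so that a domain occurring multiple
times in one protein counts once; `count(species, domain)` is the number of
distinct proteins carrying the domain, which also bounds every count by its
species' gene total — an invariant the matrix container enforces.

For a focal species and each domain, the test builds the 2x2 table

    [ focal count,                  focal genes - focal count ]
    [ round(bg mean count),  round(bg mean genes) - round(bg mean count) ]

where the background is the average over the remaining species. The gene
totals *are* the normalisation: they form the table margins, so each row
compares a repertoire against the rest of its proteome, and the background
row uses the rounded mean count and rounded mean gene total (half away from
zero) to keep the table integer, as an exact test requires. A `pooled`
variant (summed background counts and totals) is available behind an
argument; rounded-mean is the default. The two-sided p-value comes from the
hypergeometric distribution, computed in log space from a cached cumulative
log-factorial table, exact-to-double up to proteome-scale margins; tests
check it against an independent enumeration oracle to 1e-12. The direction
gate compares unrounded per-gene rates, so a domain significantly *depleted*
in the focal species is a contraction, never an expansion call.

Multiple testing uses Benjamini–Hochberg step-up adjustment over all domains
in the matrix (the family includes domains absent from the focal species but
present elsewhere; restricting the family is a matter of subsetting the
matrix before testing). A domain is called expanded when its q-value is
below `alpha` (default 0.05) *and* its direction is up. Sample odds ratios
use the conventions 0/0 -> 1, positive/0 -> Inf, 0/positive -> 0.

Heatmap matrices standardise each selected domain row across species —
counts expressed as the number of sample standard deviations from the row
mean — with constant rows mapped to zero.

Simulation results in the test suite: with 10 domains planted at 8-fold
among 500 (rate 5, 5 species), at least 8 of 10 are recovered with at most 2
false positives in at least 45 of 50 seeds; under the null, at most 20% of
50 replicates produce any call at all. These sizes (500 domains, 5 species,
50 replicates) are the package's chosen simulation scale.

# Effect size

`hedges_g()` implements the bias-corrected standardized mean difference:
pooled sample SD with `df = n1 + n2 - 2`, `d = (mean1 - mean2) / pooled_sd`,
and `g = J d` with `J = 1 - 3 / (4 df - 1)` — the approximation conventional
in the effect-size literature; the exact gamma-ratio correction sits behind
`exact_j = TRUE` and differs by under 0.1% at realistic group sizes.

The default confidence interval inverts the noncentral t distribution: with
`nu = n1 n2 / (n1 + n2)`, the observed `t = d sqrt(nu)` has noncentrality
`lambda = delta sqrt(nu)` under a true standardized difference `delta`, and
the bounds are the `lambda` values whose tail probabilities at `t` equal the
interval's quantiles, divided by `sqrt(nu)`. The bounds are *not* shrunk by
J: J corrects the small-sample bias of the point estimate, while the
inverted interval is exact for `delta` itself. At very small, unbalanced n —
three against nine — this interval is noticeably wider than the closed-form
normal approximation (`g ± z * sqrt((n1+n2)/(n1 n2) + g^2/(2(n1+n2)))`),
which is also provided; the inversion is verified by plugging the bounds
back into the noncentral t CDF (tail probabilities reproduced to 1e-8).

The packaged 12-species detoxification table carries its printed "Total
numbers" row verbatim; the row sums reproduce it for all 12 species. One
known inconsistency in the source material is preserved rather than patched:
the accompanying text prints the scolytine mean as 327, while the table's
own values give 327.67, which rounds to 328. The test suite asserts the
computed value and documents the difference.

# Expression matrices

`tpm_from_counts()` uses the standard definition with effective length equal
to the annotated transcript length (no fragment-length correction — the
quantifier that would supply it is upstream of this package): per-length
rates scaled so every sample column sums to one million, making the measure
invariant to sequencing depth. All-zero samples stay zero with a warning.
`log_scale_matrix()` applies `log2(TPM + 1)` and then centres and scales
each gene row by its sample SD across samples (the behaviour of base R's
`scale()` applied gene-wise), mapping constant rows to zero. Replicate
averaging before scaling is not performed. The heatmap image is optional
output; the numeric matrix is the product.

# Numerical and degenerate-input conventions

* Rounding for presentation-layer integers: nearest, half away from zero.
* Fisher p-values: log-space, with the standard `1 + 1e-7` relative
  tolerance when comparing table probabilities to the observed one.
* Zero pooled SD with unequal means is an error (undefined effect), with
  equal means it yields g = 0.
* Empty contig sets, even k, non-ACGT motifs, coverage <= 0, fold changes
  <= 1, p-values outside [0, 1] and missing gene lengths are all rejected
  with input errors naming the problem.

# Limitations

The desk-scale simulations validate correctness, not performance at
hundreds of gigabases; k-mer counting is in-memory and exact, suitable for
genomes up to tens of megabases. The expansion test treats species as
independent observations, as the underlying procedure does — no
phylogenetic correction. The genome-size estimator will not resolve
heterozygous peaks that merge with the error spike at low coverage, and
reports an error rather than a guess when the histogram is error-dominated.
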