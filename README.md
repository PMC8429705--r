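# ipsgenome

Statistical workflow for bark beetle genome projects: assembly QC, k-mer
genome-size estimation, gene-family expansion testing, and repertoire
effect sizes.

Draft genome reports for non-model insects such as the Eurasian spruce bark
beetle (*Ips typographus*) rest on a recurring set of computations: contig
contiguity and composition statistics (N50/L50, GC%), annotation summaries,
telomeric-repeat scans that hint at chromosome-scale contigs, k-mer-based
haploid genome-size estimates, and comparative tests asking which protein
(Pfam) domain families are expanded in the new genome relative to other
species. `ipsgenome` implements that whole layer as ordinary, tested R
functions, with a synthetic-data module that generates every input with
known ground truth so the pipeline is verifiable without the underlying
sequencing data.

## The statistics at the core

* **Expansion test.** For focal species *f* and each domain, a 2×2 Fisher
  exact test on `[[c_f, G_f − c_f], [round(c̄_bg), round(Ḡ_bg) − round(c̄_bg)]]`,
  where `c` are domain counts (each protein counted once per domain), `G`
  gene totals, and the background is the mean of the remaining species —
  the gene totals are the normalisation, forming the table margins.
  Two-sided p-values from the hypergeometric distribution (log-space,
  exact-to-double), Benjamini–Hochberg FDR across domains, and a call rule
  of q < 0.05 *and* focal rate above background (depletions are
  contractions, not expansions). Row z-score matrices feed heatmaps.
* **Effect size.** Hedges *g* = *J·d* with pooled SD,
  `d = (x̄₁ − x̄₂)/s_pooled`, `J = 1 − 3/(4·df − 1)`, and a 95% CI from
  inverting the noncentral t distribution (a normal approximation is also
  available).
* **Genome size.** Canonical k-mer depth histogram (strand-independent
  counting, N windows skipped), error valley at the first smoothed local
  minimum, and `size = Σ_{d≥valley} d·count[d] / peak_depth`; one coverage
  peak ⇒ homozygous-like.
* **Assembly/annotation QC.** N50/L50 with the ≥-at-boundary convention,
  GC% excluding N, size-class summaries, gene/exon/intron averages rounded
  half-away-from-zero, and a terminus-windowed tandem telomere scanner
  (`TTAGG`, ≥5 copies within 1 kb by default).

## Worked example

The packaged table `detox_domain_counts()` holds the counts of eight
detoxification-associated Pfam families (P450s, GSTs, ABC transporters,
UDP-glucosyl transferases, carboxylesterases, ligand-gated ion channels,
cathepsin propeptide inhibitors) for three scolytine bark beetles and nine
other coleopterans. Comparing total repertoire sizes:

```r
library(ipsgenome)
tab <- detox_domain_counts()
res <- compare_family_totals(tab,
                             tab$species[tab$guild == "scolytini"],
                             tab$species[tab$guild != "scolytini"])
print(res$summary1)
#> 327.67 ± 37.58 (n = 3)
print(res$summary2)
#> 527.56 ± 125.86 (n = 9)
print(res$effect)
#> Hedges g = -1.6 (d = -1.756, J = 0.9231, pooled SD = 113.82)
#> 95% C.I. = -3.2 to -0.2 (noncentral_t)
```

The three bark beetles carry on average 200 fewer detoxification-family
proteins than the other nine species — a strong standardized effect
(g ≈ −1.6) whose wide interval reflects the tiny group sizes.

A fully synthetic run of the other stages (simulate → QC → genome size →
expansion test → expression matrices) lives in the numbered scripts under
`analysis/`; each writes its tables under `results/`. For example
`analysis/03_genome_size.R` estimates a simulated 500 kb genome from 60×
error-bearing reads to within ~2%, and `analysis/04_domain_expansion.R`
recovers 15/15 planted 6-fold expansions among 800 domains with zero false
positives.

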