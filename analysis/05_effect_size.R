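#!/usr/bin/env Rscript
# Stage 5: the detoxification-repertoire comparison on the packaged
# 12-species family-count table: totals per species, group summaries,
# Hedges g and its noncentral-t 95% CI.

suppressPackageStartupMessages(library(ipsgenome))

tab <- detox_domain_counts()
stopifnot(all(rowSums(tab[, detox_family_columns()]) == tab$total_printed))

scolytines <- tab$species[tab$guild == "scolytini"]
others <- tab$species[tab$guild != "scolytini"]
res <- compare_family_totals(tab, scolytines, others)

cat("scolytine totals:      "); print(res$summary1)
cat("other coleopterans:    "); print(res$summary2)
print(res$effect)

eff <- res$effect
utils::write.table(
  data.frame(group1_n = eff$n1, group1_mean = round(eff$mean1, 2),
             group2_n = eff$n2, group2_mean = round(eff$mean2, 2),
             pooled_sd = round(eff$pooled_sd, 2), d = round(eff$d, 4),
             J = round(eff$J, 4), g = round(eff$g, 4),
             ci_low = round(eff$ci_low, 2), ci_high = round(eff$ci_high, 2),
             ci_method = eff$ci_method),
  "results/effect_size_report.tsv", sep = "\t", quote = FALSE,
  row.names = FALSE)
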