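#!/usr/bin/env Rscript
# Hotelling-Williams comparison of the haplotype models against the
# in-block SNP model: the two accuracies share the adjusted phenotype, so
# the dependent-correlation t-test applies, per repeat on the pooled
# validation predictions.

library(hapblup)

cmp <- read.table("results/cv/model_comparisons.tsv", header = TRUE,
                  sep = "\t", check.names = FALSE)
print(cmp, row.names = FALSE)

sig <- cmp[cmp$p_mean <= 0.05, ]
if (nrow(sig)) {
  message(nrow(sig), " comparison(s) significant at alpha = 0.05:")
  for (i in seq_len(nrow(sig)))
    message("  r2 >= ", sig$r2_threshold[i], ": ", sig$model_alt[i],
            " vs ", sig$model_ref[i], " (mean p = ",
            signif(sig$p_mean[i], 3), ")")
} else {
  message("no comparison significant at alpha = 0.05")
}
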