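#!/usr/bin/env Rscript
# Mappability-corrected expression: effective transcript lengths from
# exact 50-nt window uniqueness, cRPKM per gene and tissue, expressed
# calls at cRPKM >= 10, tissue-specificity scores over 16 tissues, and
# the rank correlation of tissue specificity with disorder composition.

suppressPackageStartupMessages(library(disordAS))

data <- read_sim_dataset("results/simdata")
composition <- read_tsv("results/protein_composition.tsv")

eff_tx <- effective_lengths(data$expression$transcripts)
eff_gene <- setNames(eff_tx, data$expression$tx2gene[names(eff_tx)])
expr <- expression_table(data$expression$counts, data$expression$totals,
                         eff_gene)
tss <- ts_scores(expr)

write_tsv(expr, "results/expression.tsv")
write_tsv(tss, "results/ts_scores.tsv")

cat("effective lengths: median", median(eff_tx), "nt of",
    median(nchar(data$expression$transcripts)), "nt transcripts\n")
cat("expressed gene-tissue pairs:", sum(expr$expressed, na.rm = TRUE),
    "of", nrow(expr), "\n")
cat("tissue-breadth distribution (t):\n"); print(table(tss$t))

for (cls in c("flexible", "constrained")) {
  corr <- ts_disorder_correlation(tss, composition, cls)
  cat(sprintf("Spearman rho, TS score vs %s proportion: %.3f (p = %.2g, n = %d)\n",
              cls, corr$rho, corr$p, corr$n))
  write_tsv(corr$bins, sprintf("results/ts_%s_bins.tsv", cls))
}
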