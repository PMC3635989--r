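#!/usr/bin/env Rscript
# Phosphosite and linear-motif analyses: positional disorder-class
# profiles around phosphosites, feature enrichment per exon role against
# distal constitutive exons, and disorder rates inside versus outside
# features stratified by event label.

suppressPackageStartupMessages(library(disordAS))

data <- read_sim_dataset("results/simdata")
residues <- read_tsv("results/residue_classification.tsv")
phospho <- data$features[data$features$kind == "phosphosite", ]
motifs <- data$features[data$features$kind == "motif", ]

prof <- positional_profile(phospho, residues, window = 10)
write_tsv(prof, "results/positional_profile.tsv")
con <- prof[prof$category == "constrained_disorder", ]
cat("constrained-disorder profile peak at offset",
    con$offset[which.max(con$rate)], "over", nrow(phospho), "sites\n")

for (kind in c("phosphosite", "motif")) {
  sites <- if (kind == "phosphosite") phospho else motifs
  fr <- feature_rate_by_exon(data$exons, sites)
  write_tsv(fr$contrasts, sprintf("results/%s_exon_contrasts.tsv", kind))
  cat("\n", kind, "density by exon role (vs distal constitutive):\n")
  print(fr$contrasts, digits = 3)
}

strata <- rates_within_outside(data$exons, phospho, residues)
write_tsv(strata$rates, "results/feature_strata.tsv")
cat("\ndisorder rates inside/outside phosphosites in labelled A exons:\n")
print(strata$rates, digits = 3)
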