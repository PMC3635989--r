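#!/usr/bin/env Rscript
# GO-style enrichment of disorder classes over annotation terms, and the
# overlap-coefficient enrichment map (edges kept at coefficient >= 0.4).

suppressPackageStartupMessages(library(disordAS))

data <- read_sim_dataset("results/simdata")
composition <- read_tsv("results/protein_composition.tsv")

for (cls in c("flexible", "constrained")) {
  res <- go_term_enrichment(composition, data$annotations, cls)
  write_tsv(res, sprintf("results/go_enrichment_%s.tsv", cls))
  sig <- res[res$p_adjusted < 0.05, ]
  cat(cls, "disorder:", nrow(sig), "of", nrow(res),
      "terms enriched at FDR 0.05\n")
  if (nrow(sig)) print(sig, digits = 3)
  if (cls == "flexible" && nrow(sig) >= 1) {
    members <- split(data$annotations$protein_id, data$annotations$term_id)
    map <- build_enrichment_map(
      members[sig$term_id], setNames(res$p_adjusted, res$term_id))
    write_tsv(map$nodes, "results/enrichment_map_nodes.tsv")
    write_tsv(map$edges, "results/enrichment_map_edges.tsv")
    cat("enrichment map:", nrow(map$nodes), "nodes,",
        sum(map$edges$kept), "edges kept of", nrow(map$edges), "\n")
  }
}
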