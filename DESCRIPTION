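Package: disordAS
Title: Conserved Protein Disorder Classes Across Alternative Splicing Neighborhoods
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Classifies protein residues into constrained, flexible and
    non-conserved intrinsic disorder from ortholog multiple sequence
    alignments plus per-species disorder tracks, and quantifies how these
    classes, phosphosites, short linear motifs and recurrent somatic
    mutations distribute across tissue-specific and general cassette
    (alternative) exons and their flanking constitutive exons. Includes
    mappability-corrected expression (cRPKM) with a tissue-specificity
    score, driver/passenger recurrence classification, rank-sum and
    chi-squared enrichment statistics with Benjamini-Hochberg correction,
    overlap-coefficient enrichment maps, and a fully synthetic data
    generator with planted ground truth so every stage is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    stats,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
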