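# disordAS

Conserved intrinsic disorder comes in two regimes. In **flexible
disorder** the property of being disordered is positionally conserved
across orthologs while the amino-acid sequence has diverged; in
**constrained disorder** both the disorder and the sequence are
conserved. disordAS classifies every residue of a reference protein into
one of these regimes (or non-conserved disorder, or order) from an
ortholog multiple sequence alignment plus per-species disorder tracks,
and then asks where the regimes sit relative to alternative splicing:
cassette (A) exons that are tissue-specifically or generally included,
their flanking constitutive exons (C1, C2), distal constitutive exons,
and the rest of the proteome. Around that core it provides
mappability-corrected expression (cRPKM) with a tissue-specificity
score, phosphosite/linear-motif positional and per-exon enrichment,
driver/passenger classification of recurrent somatic mutations with
neighborhood enrichment tests, and GO-style enrichment with
overlap-coefficient maps. It is written for computational biologists who
want the full analysis replayable offline: a synthetic-data generator
with planted ground truth produces every input the pipeline consumes.

## The classification in brief

For column *n* of an alignment with *K* sequences, the identity fraction
is max_i a(i,n)/K (a(i,n) = sequences with amino acid *i*; gaps count in
*K* but are never a type) and the disorder fraction is the share of
non-gap rows whose residue carries the reference residue's disorder
state. A disordered reference residue is

* constrained disorder: disorder fraction ≥ 0.30 and identity ≥ 0.80
  (equivalently D ≥ 3 and A ≥ 9 on the 10-point bins);
* flexible disorder: disorder fraction ≥ 0.30, identity < 0.80;
* non-conserved disorder otherwise;

and an ordered reference residue is ordered. Drivers among somatic
mutation sites are those recurring in ≥ 5 samples from ≥ 3 studies or in
≥ 3 whole-genome-screen samples; the tissue-specificity score of a gene
expressed in *t* of *T* = 16 tissues (cRPKM ≥ 10) is (T − t)/(T − 1).

## Worked example

The numbered scripts under `analysis/` run the whole study on the
default synthetic configuration (seed 1): `01_simulate.R` writes the
dataset, `02`–`07` classify disorder, score expression, contrast exons,
profile features, test mutations, and build the enrichment map, each
writing its tables under `results/`.

```sh
Rscript analysis/01_simulate.R 1
Rscript analysis/02_classify_disorder.R
Rscript analysis/06_mutations.R
```

prints, among other lines:

```
simulated 40 ortholog groups ( 22 species each), 230 exon models, 810 features, 4626 mutation records
proteome proportions: constrained 0.042, flexible 0.150, nonconserved 0.048, ordered 0.760
mean cross-species disorder overlap: 56.5%
sites: 2000 ( 500 driver / 1500 passenger )
neighborhood vs rest: driver:passenger 0.781 vs 0.163, ratio-of-ratios 4.78, X2 = 195.7, p = 1.78e-44
enrichment direction stable across threshold grid {3..7}x{2..4}: TRUE
```

Reading: the classified proteome is ~24% disordered with flexible
disorder the largest conserved class; disorder assignments re-anchored
on a second species agree at 56% of disordered positions; and the
mutation generator's planted 5× driver recurrence inside C1/A/C2
neighborhoods is recovered as a driver:passenger ratio-of-ratios of 4.78
versus the rest of the exome, significant by an uncorrected chi-squared
test and directionally stable across recurrence-threshold choices.
`04_splicing_contrasts.R` likewise recovers the planted excess of
flexible disorder in tissue-specific A exons (Wilcoxon rank-sum,
BH-adjusted), and `03_expression_tissue_specificity.R` reports a
Spearman correlation of 0.765 between tissue specificity and flexible
disorder proportion under the default coupling.

A single call reproduces the whole pipeline programmatically:

```r
library(disordAS)
sim <- simulate_dataset(sim_config(seed = 1))
res <- run_pipeline(sim, "out")   # six-section report in out/report.txt
```

## Layout

* `R/` — classification, expression, splicing, features, mutations,
  statistics, IO, pipeline, and the synthetic-data generator
* `analysis/` — numbered narrative drivers (the study, end to end)
* `tests/testthat/` — unit, property and acceptance suites with
  brute-force oracles
* `vignettes/conserved-disorder-methods.Rmd` — models, assumptions,
  parameter choices and limitations
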