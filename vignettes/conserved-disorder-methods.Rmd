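---
title: "Constrained and flexible conserved disorder across splicing neighborhoods: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Constrained and flexible conserved disorder across splicing neighborhoods: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(disordAS)
```

## The problem

Intrinsically disordered regions (IDRs) of proteins lack a stable fold,
yet many are under strong evolutionary constraint. Comparing orthologs,
two distinct conservation regimes appear: regions where the *property*
of disorder is positionally conserved while the underlying sequence has
diverged ("flexible" disorder, typical of signaling and regulatory
segments), and regions where both disorder and the amino-acid sequence
are conserved ("constrained" disorder). disordAS implements a complete,
testable pipeline that (i) classifies each residue of a reference
protein into one of these regimes from an ortholog multiple sequence
alignment plus per-species binary disorder tracks, and (ii) quantifies
how the regimes — together with phosphosites, short linear motifs, and
recurrent somatic mutations — distribute across cassette-exon
alternative-splicing (AS) neighborhoods: the alternative exon (A), its
flanking constitutive exons (C1 upstream, C2 downstream), distal
constitutive exons, and the rest of the proteome.

## Residue classification model

For alignment column $n$ of a group with $K$ sequences, the identity
fraction is $\max_i a(i,n)/K$, where $a(i,n)$ counts sequences carrying
amino acid $i$ at column $n$. Gaps remain in the denominator but are
never a type, so a gappy column can only be less conserved. The disorder
conservation fraction is the proportion of non-gap rows whose residue
carries the same disorder state (disordered/ordered) as the reference
residue; gap rows drop from numerator and denominator because disorder
is undefined at a gap, and the classification is anchored on the
reference (human) residue.

A reference residue predicted disordered is:

* **constrained disorder** if its column is disordered in ≥ 30% of
  aligned residues *and* sequence-identical in ≥ 80%;
* **flexible disorder** if disordered in ≥ 30% but identical in < 80%;
* **non-conserved disorder** otherwise.

Ordered reference residues are **ordered**. Both thresholds are
inclusive and configurable (`disorder_threshold`, `identity_threshold`
in `run_config()`). For reporting, fractions are binned as
$D = \lfloor 10\,d \rfloor$ and $A = \min(10, \lfloor 10\,a\rfloor + 1)$
so that $D \ge 3 \iff d \ge 0.30$ and $A \ge 9 \iff a \ge 0.80$; the
classification itself always uses the fractions, the bins are derived
views. Per-protein compositions take the dominant category by maximum
proportion, with deterministic tie-breaking (constrained > flexible >
non-conserved > ordered).

Ortholog-group admission mirrors the upstream selection rules:
CCDS-mapped proteins with strictly more than 15 eukaryote orthologs,
one ortholog per species chosen by lowest BLAST e-value
(lexicographic id on ties) — see `filter_orthologs()`.

## Expression and tissue specificity

Read alignment is out of scope; the pipeline consumes per-gene,
per-tissue raw counts and recomputes mappability exactly: a 50-nt window
of a transcript is uniquely mappable when its sequence occurs nowhere
else in the transcript set, and the effective length is the count of
unique windows (at most $L - 49$). This is a deterministic,
oracle-checkable stand-in for alignment-based mappability that tolerates
no mismatches; real aligners allowing two mismatches would discard
slightly more windows. cRPKM divides counts per million mapped reads by
the effective length in kb; genes with effective length 0 are flagged
unmeasurable rather than given a value. A gene is called expressed at
cRPKM ≥ 10 (a conservative cutoff), and its tissue-specificity score
over $T = 16$ tissues is $(T - t)/(T - 1)$, which maps single-tissue
genes to 1 and ubiquitous genes to 0; genes expressed nowhere are
excluded. This normalization is the simplest one consistent with those
extremes; it is exposed as a parameter rather than hard-coded.
`ts_disorder_correlation()` relates the score to per-protein class
proportions by Spearman rank correlation with five equal-width score
bins for display.

## Splicing, feature and mutation analyses

Exons live in protein coordinates (1-based inclusive); a residue whose
codon is split across exons belongs to the exon holding the codon's
first nucleotide (`codon_interval()`). Per-exon summaries report
category proportions over classified residues and a gap rate (mean
per-column gap fraction). Group contrasts use the two-sample Wilcoxon
rank-sum test on per-exon proportions; contrasts against the proteome
background use a one-sample signed-rank test against the
residue-weighted background proportion, because the background is a
scalar (the dotted-line level), not a sample of comparable units.
P-values are Benjamini–Hochberg adjusted within each contrast family.

Feature analyses use set semantics (overlapping features count a residue
once). The positional profile pools, per offset $d \in [-w, w]$ with
default $w = 10$, the category rates at site + $d$, excluding offsets
outside the protein from numerator and denominator alike. The
within/outside stratification defaults to the modified residue itself
(halo 0), with a configurable ±k halo since the boundary between "at the
site" and "near the site" is a modelling choice.

Mutation records collapse to one per (sample, site); a site — keyed by
(gene, position, alternate amino acid), with (gene, position) keying as
a switch — is a **driver** when seen in ≥ 5 distinct samples from ≥ 3
distinct studies, or in ≥ 3 distinct samples from whole-genome screens
(guarding against targeted-panel ascertainment); every other site is a
passenger, so the calls partition sites exhaustively. Densities are
sites per 10 kb of region length; enrichment uses the 2×2
driver/passenger × neighborhood/comparison table, reporting the
driver:passenger ratio per region, their quotient, and an uncorrected
Pearson chi-squared test. The rank-sum normal approximation (used above
the exact-enumeration size of 16) applies tie and continuity
corrections, which keeps it within 0.02 of the exact tail at the
crossover size; the chi-squared test is uncorrected.

## The synthetic-data generator

Every input is generated with planted ground truth so the whole pipeline
is testable offline (`simulate_dataset()`):

* **Alignments.** Each reference residue receives a planted category;
  the category fixes a column model (reference disordered?, probability
  a non-reference row shares the disorder state, probability it carries
  the reference amino acid: defaults 0.90/0.95 for constrained,
  0.90/0.40 for flexible, 0.10/0.40 for non-conserved, 0.90/0.60 for
  ordered). Columns are independent; rows are independent given the
  column. Gaps arrive as per-species indel segments covering ~5% of
  columns (mean length 5); the reference row is never gapped. This makes
  the conservation fractions directly controllable, at the price of no
  phylogenetic correlation between species and no realistic indel
  evolution — recovery tests therefore certify the estimators, not
  robustness to tree structure.
* **Exons.** Events (C1, A, C2 adjacent, non-overlapping) and distal
  exons are placed left-to-right with small random margins; events that
  do not fit are skipped with a warning, never emitted partially.
  Default planted rates put flexible disorder at 0.50 in
  tissue-specific A exons versus 0.20 in general A exons, and
  constrained disorder at 0.30 in tissue-specific flanking exons versus
  0.05 elsewhere — the enrichment pattern the pipeline is designed to
  detect. Exon lengths default to 20–60 residues with at most 3 events
  per protein; these are configurable defaults, not estimates.
* **Features.** Phosphosites and motifs are Bernoulli-placed per residue
  with role-specific densities (flanking exons denser by default), or,
  under profile planting, phosphosites sit exactly at
  constrained-planted residues with flexible ±1..5 flanks — the
  configuration used to exercise the positional profile.
* **Mutations.** 2000 sites by default, 25% planted driver-like with
  recurrence at or above the thresholds by construction. The driver
  fraction is far above the ~1.5% seen in somatic catalogues; it was
  fixed at design time so that the ratio-of-ratios estimator at 2000
  sites has a log-scale sampling sd near 0.11, making the planted 5×
  neighborhood odds recoverable within ±20% in most runs. Driver and
  passenger positions are drawn without replacement within region pools
  so that site collisions cannot thin passengers preferentially inside
  neighborhoods (which would bias the ratio upward).
* **Expression.** One transcript per gene (600 nt, random sequence;
  optionally duplicated 50-nt blocks to exercise mappability). Counts
  are Poisson around a target cRPKM drawn above 20 in the gene's planted
  expressing tissues and below 5 elsewhere, so the cRPKM ≥ 10 call
  recovers the planted tissue breadth in ≥ 95% of genes. Tissue breadth
  is optionally coupled to planted flexible disorder (default coupling
  0.5) so the tissue-specificity correlation has signal to find.

Determinism: all stages draw from seeds derived from the master seed, so
identical (seed, config) pairs reproduce byte-identical outputs; every
written table embeds the package version and a config hash.

## Problem sizes and numerical choices

The default study configuration is 40 ortholog groups of 22 species with
proteins of 450–700 residues, 10 tissue-specific and 40 general events,
16 tissues, and 2000 mutation sites; recovery properties in the test
suite use 150 events per arm (300 proteins' worth of alignments) for the
splicing contrast, 100 seeded replicates for power statements, and 1000
replicates for null calibration of the contrast layer (fed with
binomially sampled per-exon proportions, since calibration concerns the
test, not the alignment generator). Wilcoxon tests enumerate the exact
null up to a pooled n of 16 and switch to the corrected normal
approximation beyond; alignment columns that are all gaps score identity
0 and are flagged unusable; exons with no classified residues are
dropped with a warning; empty contingency margins skip the test rather
than returning a spurious statistic.

## Known limitations

Orthology, alignments and disorder predictions are consumed, not
recomputed: any systematic error in those upstream tools propagates
untouched. The synthetic generator's independence assumptions (across
columns, species and sites) make planted effects easier to recover than
phylogenetically correlated real data; passing recovery tests shows the
estimators are correct and calibrated, not that real-data effect sizes
will match. Mappability is exact-match only; tissue-specific/general
event labels are inputs; and the GO analysis treats terms as flat sets
with no ontology propagation.
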