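---
title: "Detecting and dating tandem duplicate gene clusters with tandemscan"
author: "tandemscan maintainers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting and dating tandem duplicate gene clusters}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tandemscan)
```

## The problem

Tandem gene duplication — the local copying of a gene next to its parent —
is a major source of new genic material in plant genomes, and maize carries
thousands of such duplicates. Identifying them genome-wide from an
annotation is harder than it sounds: duplicate copies diverge over time,
later insertions separate them, annotations split or miss copies, and a
cluster of similar genes may be the footprint of one multi-gene duplication
(a *cassette*) rather than several single-gene events. `tandemscan`
implements a complete, testable pipeline for this analysis on a pair of
related genotypes: duplicate detection from sequence similarity between
proximal genes, cassette detection from interleaved coordinates, genomic
context (feature densities, a linear model of duplicate density, TE
containment and capture, GC content), molecular-clock dating against an
outgroup, cross-genotype comparison, and the filtering/decision scaffolding
for relative-rate tests. A seeded synthetic-genome generator stands in for
real assemblies so that every stage can be validated against planted truth.

## Duplicate detection

### Adjusted pairwise similarity

Candidate pairs are all same-chromosome gene pairs separated by at most 15
intervening genes (the default; the allowance absorbs post-duplication
insertions, misassembly and misannotation). For each pair the longest
transcript of each gene is translated — a single terminal stop codon is
trimmed, internal stops are kept as `X` and count as mismatches, and genes
with no in-frame transcript are excluded — and the two proteins are aligned
globally.

The similarity statistic down-weights alignment gaps:

$$ s_{adj} \;=\; \underbrace{\frac{n_{ident}}{n_{ungap}}}_{\text{identity in
aligned regions}} \times \underbrace{\frac{n_{ungap}}{n_{col}}}_{\text{ungapped
fraction}} \;=\; \frac{n_{ident}}{n_{col}} $$

where $n_{col}$ is the number of alignment columns, $n_{ungap}$ the columns
with a residue in both rows, and $n_{ident}$ the ungapped columns with
identical residues. Identity is undefined in gapped regions; two genes can
be nearly identical over a short conserved stretch yet unalignable
elsewhere, and the product corrects for exactly that. When every column is
gapped the score is defined as 0. Similarity is strict amino-acid identity,
not a substitution-matrix-weighted score; the matrix only shapes the
alignment itself.

Pairs scoring at least 0.3 become edges of a similarity graph whose
connected components (of two or more genes) are the tandem duplicate
clusters. A component may chain genes farther apart than the rank limit end
to end; each individual edge still respects it. Externally supplied
candidate clusters (e.g. from a synteny pipeline) are validated by the same
threshold and merged with the graph-derived clusters.

### The aligner

Pairwise alignment uses a global Needleman–Wunsch with BLOSUM62 and affine
gap penalties (opening 10, extension 0.5 — the scoring a practitioner would
get from `needle`), implemented in compiled code. A progressive aligner
with iterative refinement adds nothing for two sequences, and a
deterministic NW makes every score reproducible. Two numerical choices
matter:

* **Tie-breaking.** Among co-optimal alignments the recursion prefers a
  substitution over a gap in the second sequence over a gap in the first,
  at every cell. Because co-optimal alignments can differ in their column
  counts, pairs are canonicalized by sequence content before aligning, so
  $s_{adj}(a,b) = s_{adj}(b,a)$ exactly.
* **Cross-checking.** The implementation is validated in the test suite
  against `Biostrings::pairwiseAlignment` for score equality on random
  sequence pairs; the column bookkeeping is validated against hand-counted
  toy alignments.

With this scoring, unrelated random-codon proteins score $s_{adj} \approx
0.15$ (empirically < 0.26 over hundreds of thousands of simulated background
pairs), comfortably below the 0.3 threshold, while duplicates at up to 20%
nucleotide divergence score well above it.

## Cassettes

A cassette is a group of two or more clusters whose gene coordinates
interleave — the `A1 B1 A2 B2` pattern expected when a multi-gene block
duplicated as a unit. Two same-chromosome clusters are interleaved when at
least one gene of each lies strictly between two genes of the other (by
start coordinate; starts are unique after the load-time tie-break). A
cluster *fully nested* inside another's span is excluded even if its genes
fall between the host's genes: nesting is checked first, and only
interleaved links contribute. Clusters connected solely through a nested
relation are not merged. Cassettes are the connected components of the
interleaving relation. The test suite checks this implementation
exhaustively against a brute-force classifier over all coordinate
arrangements of 2–3 clusters (sizes 2–4) and randomized arrangements of up
to 6 clusters.

## Genomic context

Densities are computed in 1-Mb windows as the proportion of window bases
covered by the base-level union of features of a type (union keeps
proportions ≤ 1; the trailing partial window is normalized by its actual
width). RNA TEs are LTR + LINE + SINE; DNA TEs are TIR. Window subgenome
labels follow majority base coverage of the block assignment, with ties and
uncovered windows labelled nonsyntenic. The density model is ordinary least
squares:

$$ Y = \beta_0 + \beta_1 g + \beta_2 r + \beta_3 d + \beta_4 s + \varepsilon $$

with $Y$ tandem duplicate gene density, $g$ gene density, $r$ RNA TE
density, $d$ DNA TE density and $s$ the subgenome factor (maize1 as
reference). Term significance uses drop-one ANOVA of nested models, and an
optional gene-density × subgenome interaction can be compared by a nested
F test. A complementary test asks whether gene-dense windows carry a
disproportionate *share* of tandem bases: the Pearson correlation between
window genic proportion and the tandem share of genic bases (windows with
zero gene density are excluded; an exactly constant share is flagged
undefined rather than given a correlation).

TE relationships use full containment only (`bedtools intersect -f 1.0`
semantics): a gene *contains* a TE when the TE interval lies inside the
gene span, and is *captured* when its whole span lies inside a TE. Partial
overlaps are never classified, identical intervals resolve to *contains*,
and counts are gene-level (a gene with three contained LTRs counts once in
the LTR/contains cell).

## Dating

Duplication ages come from either source the analysis supports:

* **Dated trees.** The age of the most recent common ancestor of two tips
  is read directly off an ultrametric, time-calibrated tree.
* **Clock calibration.** From pairwise substitution distances:
  $\hat t = 12\,\mathrm{MY} \times d_{pair} / d_{outgroup}$, where 12 MY is
  the approximate maize–*Sorghum* divergence. Distances are Jukes–Cantor
  corrected p-distances over ungapped codon-alignment columns; unequal-
  length sequences are aligned at the protein level and back-translated.
  The estimator is scale-invariant and exact at the anchor
  ($d_{pair} = d_{outgroup} \Rightarrow 12$ MY).

Events are classified *ancient* at ≥ 10 MY and *recent* at ≤ 2 MY; ages
between fall in an explicit *intermediate* class. Duplications shared by
the two genotypes — homologous clusters with at least two members each;
copy-number differences do not break sharing — are deduplicated into one
event whose age is the mean of the genotype estimates. GC content
(ambiguity codes excluded from the denominator) supports the comparison of
ancient vs recent duplicates as a proxy check on GC-biased gene conversion.

## The synthetic genomes

`simulate_genotypes()` builds two genotypes whose defaults define the
simulated study conditions: 2 chromosomes × 5 Mb, 200 shared background
genes, 30 planted tandem clusters (sizes 2–4, mostly 2), three interleaved
cassette pairs, intervening genes for a minority of clusters, TE features
of all four classes, and maize1/maize2/nonsyntenic blocks. Key numerical
choices, made once:

* **Substitution model.** Jukes–Cantor on CDS sites at
  $r = 6.5 \times 10^{-3}$ substitutions/site/MY (a grass nuclear rate of
  $\sim 6.5\times10^{-9}$/site/yr), no indels. Copies planted at age $t$
  evolve independently from a common parent, so expected pairwise
  divergence is $2rt$ and the closed form
  $L \cdot \tfrac34 (1 - e^{-8rt/3})$ serves as an exact oracle for
  observed differences. Gap handling is exercised by hand-built alignments
  instead of simulated indels.
* **Ages.** A bimodal recent (≤ 2 MY) / ancient (≥ 10 MY) mixture with a
  minority of intermediate ages, capped so expected CDS divergence stays
  ≤ 20%. Multi-copy clusters use a star topology (all copies split from
  the parent at the cluster age).
* **Outgroups.** Each cluster gets an outgroup CDS that diverged from the
  cluster's ancestor 12 MY ago, with the ingroup lineage evolving
  $12 - t$ MY before duplicating, so the clock estimator is unbiased for
  $t$ by construction.
* **Gene models.** CDS lengths uniform over 100–200 codons (compact but
  realistic gene models that keep the synthetic genomes light); gene spans
  add a modest untranslated margin; single-exon status (25% of clusters)
  is carried as metadata with the CDS, introns are not materialized.
* **Layout.** Intergenic gaps are sized so genes spread over ~85% of each
  chromosome; background TEs are placed strictly intergenically, so the
  only gene-overlapping TEs are the planted contains/captured/partial
  configurations recorded in the truth ledger.
* **Sharing.** 38% of planted clusters are present in both genotypes
  (shared copies are sequence-identical, as inbred divergence is
  negligible on these timescales), which yields per-genotype shared
  fractions near the 50–60% range; the remainder are split between
  A-private and B-private.

What the generator deliberately does **not** emulate: indels and
alignment ambiguity in duplicate pairs, gene conversion between copies
(assumed negligible), realistic TE sequence content (TEs are labelled
intervals), intron sequence, and segmental rearrangement between
genotypes. Passing tests therefore demonstrate the correctness of the
pipeline's logic under a clean substitution-only model, not robustness to
annotation noise or conversion-driven similarity inflation in real
assemblies.

## Relative-rate scaffolding

The likelihood engines (codon-model and polymorphism/divergence fitting)
are external; `tandemscan` implements the decision layer that consumes
their output tables: orthogroup filtering (size 10–75, must contain
complete tandem clusters), codon-column gap filtering (≤ 50% gaps and ≥ 8
non-gap sequences, columns removed atomically; idempotent), LRTs of clade
models against the single-rate null (statistic clamped at zero, df = the
parameter difference taken from the table, no multiple-testing correction
across groups), omega-based constraint classification (foreground ω > 10
is untestable because dS is too small; otherwise above/below background ω
means weaker/stronger constraint, with exact equality flagged as a tie),
and the HKA window rule (a window where the selection model's \|lnL\|
exceeds the neutral model's lacks power and is not tested; otherwise an
LRT with df equal to the window's tandem gene count at α = 0.05).

## Problem sizes and determinism

All randomness in the package flows from explicit seeds; `run_all()` twice
with the same configuration writes byte-identical outputs (fixed-format
TSVs, stable orderings, a manifest without timestamps). The validation
suite runs the generator at its default study conditions across 50 seeds
for cluster recovery, 200 replicates for the regression calibration
(n = 500 windows), 100 replicates at 1,000 codons for dating, and
thousands of exhaustive coordinate arrangements for cassette detection —
sizes chosen as the package's own validation design.

## Known limitations

* Cluster membership is transitive; one promiscuous gene can bridge two
  otherwise distinct clusters.
* The clock estimator inherits the calibration's uncertainty wholesale; an
  age planted exactly on a class boundary (2 or 10 MY) is classified
  inconsistently by any unbiased estimator, which is why the intermediate
  class is explicit.
* The density model treats windows as independent (no spatial
  autocorrelation).
* Cross-genotype sharing is decided by any homologous link; many-to-many
  homologies make the per-genotype shared counts asymmetric by design.
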