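---
title: "Methods: cross-species accessibility and expression signatures"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: cross-species accessibility and expression signatures}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cellsig)
```

# Overview

`cellsig` identifies candidate "unicellular" and "multicellular" signature
genes by intersecting two layers of evidence over a set of conserved genes:
chromatin accessibility, compared across one stage-transitioning focal
organism and two reference organisms, and stage-exclusive expression in the
focal organism. This vignette describes the model behind each stage, the
parameters that matter, the numerical choices, and what the synthetic-data
tests do and do not demonstrate.

# Coordinates and containers

All internal coordinates are 0-based half-open, the BED convention; GFF3
(1-based closed) is converted at the file boundary and converted back on
write. A gene carries one model: where an annotation has several isoforms,
exons are collapsed to their interval union over the gene span. The TSS is
the 5' gene end on the gene's strand, the TTS the 3' end.

# Feature annotation and accessibility

The promoter of a gene is the `upstream = 1500` bases immediately 5' of the
TSS; the downstream window is the `3000` bases past the TTS, away from the
gene body. Both clip at sequence edges when lengths are supplied. A peak is
assigned the single highest-priority feature it overlaps by at least one
base, in the order promoter > exon > intron > downstream > intergenic.
Neither the priority source nor typical annotation tools specify behaviour
for ties *within* one class, so the package makes it deterministic: smallest
distance from the peak midpoint to the candidate gene's TSS, then
lexicographic gene id.

A gene is called *accessible* in a condition when at least one peak overlaps
its promoter (default), its gene body, or either, with replicate peak sets
merged by interval union first. The one-base overlap threshold is the
natural minimal criterion and is asserted by brute-force interval
enumeration in the tests. Promoter overlap is the default because the
signature analysis is promoter-centric; `gene_body` and `promoter_or_body`
support gene-body-level analyses. Note the promoter used for calls is
strictly upstream, while metagene profiles span the symmetric
±`window` around the TSS — the two windows intentionally differ.

Metagene profiles use binary per-base peak occupancy (not read depth — only
peak files are in scope), reversed for minus-strand genes so upstream is
always plotted left, averaged first over genes and then within fixed-width
bins. Values therefore live in [0, 1], and the profile of a union of
disjoint gene sets is the gene-count-weighted mean of the parts, which the
suite checks exactly.

# Expression enrichment

The chain mirrors standard count-based differential expression:

1. **Filter**: keep genes with CPM ≥ `min_cpm = 1` in at least
   `min_samples = 2` samples (any samples — the usual convention).
2. **TMM normalization**, authored in the package so the pipeline is
   self-contained. The reference sample is the one whose 75th-percentile
   count fraction is closest to the mean of that quantity. For each sample
   against the reference, genes zero in either are dropped; M (log2 ratio of
   count fractions) is trimmed 30% at each tail and A (mean log2 abundance)
   5% at each tail; the factor is 2 to the precision-weighted mean of the
   surviving M, weights the inverse asymptotic binomial variance; factors
   are rescaled to geometric mean 1. The tests require agreement with an
   independent implementation within 2% (observed: within ~0.1%).
3. **Equalization**: counts are linearly rescaled to the geometric mean of
   the effective library sizes and rounded. This is an approximation (a
   quantile-matching adjustment is out of scope) and is the one place the
   chain departs from exactness; it is documented rather than hidden.
4. **Common dispersion** by method of moments: per gene, the pooled
   within-group `(variance − mean)/mean²`, averaged over genes through the
   positive part and floored at zero. Deterministic and closed-form;
   genewise shrinkage is deliberately out of scope. On Poisson data the
   estimate sits below 0.02; at a true φ of 0.2 it lands in [0.1, 0.3].
5. **Conditioned NB exact test** per gene. Group sums of n samples with
   per-sample mean μ and dispersion φ are negative binomial with mean nμ and
   size n/φ. Conditioning on the total s, the two-sided p-value is the
   probability mass of all splits (k, s−k) whose probability does not exceed
   the observed split's, under equal per-sample means. At φ = 0 the
   conditional law is exactly binomial with success probability
   n_a/(n_a+n_b), and the implementation uses that form directly. Splits
   within a relative factor 1+1e-7 of the observed probability count as
   ties — the standard exact-test convention, without which mathematically
   tied splits computed in different floating-point orders break the
   binomial equivalence. The suite verifies agreement with an independent
   enumeration oracle to 1e-10 over all splits with s ≤ 30 and
   φ ∈ {0, 0.1, 0.5}, calibration under the null (raw p < 0.05 fraction in
   [0.02, 0.09] — exact tests run conservative-to-nominal), and ≥ 90% recall
   of 8-fold planted effects with ≤ 10% null calls at FDR 0.05.
6. **BH correction** (`bh_fdr()`, backed by `stats::p.adjust`), threshold
   `alpha = 0.05`; classes are `multicellular` / `unicellular` by the sign
   of the log2 fold change of group-mean CPM with a prior count of 0.5
   (avoiding log of zero), `even` otherwise.

The contrast pools all multicellular stages against the unicellular stage by
default; any stage subsets can be passed instead. The classifier processes
columns in their original matrix order whichever side is called
"unicellular", so swapping the group labels flips every class exactly.

# Signature set algebra

Over the conserved genes (one row per ortholog triplet; focal multicellular
accessibility is the union over multicellular stages; genes missing from a
call set count as inaccessible and are reported):

- unicellular parent = accessible in focal-unicellular;
- unicellular *shared* = parent ∧ (focal-multicellular ∨ multicellular
  reference);
- unicellular *exclusive* = parent ∧ unicellular-reference ∧
  ¬focal-multicellular ∧ ¬multicellular-reference;
- unicellular signature = exclusive ∧ expression class unicellular;

and the mirror image for the multicellular side. This reading of
"exclusively accessible" (within the parent set, requiring the same-side
reference and excluding both opposite-side call sets) is the only one
consistent with shared + exclusive < parent, leaving a remainder accessible
in the focal stage alone. Expression exclusivity uses the focal organism's
classes only; reference-organism expression filtering is a possible
extension, not implemented. Percentages are 100·count/parent, half-up
rounded to one decimal (half-up, not round-half-even: 333/720 = 46.25%
must print as 46.3).

The accessibility–expression association cross-tabulates unicellular- vs
multicellular-enriched genes against accessibility in the unicellular stage
only vs the multicellular stages only (both/neither excluded) and applies
the Pearson χ² without continuity correction; expected cells below 1 attach
a warning but still return the statistic.

# Motif enrichment

The module scans for one fixed consensus (default `CCATATATGG`, a MADS-box
binding site) by exact matching on both strands, reporting overlapping
occurrences; for palindromic motifs the two strands coincide and hits
collapse to one + hit. No IUPAC codes or PWMs — the target is a fixed
consensus, and de-novo discovery is out of scope. Enrichment counts regions
with ≥ 1 hit and applies a one-sided Fisher exact test, foreground hit rate
greater than background. The conventional background is all promoters, which
contains the foreground; the synthetic fixture tests therefore check power
both against that diluted background (pipeline test) and at the stated
planting rates on disjoint sets (40% vs 2%, n = 200 + 200, p < 1e-6).
GC-matched background correction is a known methodological difference and is
not reproduced.

# EM heterochromatin

A nucleus image carries a pixel matrix in [0, 1], a nucleus mask and a
nucleolus mask (masks are inputs — outlining is manual in practice). The
evaluation region is nucleus minus nucleolus. The "15% threshold" is
interpreted as 15% of the dynamic range above the evaluation-region minimum
(the percentage-threshold semantics of common image software); a pixel at or
below `min + 0.15·(max − min)` is heterochromatin, and a flat region yields
0%. The alternative reading — the darkest 15% of pixels — is available as
`mode = "quantile"`. Range-relative thresholding is invariant under affine
intensity rescaling, which the tests assert exactly. It is *not* globally
monotone under darkening single pixels (darkening the minimum lowers the
threshold); with the dynamic range anchored, monotonicity holds and is
tested in that regime. Batches report per-image percentages, group
mean ± sd, and a two-sided Welch t-test when exactly two groups are given.

# Synthetic data: what it emulates, and what it does not

The generator produces a three-species study: AT-rich focal genome
(GC 0.23, in line with the *Dictyostelium* genome) with one unicellular and
three multicellular stages at two replicates each, two reference genomes
(GC 0.36) with one peak set each, 500 conserved triplets by default, and 30
planted signature genes per side. Genes are laid out with intergenic gaps of
3200–4000 bp so promoter windows never collide; accessible genes receive a
200–400 bp promoter peak with jittered placement; counts are negative
binomial (φ = 0.05) around log-uniform means in [20, 2000] with 8-fold
planted stage effects and ±20% per-sample depth; motifs are planted in 40%
of multicellular-accessible promoters vs 2% elsewhere; nucleus images grow
dark clumps to exactly the planted fraction of the evaluation area before
Gaussian noise (σ = 0.03). Defaults were chosen once to represent a
realistic, clearly powered design and are not tuned per test.

Two generator properties are load-bearing for the closed-loop identity (the
master regression: on zero-noise fixtures the pipeline returns exactly the
planted signature sets):

- condition-level peak noise is applied before replication, so replicate
  union does not silently square away false negatives; and
- background conserved genes never draw a side-exclusive accessibility
  pattern (one reference flag is dropped when a draw would be exclusive).
  This matters because expression classes are *estimated* at FDR 0.05: a
  statistically expected false-positive call on an exclusive-pattern
  background gene would otherwise create a spurious signature gene, and the
  identity could not hold even with noise-free peaks.

Everything is a deterministic function of the configuration seed, with fixed
sub-seed offsets per stage so each generator can be re-run independently.

What passing these tests does **not** show about real data: peaks here are
clean rectangles in disjoint promoters, whereas real ATAC peaks overlap
features ambiguously; counts have a single common dispersion, no outliers
and no batch structure; ortholog maps are noiseless; motif background
composition is uniform at fixed GC; images contain no imaging artifacts.
The suite demonstrates correctness of the algebra and the statistics, not
robustness to every failure mode of real experiments.

# Problem sizes and runtime choices

The shipped tests use fixtures of 60–600 genes (500–1000 for the enrichment
and calibration checks, 2000 for null simulations, 1000 peaks × 100 genes
for the annotation oracle), sizes at which every check is decisive yet the
whole suite completes in about a minute; the acceptance script's fixture is
600 genes / 500 conserved with 30 + 30 planted signature genes.

# Known limitations

- The exact test uses a single common dispersion; genewise/shrunken
  dispersions and GLM-based testing are out of scope by design.
- Pseudo-count equalization is linear rescaling with rounding, an
  approximation to quantile-based equalization.
- One gene model per gene; transcript-level annotation is not performed.
- narrowPeak summits are parsed but unused (whole-peak overlap semantics).
- Reference-organism expression evidence does not enter the signature
  filter; only their accessibility does.
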