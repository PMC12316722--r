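---
title: "Methods: dosage typing, junction discovery and breakpoint statistics for ring minichromosomes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: ring minichromosome workflow}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's account of its science: the models and
procedures, the parameters that matter, what the synthetic generator does
and does not emulate, and the choices made where the design was genuinely
open. It states no empirical result that the test suite or the analysis
scripts do not themselves compute.

## The system being modelled

A ring minichromosome is a circular derivative of a normal chromosome that
retains an active centromere. In the pedigree this package models, the mini
derives from a ~6 Mb window of one chromosome (the "mini region"), spanning
the ~2 Mb centromere; a rearranged form additionally lacks a ~1.3 Mb
interval overlapping half the centromeric array, and carries a handful of
novel adjacencies confined to the mini region. Individuals carry zero, one
or two copies of either form — six structural classes in all — and copy
number is strictly integer: a mini is either present on a chromatid or not,
so read-depth dosage is "distinctly single or double, never intermediate".

All genomic extents are mapped to a toy scale by a single linear factor
(default 0.1 against Mb coordinates): a 2 Mb chromosome with mini region
1.3–1.9 Mb, centromere analog 1.5–1.7 Mb, deletion analog 1.6–1.73 Mb, and
enrichment control region 1.3–2.0 Mb. Bin sizes for dosage profiles scale
with the genome (2.5 kb and 10 kb, analogs of 25 kb and 100 kb); read-level
parameters do not (150 bp paired-end reads, 2 kb split-segment separation,
5 kb pseudo-junction bins, 1 kb / 10 kb enrichment windows), because they
control resolution relative to reads and annotation, not genome extent.

## Dosage model

With bin count $s_b$ in the sample and $c_b$ in a non-carrier control,

$$\mathrm{dosage}(b) = 2\,\frac{s_b / \tilde s}{c_b / \tilde c},$$

where $\tilde s$, $\tilde c$ are per-sample scale factors. The euploid
expectation is pinned at 2, so $n$ extra copies of a region read as $2+n$.

**Scale-factor choice.** On a real genome the scale is effectively the
total read count: the aneuploid segment is a few percent of the genome and
cannot move the total. On the toy genome the mini region is ~30% of the
chromosome, and a carrier's own mini reads would inflate a total-read scale
by up to 15%, deflating euploid bins to ~1.8 and the one-copy gain to ~2.6
— contradicting the convention the analysis is built on. We therefore scale
by the **median bin count**, and in the pipeline additionally exclude
mini-region bins from the scale estimate. At real scale this is numerically
indistinguishable from total-read scaling; at toy scale it keeps euploid
bins at 2.000 ± sampling noise. Bins with zero control coverage are flagged
missing, never zero.

**Typing.** Each of the six structural classes implies a two-level dosage
template over the mini region: retained level $2 + n_{full} + n_{del}$,
deletion-interval level $2 + n_{full}$. A sample is assigned to the
template minimizing the mean absolute deviation over mini-region bins;
samples with more than 20% missing mini bins are unclassifiable. Template
matching is the primary classifier; the PCA + Ward clustering of coarse-bin
profiles (cluster count by mean silhouette over $k \le 8$) is exploratory,
because the source analysis reports pattern-based PCA clusters without
stating how clusters were labelled. At 10× the per-bin noise is ~0.2
dosage units against template separations of 1.0 averaged over ~240 bins,
which is why typing is effectively error-free (the tests assert 18/18).

**Deletion-dip estimator.** The deleted interval is recovered as the
maximal run of consecutive mini-region bins whose dosage sits more than 0.5
units (half a copy step) below the retained level, at least 2 bins long.
Two numerical safeguards: the retained level is the upper quartile of
mini-region bins (the dip itself is ~20% of them and would bias a median),
and the track is smoothed with a 3-bin rolling mean so a single noisy bin
at 10× does not split a real dip. On a clean step profile the smoothing is
exact to within one bin; the tests assert Jaccard ≥ 0.8 against truth.

## Junction discovery

A junction candidate needs a read whose alignment splits into two segments
mapping at least 2,000 bp apart (boundary inclusive, the source criterion).
Breakpoints sit at the clipped segment ends; each breakpoint records which
flank the alignment retains, and the two retained flanks determine the
orientation class: colinear (head-to-tail, both directions folded
together), two tails (tail-to-tail), two heads (head-to-head). Evidence
agreeing within 10 bp on both sides, with equal sides and orientation, is
merged; the candidate position is the member median. The 10 bp tolerance
and the per-sample support tallies are our choices; the source reports
junctions, not its clustering rule.

**Pseudo-junction threshold.** The minimum cross-junction support is
estimated from the sample itself: boundaries between consecutive 5 kb bins
are ordinary loci that every chromosome copy crosses, so the mean count of
reads whose primary alignment spans a boundary, divided by 2 (diploid
genome, junction expected on one copy), is the support an honest one-copy
junction should attain. "Average read coverage" at a boundary is
interpreted as the boundary-spanning read count, since that is the quantity
a junction's supporting evidence is drawn from. Thresholds are per-sample;
a candidate is accepted iff some carrier reaches its own threshold **and**
support is exactly zero in every control.

A structural note the tests encode: expected split support for a junction
on $c$ mini copies is $\approx 0.74\,c\,D/2$ at depth $D$ (the 0.74 is the
fraction of crossing reads with ≥ 20 bp anchors on both sides), while the
realized threshold is at least $D/2$ — both scale with depth, so the
support/threshold margin is bounded by ~1.5 and recall guarantees are only
meaningful for two-copy junctions with several carriers, which is how the
acceptance test is constructed (depth 26, the study's resequencing depth).

## Synthetic data

`build_mini()` composes the mini as an oriented segment walk over the mini
region: the full form is the region excised and circularized (one novel
adjacency, the circularization site); the deleted form lacks the deletion
interval and applies each extra junction as one walk event, so the truth
junction count is exactly 1 + 1 + n\_extras. Orientations are pairwise
constrained — a tail-to-tail flips the walk to the minus strand and must be
closed by a head-to-head before the ring can close — and infeasible walks
raise invalid-configuration errors. The default extras are one inverted
30 kb block (its two adjacencies), so default cohorts exercise all three
orientation classes.

`simulate_individual()` emits the background genome at two copies and each
mini copy at one copy (expected dosage $2 + c$ in the retained region),
fragments Normal(400 bp, sd 40) truncated at the read length, reads
error-free by default (substitution rate configurable; sequencing error is
not this model's subject). Junction-crossing reads become a primary plus
supplementary alignment with soft clips and SA tags — what a real aligner
emits and what the detector consumes — provided both anchors reach 20 bp
(shorter pieces are dropped as unmappable, as an aligner would). Reads from
the mini carry the mini-haplotype allele at every diagnostic SNP (default
density 1/500 bp, an inbred-cross figure). Identical seeds give
byte-identical SAM.

What the generator does **not** emulate — and hence what a green test does
not establish: mapping ambiguity in repeat arrays (the reason the source
could not recover the centromeric-array deletion junction), GC/mappability
bias, PCR duplicates, indels and soft-clip noise, and background structural
variation. Specificity results ("zero false junctions in controls") are
statements about the filters, not about repeat-mapping artifacts.

## Validation and haplotype assignment

Cross-junction reads of an accepted candidate (from the best-supporting
carrier, matching per-line extraction) are assembled by strand-aware greedy
merging on maximal exact suffix–prefix overlaps ≥ 20 bp, with deterministic
lexicographic tie-breaks; reads contained in longer sequences are absorbed.
A bespoke assembler replaces an external assembly binary deliberately: the
problem is desk-scale (tens of error-free 150-mers spanning one junction),
and the greedy result is checked against exhaustive merge-order search in
the tests.

Validation aligns the contig (both strands, local alignment, match 1 /
mismatch −2 / gap open 4, extend 1) against the expected chimeric reference
construct: 150 bp of retained flank on each side of the junction in the
junction's orientation. Validated means the alignment spans the chimeric
point with ≥ 30 aligned bases and ≥ 0.95 identity on each side — the
both-ends-align rule with a ±150 bp placement window; a contiguous
reference slice can anchor only one side and always fails. Anchor length,
identity cutoff and window are our choices; the source states none of them.

Haplotype assignment inspects the supporting reads and their mates within
1 kb of either breakpoint, tallies bases at diagnostic SNP sites, and calls
the mini haplotype only when ≥ 2 reads carry mini alleles and none carries
the background allele (symmetrically for background; anything else,
including zero reachable SNPs, is indeterminate). Junctions without
reachable SNPs stay indeterminate in our synthetic runs too — the same
outcome the source reports for 9 of its 20 breakpoints.

## Breakpoint enrichment

Feature density of a breakpoint is the fraction of covered bases in
$[pos - w/2, pos + w/2)$, computed on merged intervals (no double-counting)
with end-truncation adjusting the denominator. The null draws 10,000
uniform pseudo-breakpoints in the control region and records the mean
density, 1,000 times; the enrichment ratio divides the real breakpoints'
mean density by the null grand mean, so ratio > 1 iff real mean > null mean
by construction. Significance is a two-sided one-sample t-test of the
per-breakpoint real densities against the null grand mean: the "sample set
vs population set" wording is ambiguous about what varies in the test, and
testing the per-breakpoint densities against the (precisely estimated) null
grand mean is the reading that makes the t-test well-posed with n = number
of breakpoints. When all real densities are identical the variance is
degenerate and p is reported as 1 with a warning. Both breakpoints of each
junction enter independently. The gene-disruption probability is an
upper-tail binomial with success probability the gene-body base fraction of
the region; a permutation alternative would differ only in third-decimal
places at these sizes. Calibration (ratio 1.0 ± 0.05 under uniform
placement, t-test size in [0.02, 0.08], recovery of a constructed 2×
signal) is asserted over 200 seeds in the acceptance tests, with null sizes
scaled down (150 × 400) purely for runtime; the statistic is unchanged.

## Degenerate inputs and numerical conventions

Coordinates are 1-based inclusive internally, SAM convention on output,
BED half-open on disk (conversion via rtracklayer). Empty alignment sets
give all-zero coverage vectors, not errors; zero-control bins are missing;
an empty junction set makes the orientation test an error (undefined), and
fewer than two breakpoints make the enrichment t-test an error (no
variance). All randomness flows from explicit integer seeds; derived
per-sample seeds are drawn below $2^{31}$.

## Known limitations

Single-chromosome toy world (multi-chromosome SAM is parsed, but the
generator emits one chromosome); no GC or mappability correction; no
read-pair (discordant-insert) signal — split reads only, as in the source
analysis; the assembler assumes low error rates; haplotype calls need
diagnostic SNPs within 1 kb of a breakpoint and stay indeterminate
otherwise; and headline counts of the real study (25 candidates, 10
validated junctions) depend on the deposited sequencing data and are not
reproducible from synthetic cohorts — the package reproduces the *methods*
and their calibration, not those counts.
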