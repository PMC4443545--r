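---
title: "Counting genomic scars of homologous recombination deficiency"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Counting genomic scars of homologous recombination deficiency}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(scarscore)
```

## The data model

`scarscore` consumes allele-specific copy-number segment profiles: per
tumor, a table of segments `(chrom, start, end, n_major, n_minor)` with
integer allele counts `n_major >= n_minor >= 0`, plus the sample's ploidy
(average copies per locus) and aberrant cell fraction (ACF), as estimated
upstream by an allele-specific segmentation method such as ASCAT. The
package deliberately starts *after* segmentation: probe-level
normalization, BAF adjustment and model fitting are out of scope, which is
what makes the counting rules testable in isolation.

Internal coordinates are 0-based and half-open, so `length = end - start`
with no off-by-one corrections anywhere; `read_segments(one_based = TRUE)`
converts the common 1-based inclusive dialect on ingest. Segments separated
by an uncovered gap (probe dropout) are never merged and contribute to
denominators only through covered length. Sex chromosomes are accepted on
input but excluded from every signature and metric by default
(`include_sex = TRUE` overrides): the signatures were defined on autosomes,
and allele-specific states on X/Y are ambiguous by sex.

Before any counting, profiles are canonicalized with
`merge_adjacent_equal()`, which fuses abutting equal-state segments. All
counters are therefore invariant to how finely an upstream segmenter split
a constant-state region — a property the test suite checks directly.

## The three signature counters

**NtAI.** For each autosome, the *major copy state* is the allele-specific
state covering the greatest total length among segments with total copy
number above zero. A chromosome-end event is counted when the terminal
covered segment (its outer boundary is the outermost covered coordinate —
array coverage never reaches the physical telomere, so coverage ends stand
in for telomeres) lies fully within one arm, is allelically imbalanced, and
deviates from the major copy state. Requiring deviation from the major
state, rather than from balance, is what keeps a triploid chromosome with
an interstitial event from being over-counted. Segments overlapping the
centromere interval are disqualified, so a whole-chromosome aberration is
never an NtAI event. Ties in the major-state tally are broken
deterministically: greatest length, then lower total copy number, then
lower `n_major`. No minimum event size is imposed by default; `min_tai`
exists for sensitivity analysis.

**LST.** Segments are split at the centromere into arms (the slice inside
the centromere interval is dropped; centromeric probes are unreliable and
arm-interior boundaries are unaffected). Each arm is smoothed: segments
strictly shorter than 3 Mb (`min_keep`) are removed, shortest first
(leftmost on ties), and the flanks of a removed segment are joined when
they carry the same state and end up closer than 3 Mb, iterating to a fixed
point. A transition is then counted at every boundary between
differing-state neighbours that are both at least 10 Mb (`min_flank`,
inclusive) long and separated by less than 3 Mb (`max_gap`, strict). The
boundary conventions — `>=` for flank length, `<` for removal and gap —
follow the published 10 Mb / 3 Mb protocol.

**HRD-LOH.** Abutting segments with `n_minor == 0` and `n_major >= 1` are
merged into LOH regions regardless of internal copy-number changes (LOH is
about allele identity, not dosage). A region is counted when strictly
longer than 15 Mb (`min_loh`) and not spanning the entire covered extent of
its chromosome. Homozygous deletions `(0,0)` are total loss rather than
retention of one parental allele: they neither extend an LOH run nor fuse
two runs — the published definitions are silent here, and this is the
package's documented choice. Chromosome 17 is included by default; passing
`exclude_chroms = "chr17"` restores the original HRD-LOH behaviour, and
exclusion can only lower the score (tested as a monotonicity property).

**Breakpoint bookkeeping.** For the overlap (Venn) analysis, each event
records the subset of its region boundaries that are internal segmentation
boundaries: coverage ends and centromere-adjacent boundaries of telomeric
or whole-arm events are excluded, and an LST contributes exactly the one
counted boundary. Breakpoint identity across signatures is exact `(sample,
chrom, position)` equality, legitimate because all three counters run on
the same segmentation of the same sample. `venn_fractions()` partitions the
union into the seven exclusive regions as percentages, which sum to 100 by
construction.

## Auxiliary metrics and cohort statistics

wGII takes the rounded sample ploidy (half-up at .5) as the "normal" total
copy number, computes per autosome the fraction of *covered* length
deviating from it, and averages the fractions unweighted across autosomes.
FLOH is the covered autosomal length with `n_minor == 0` over total covered
autosomal length. Both use covered-length denominators so probe-sparse
regions do not dilute the fractions; this convention is fixed and stated
here rather than configurable. Nmut counts substitutions, indels, and
dinucleotide mutations; missing mutation data yields `NA`, never a silent
zero. The DNA index is ploidy / 2, with a strict `> 1.2` calling
near-tetraploid, so an index of exactly 1.2 remains near-diploid.

Cohort QC excludes samples with ACF strictly below 0.36 (exactly 0.36 is
retained). Group summaries report linear-interpolation quartiles, and the
ranking of groups averages per-signature *ranks* of medians rather than raw
medians, since the three scores live on different scales. Spearman's rho is
computed on average ranks with pairwise-complete deletion, returning `NA`
on zero rank variance. The Wilcoxon rank-sum test enumerates all group
assignments of the observed tie-averaged ranks exactly for combined n of at
most 12 (enumeration remains valid under ties, which the closed-form exact
distribution does not) and otherwise uses the tie-corrected normal
approximation with continuity correction. Fisher's test reports the sample
(cross-product) odds ratio `(a d)/(b c)` — not the conditional MLE — with
the two-sided p obtained by summing hypergeometric probabilities no larger
than the observed table's.

## The simulator and what it does (not) emulate

`simulate_profile()` implants a requested number of events of each scar
class into an all-`(1,1)` diploid genome on a 22-autosome annotation with
approximate human chromosome lengths and centromeres. Each event gets its
own chromosome arm; telomeric-AI events are terminal `(2,1)` segments of
5–30 Mb, LST events are terminal balanced `(2,2)` blocks of 10–30 Mb
abutting the baseline, and LOH events are interstitial `(1,0)` runs of
16–40 Mb. Two mechanisms guarantee that implanted counts are recovered
exactly: a per-chromosome budget (implanted length at most 40% of the
chromosome) keeps `(1,1)` the major copy state everywhere, and
telomeric-AI and LOH implants carry a 3 Mb uncovered gap on their interior
side(s) — emulating the probe dropout often seen at rearrangement
boundaries — which keeps their state changes below the LST gap rule, so no
event is counted by a signature it was not implanted for. The
`k_composite` class deliberately breaks this separation: a terminal
`(2,0)` region over 15 Mb with an abutting `>= 10` Mb flank is counted by
all three signatures at one shared breakpoint, exercising the overlap
accounting. Placement is rejection sampling with a retry cap; an
unplaceable configuration raises an explicit error rather than silently
implanting fewer events.

The simulator makes no claim of biological realism: there is no clonal
mixture, no noise in integer copy states, no replication-timing structure,
no correlated events, and ploidy is a metadata field rather than an
emergent property of the segments. Passing the recovery tests therefore
shows that the counters implement their rules exactly — not that the
signatures are well-calibrated on noisy real segmentations, where upstream
segmentation error dominates.

## Problem sizes and numerical choices in the test suite

The suite validates parameter recovery exhaustively over the full
`(0..10)^3` grid of implanted counts (1,331 simulated genomes), checks the
optimized counters against clause-by-clause brute-force references on
1,000 random small profiles (up to 5 chromosomes, 20 segments), and runs
100 random balanced-diploid segmentations through every counter and
metric expecting exact zeros. Cohort power is checked at a scaled size (15
vs 15 samples, NtAI rates 1 vs 10, 10 replicates), at which the rank-sum
separation is unambiguous. Statistical kernels are anchored to closed-form
and enumeration values (for example, the most extreme split of 3 vs 3
distinct observations has exact two-sided p = 2/20 = 0.1) and
cross-checked against `stats::wilcox.test`, `stats::fisher.test`, and
membership-tally oracles.

## Known limitations

- Arm assignment drops the slice of any segment inside the centromere
  interval; signatures that would depend on pericentromeric boundaries are
  therefore conservative there.
- The NtAI "telomere" is the outermost covered coordinate; profiles with
  grossly truncated terminal coverage will still have their terminal
  segment considered telomeric.
- Breakpoint identity for the Venn analysis is exact-position equality
  within a sample; a tolerance window for cross-platform comparisons is
  not implemented.
- No probe-count filtering, purity/ploidy re-estimation, MSI inference, or
  therapy-response prediction is attempted.
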