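---
title: "Methods: perfect-match HLA genotyping and allele-level expression"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: perfect-match HLA genotyping and allele-level expression}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hlacapture)
```

This vignette documents the model behind `hlacapture`, the parameters that
matter, the design choices that were genuinely open, and what the
simulation-based validation does and does not demonstrate.

## The measurement model

The pipeline estimates allele-level RNA abundance at the twelve classical
HLA loci from capture-enriched paired-end RNA-Seq reads. Three modelling
commitments shape everything downstream.

**Perfect-match read assignment.** A read supports an allele if and only
if the full read, or its reverse complement, occurs as an exact substring
of the allele's reference sequence. The HLA loci are paralogous and
alleles within a locus differ by a handful of substitutions, so any
mismatch tolerance lets reads migrate between references; exactness makes
assignment binary and auditable. The cost is a stringent filter:
error-bearing reads are simply lost (at a per-base error rate $e$ and read
length $L$, a fraction $1-(1-e)^L$ of reads — about 14% at $e = 10^{-3}$,
$L = 150$). Because the loss applies to both alleles of a heterozygote
symmetrically, allelic *ratios* are unaffected in expectation; this is the
central reason the filter is acceptable for DAE.

**Mapping windows.** Counting is restricted to the most polymorphic
exons: exons 2 and 3 (546 bp) for HLA-A/B/C, exon 2 alone for class II
(DRA 239 bp, DPA1 246 bp, DQA1 249 bp, DPB1 264 bp, DQB1 and the DRB
genes 270 bp). These windows concentrate the allele-distinguishing sites,
so reads overlapping them can be phased; sequence outside the window
(shared exons, UTRs) is still used for exact matching but does not
contribute counts. The window length is also the *target size* used to
standardize counts.

**In-phase counting.** For a heterozygous pair $(X, Y)$, a mate counts
for $X$ iff it (i) perfectly matches $X$'s reference, (ii) overlaps $X$'s
window by at least one base, and (iii) does not perfectly match $Y$'s
reference anywhere. Reads matching both alleles are ambiguous and are
discarded rather than split — "in-phase read numbers" are meant to be
unambiguous evidence. A `split_ambiguous` flag (default off) assigns such
reads 0.5/0.5 for sensitivity analysis. Mates are counted independently;
genotype *support*, by contrast, is deduplicated per read pair so a
fragment is never double-counted as evidence for a call.

Normalization proceeds in two steps within each sample and locus set:
$\text{rate}_a = \text{raw}_a / \text{targetsize}_a$ (reads per base),
then $\text{normalized}_a = 10^6 \cdot \text{rate}_a / \sum_b
\text{rate}_b$. Normalization is per sample, never pooled, so samples are
comparable after scaling; ratios between alleles within a sample are
preserved exactly.

## Genotype calling

The reference assay assigned genotypes by similarity search with
unpublished selection rules, so the caller here is specified from
scratch to be deterministic and testable:

* candidate scoring uses read pairs matching alleles of exactly one
  locus (cross-locus matchers are discarded — the mismapping guard);
* the called pair maximizes the number of *explained* pairs (pairs
  hitting either allele), with ties broken by total *unique support*
  (pairs hitting exactly one of the two), then by lexicographic allele
  name; remaining exact ties are reported in an `ambiguity` field rather
  than silently resolved;
* a heterozygous call requires unique support of at least
  `min_unique_support` (default 10 pairs) on *both* alleles. The default
  is small enough for desk-scale experiments and large enough that
  sequencing errors cannot manufacture an allele at typical error rates;
* if one allele explains every locus read the call is homozygous — or
  *hemizygous* for DRB3/DRB4/DRB5, whose single-copy state is
  read-indistinguishable from homozygosity. We report hemizygous for the
  paralogs because single carriage is the more common state; either way
  the genotype is excluded from quantification, so the label does not
  affect counts.

Calls are made at the finest field resolution the panel supports; names
are not truncated to field 3, though concordance checks compare at
field 3.

Novel-variant flagging scans reads that matched nowhere for placements on
a called allele with exactly one substitution; candidates require at
least `min_support` (default 10) reads agreeing on position and base, and
only positions inside the mapping window — the analysis region — are
reported. Confirmation (in practice, targeted re-sequencing) is out of
scope.

## The DRB3/DRB4/DRB5 composite

Each haplotype carries at most one secondary DRB gene (or none), so a
diploid sample has 0–2 expressed copies spread over up to two paralog
loci. Quantification treats the three paralogs as one composite unit:

* two distinct copies — whether DRB3\*x/DRB3\*y at one locus or
  DRB3\*x/DRB4\*y across loci — form a phaseable pair and are counted
  like any heterozygote (cross-paralog windows always differ);
* a single copy is hemizygous; identical copies are
  homozygous-equivalent. Both are unphaseable and excluded.

Locus sets 1 and 4 include the composite, so a sample qualifies for them
only with two distinguishable copies; otherwise the sample is dropped
from those sets entirely (and retained in sets 2–3, which do not involve
the paralogs).

## Phase classification

A heterozygous pair is *completely phased* when its window sequences
differ in **every** window exon, *partially phased* when they differ in
some but not all (reads in the identical exon cannot be divided), and
homozygous-equivalent when the windows are identical — even if the full
names differ at field 4, since counting cannot separate identical
windows. Alleles lacking a window exon annotation (partial references)
make a pair partially phased; partial references still participate in
genotyping. Only completely phased pairs enter the comparative datasets;
this mirrors the exclusion of homozygous, partially phased and
hemizygous genotypes in the assay the package models.

## Statistical conventions

* Quartiles: inclusive linear interpolation on the sorted values
  (`stats::quantile` type 7) — the convention of the spreadsheet software
  in which the original summaries were produced. At small n, quartile
  conventions visibly change hinge ratios, so the convention is fixed and
  tested against a manual interpolation oracle.
* Rounding: fold changes, hinge ratios and percentages round half-up to
  one decimal (`round_half_up`), matching table precision; base R's
  round-half-to-even would disagree on exact ties.
* ANOVA: standard fixed-effects one-way ANOVA via `stats::aov`. Two
  degenerate cases are handled explicitly: all values identical gives
  F = 0, p = 1; zero within-group variance with differing means gives
  F = Inf, p = 0. With two groups F equals the squared pooled-variance t
  statistic (tested to 1e-10 relative).
* Box-whisker: whiskers reach the most extreme data points within 1.5
  interquartile ranges of the box; points beyond are outliers. With
  IQR = 0 the whiskers coincide with the box edges.
* No multiple-testing correction by default, matching the modelled
  analysis; `compare_groups(bonferroni = TRUE)` is available.
* Group comparisons drop groups with fewer than `min_n = 3` observations
  (the "at least three samples" rule) and skip with a message when fewer
  than two groups remain. For the per-locus allele table, the ANOVA
  p-value can compare either the two extreme allele groups
  (`p_mode = "extremes"`, default) or all allele groups (`"all"`); the
  source analysis is ambiguous on this point, so both are exposed.
* A 3'UTR regulatory SNP grouping (e.g. DPB1 expression classes) is
  supported through a user-supplied allele-to-class map passed to
  `compare_groups`; the SNP itself is never genotyped, since the windows
  carry no 3'UTR sequence.

## The simulator: what it emulates, and what it does not

The generator produces, per sample: a diploid genotype over a synthetic
panel (per-haplotype secondary-DRB carriage with probabilities
DRB3 0.40 / DRB4 0.30 / DRB5 0.15 / none 0.15); per-copy expression
weights; and 2×150 bp paired reads.

* **Panel.** Per locus, a random ancestral window of the exact mapping
  window length with 100 bp flanks; each allele receives `divergence`
  random window substitutions (pairwise distinctness enforced when
  `divergence >= 1`; `divergence = 0` deliberately produces
  indistinguishable alleles for exclusion tests).
* **Expression.** Copy weight = locus mean × log-normal(0, σ_allelic) ×
  per-allele log-normal(0, σ_capture) capture efficiency. Default locus
  means follow the ordering observed in blood (B highest of class I,
  DRA highest of class II, DQA1/DQB1 lowest, DRB4/DRB5 above DRB3).
  σ_allelic defaults to 0.15 for class I and 0.35 for class II so that
  simulated allele-level dispersion reproduces the class I (low) versus
  class II (high) contrast; σ_capture defaults to 0.25. Capture bias is
  drawn once per allele, constant across fragments and samples, modelling
  probe-affinity differences.
* **Reads.** Fragment lengths are normal (mean 250 bp, sd 50 bp,
  truncated to the transcript; the real assay's fragment distribution is
  not published, so these are stated defaults, not calibrated ones).
  Fragments are drawn uniformly from the flank+window transcript;
  substitution errors are applied per base. Only substitutions are
  simulated: under perfect-match counting an indel-bearing read behaves
  identically to a mismatched one (it is dropped), so substitutions
  exercise the filter fully. Read names encode the source allele, and
  every output is byte-identical under a fixed seed.

Passing recovery tests on these simulations shows that the
matching/phasing/normalization machinery is correct and unbiased under
the stated noise model. It does *not* show robustness to what the
generator omits: quality-score decay, PCR and optical duplicates,
hybridization thermodynamics, isoform structure, intron retention, or
real IPD-IMGT/HLA allele similarity structure (real alleles are related
by descent, not by independent mutations from an ancestor; real panels
also contain alleles absent from the sample's genotype). Cohort-level
quantities from the original assay (per-locus median levels, cohort
p-values, PBMC–cord-blood correlations) require the original raw reads
and are out of reach of desk-scale simulation by design.

## Validation scale

The shipped tests validate at sizes chosen to give tight statistical
bounds while staying desk-scale: exact-match equivalence against a
substring-enumeration oracle on 200 randomized panels (up to 50 alleles)
× 1,000 reads; field-3 genotype concordance on 50 error-free samples at
divergence 4 and ~70 pairs per allele copy (a coverage calculation puts
unique support well above the calling threshold at this depth); 2:1
allelic-ratio recovery over 100 seeded runs at 5,000 fragments per run —
the fragment, not the mate, is the independent unit, and at ~5,000
informative fragments the binomial coverage of the ±10% band is ~99.8%,
so at least 95 of 100 runs inside the band is a comfortable expectation
rather than a knife-edge; ANOVA null calibration over 1,000 replicates
against binomial 99% bounds.

## Known limitations

* Exact matching is unforgiving of reference errors: a single wrong base
  in a reference silently shifts that allele's counts down (mitigated by
  the novel-variant flagger, which surfaces consistent single-base
  disagreements).
* Alleles identical across a window are unquantifiable by construction;
  the assay's own exclusion rules apply.
* Reads are counted per mate; a fragment whose mates both overlap the
  window contributes two counts. This inflates counts relative to
  fragment-level counting by a locus-independent factor and therefore
  cancels in normalized comparisons, but raw counts should not be read
  as fragment counts.
* The `target size` is the window length; if a future reference ships
  windows of unequal length within a locus, counts remain comparable
  because standardization is per allele.
* No EM-style rescue of ambiguous reads, no isoform-level
  quantification, and no G-/P-group collapsing of allele names.
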