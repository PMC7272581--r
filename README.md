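# hlacapture

Allele-level HLA genotyping and RNA expression quantification from capture
RNA-Seq reads.

## The problem

The human leukocyte antigen (HLA) complex is the most polymorphic region of
the human genome, and the two alleles an individual carries at a locus are
often expressed at measurably different levels (differential allelic
expression, DAE) — with consequences for transplantation, infection and
autoimmunity. Measuring DAE from RNA-Seq is hard because the twelve
classical loci (HLA-A, -B, -C, -DPA1, -DPB1, -DQA1, -DQB1, -DRA, -DRB1 and
the secondary paralogs -DRB3/-DRB4/-DRB5) are so similar that reads
mismap freely between loci and alleles under ordinary alignment
stringency.

`hlacapture` implements the computational half of a capture RNA-Seq assay
that solves this with two deliberately strict rules:

1. **Perfect-match assignment.** A read supports an allele only if the
   entire read (or its reverse complement) occurs as an exact substring of
   the allele's reference sequence — no mismatches, ever. This eliminates
   cross-locus mismapping and PCR-crossover artifacts at the cost of
   discarding error-bearing reads.
2. **Phase-aware counting over polymorphic exon windows.** Counting is
   restricted to the most polymorphic exons (exons 2+3, 546 bp, for class
   I; exon 2, 239–270 bp, for class II). For a heterozygous pair, a read
   is *in phase* when it perfectly matches one allele and fails to match
   the other; reads matching both are ambiguous and dropped. Homozygous,
   partially phased, and hemizygous (single-copy DRB3/4/5) genotypes are
   excluded because their reads cannot be divided between alleles.

Counts are then made comparable across loci and samples: raw in-phase
counts are divided by the window length (*target size*, reads per base)
and scaled within a configurable locus set so each sample sums to one
million — four standard sets are provided (1: all 12 loci; 2: class I;
3: class II without DRB3/4/5; 4: class II with them; sets 1 and 4 require
two distinguishable DRB3/4/5 copies). DAE statistics on the normalized
counts follow spreadsheet conventions: five-number summaries with
inclusive interpolated quartiles, the *ratio of hinges* Q3/Q1 per locus,
the lowest-vs-highest allele *fold change* per locus (half-up rounding to
one decimal), one-way ANOVA, coefficients of variation, Pearson
correlation, and 1.5×IQR box-whisker summaries.

The package also ships a paired-end read simulator (diploid genotypes with
DRB3/4/5 haplotype structure, log-normal allelic imbalance, per-allele
capture bias, substitution errors, 2×150 bp reads) that records full
ground truth, so every stage can be validated by recovery experiments.

## Worked example

Simulate a small cohort, genotype it, and quantify class I DAE:

```r
library(hlacapture)

cfg <- pipeline_config(
  out_dir = "demo", seed = 7, sets = c(2, 3),
  simulate = list(n_samples = 6, alleles_per_locus = 2, divergence = 4,
                  depth = 6000, error_rate = 0.001))
rep <- run_pipeline(cfg)

ds2 <- read.delim("demo/dataset_2.tsv")   # class I locus set
head(ds2[, c("sample_id", "locus", "allele", "raw_reads",
             "normalized_reads")])
#>  sample_id locus     allele raw_reads normalized_reads
#>       S001     A A*01:01:01      1415         621431.7
#>       S001     A A*01:02:01       862         378568.3
#>       S002     B B*01:01:01       865         299619.0
#>       S002     B B*01:02:01      1051         364045.7
#>       S002     C C*01:01:01       429         148597.2
#>       S002     C C*01:02:01       542         187738.1

locus_summary(ds2)
#>  locus  n minimum     q1 median     q3 maximum hinge_ratio       cv
#>      A  6  101060 230598 341758 445269  621432         1.9 0.536770
#>      B  6  183039 201347 271851 347939  418076         1.7 0.338569
#>      C 10  107951 149259 163341 187453  527309         1.3 0.670505
```

Each row of the dataset is one completely phased allele of one sample;
`normalized_reads` sum to 1,000,000 per sample within the set. Samples
homozygous at a locus contribute no rows for it (S001 above is homozygous
at B and C), and `rep$accounting` shows the read attrition per sample
(total → perfectly matched → in-phase). `allele_summary(ds2)` adds the
per-locus lowest/highest expressed alleles, their fold change and ANOVA
p-value; at this toy cohort size the p-values are unremarkable, which is
expected — six samples of two synthetic alleles carry little power.

A thin command-line wrapper with `simulate` / `genotype` / `quantify` /
`stats` / `run` subcommands is installed at
`system.file("cli", "hlacapture.R", package = "hlacapture")`.

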