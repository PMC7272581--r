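# Builds a class-I-like pair whose windows differ as requested per exon.
phase_pair <- function(diff_exon2 = TRUE, diff_exon3 = TRUE) {
  e2 <- rand_seq_fixed(40, 50)
  e3 <- rand_seq_fixed(40, 51)
  e2b <- e2; e3b <- e3
  if (diff_exon2) substr(e2b, 10, 10) <- setdiff(c("A", "C", "G", "T"),
                                                 substr(e2, 10, 10))[1]
  if (diff_exon3) substr(e3b, 20, 20) <- setdiff(c("A", "C", "G", "T"),
                                                 substr(e3, 20, 20))[1]
  exons <- data.frame(exon_id = c(2L, 3L), start = c(5L, 45L),
                      end = c(45L, 85L))
  panel <- reference_set(list(
    allele_reference("A*01:01:01", paste0("AAAAA", e2, e3, "CCCCC"), exons),
    allele_reference("A*01:02:01", paste0("AAAAA", e2b, e3b, "CCCCC"), exons)
  ))
  hits <- structure(list(), class = "ignored")
  call <- structure(list(locus = "A",
                         alleles = c("A*01:01:01", "A*01:02:01"),
                         zygosity = "heterozygous",
                         support = c(20L, 20L), ambiguity = character(0),
                         n_pairs = 40L, n_cross_locus = 0L),
                    class = "genotype_call")
  list(panel = panel, call = call)
}

test_that("phase classification follows the per-exon difference rule", {
  both <- phase_pair(TRUE, TRUE)
  expect_equal(classify_phase(both$call, both$panel), "completely_phased")
  one <- phase_pair(TRUE, FALSE)
  expect_equal(classify_phase(one$call, one$panel), "partially_phased")
  none <- phase_pair(FALSE, FALSE)
  expect_equal(classify_phase(none$call, none$panel), "homozygous")

  hemi <- structure(list(locus = "DRB4", alleles = "DRB4*01:01:01",
                         zygosity = "hemizygous", support = 30L,
                         ambiguity = character(0), n_pairs = 30L,
                         n_cross_locus = 0L), class = "genotype_call")
  expect_equal(classify_phase(hemi, both$panel), "hemizygous")
  absent <- structure(list(locus = "DQA1", alleles = character(0),
                           zygosity = "absent", support = integer(0),
                           ambiguity = character(0), n_pairs = 0L,
                           n_cross_locus = 0L), class = "genotype_call")
  expect_equal(classify_phase(absent, both$panel), "absent")
})

test_that("a partial reference in the pair forces partially_phased", {
  p <- phase_pair(TRUE, TRUE)
  a <- p$panel$alleles[["A*01:01:01"]]
  partial <- allele_reference("A*01:01:01", a$sequence,
                              a$exons[a$exons$exon_id == 2, ],
                              full_length = FALSE)
  panel <- reference_set(list(partial, p$panel$alleles[["A*01:02:01"]]))
  expect_equal(classify_phase(p$call, panel), "partially_phased")
})

test_that("in-phase counting matches the brute-force oracle and drops ambiguous reads", {
  panel <- synthesize_panel(loci = "DQB1", alleles_per_locus = 2,
                            divergence = 3, seed = 52)
  a <- "DQB1*01:01:01"; b <- "DQB1*01:02:01"
  truth <- data.frame(sample_id = "S001", allele = c(a, b), weight = c(1, 1))
  cfg <- sim_config(n_samples = 1, depth = 60, error_rate = 0, seed = 53)
  em <- emit_reads(truth, panel, cfg)
  reads <- c(em$reads$S001$r1, em$reads$S001$r2)
  hits <- match_reads(reads, panel)
  got <- count_in_phase(hits, a, b, panel)
  want <- oracle_in_phase(reads, a, b, panel)
  expect_equal(got, want)
  # a read sitting entirely in the shared flank matches both alleles and
  # counts for neither
  fl <- substr(panel$alleles[[a]]$sequence, 1, 80)
  h2 <- match_reads(c(flankread = fl), panel)
  expect_equal(unname(count_in_phase(h2, a, b, panel)), c(0, 0))
  # ... unless the sensitivity split mode is on
  win <- substr(panel$alleles[[a]]$sequence, 101, 180)
  wb <- substr(panel$alleles[[b]]$sequence, 101, 180)
  if (win == wb) {  # shared window segment: ambiguous but window-overlapping
    h3 <- match_reads(c(shared = win), panel)
    expect_equal(sum(count_in_phase(h3, a, b, panel, split_ambiguous = TRUE)),
                 1)
  }
})

test_that("size standardization is exact division", {
  expect_equal(standardize_by_size(546, 546), 1)
  expect_equal(standardize_by_size(0, 270), 0)
  expect_equal(standardize_by_size(1000, 270), 1000 / 270)
  expect_error(standardize_by_size(10, 0), "positive")
})

test_that("per-million normalization preserves ratios and sums to 1e6", {
  expect_equal(normalize_to_million(c(1, 1, 2)), c(250000, 250000, 500000))
  expect_equal(normalize_to_million(5), 1e6)
  expect_error(normalize_to_million(c(0, 0)), "all-zero")
  set.seed(54)
  for (i in 1:50) {
    x <- runif(sample(2:24, 1), 0, 100)
    nx <- normalize_to_million(x)
    expect_lt(abs(sum(nx) - 1e6) / 1e6, 1e-9)
    # scale invariance and exact ratio preservation
    expect_equal(normalize_to_million(x * 7.3), nx)
    expect_equal(nx[1] / nx[2], x[1] / x[2])
  }
})

test_that("locus sets are composed as specified", {
  s1 <- locus_set_config(1)
  expect_setequal(s1$loci, hla_loci()$name)
  expect_true(s1$drb345_included)
  expect_setequal(locus_set_config(2)$loci, c("A", "B", "C"))
  s3 <- locus_set_config(3)
  expect_false(any(c("DRB3", "DRB4", "DRB5") %in% s3$loci))
  expect_false(s3$drb345_included)
  s4 <- locus_set_config(4)
  expect_true(all(c("DRB3", "DRB4", "DRB5", "DQB1") %in% s4$loci))
  expect_false("A" %in% s4$loci)
})

# Full small cohort used by the dataset tests: 12 loci, heterozygous calls
# everywhere, one sample with two secondary-DRB copies and one hemizygous.
quant_fixture <- function() {
  panel <- synthesize_panel(alleles_per_locus = 2, divergence = 4, seed = 55)
  core <- setdiff(panel_loci(panel), c("DRB3", "DRB4", "DRB5"))
  mk_truth <- function(sid, drb) {
    alleles <- unlist(lapply(core, function(lc)
      grep(paste0("^", lc, "\\*"), names(panel$alleles), value = TRUE)))
    alleles <- c(alleles, drb)
    data.frame(sample_id = sid, allele = alleles, weight = 1,
               stringsAsFactors = FALSE)
  }
  truth <- rbind(
    mk_truth("S001", c("DRB3*01:01:01", "DRB4*01:01:01")),  # two DRB copies
    mk_truth("S002", "DRB4*01:01:01")                       # hemizygous DRB
  )
  cfg <- sim_config(n_samples = 2, depth = 1500, error_rate = 0, seed = 56)
  em <- emit_reads(truth, panel, cfg)
  phase <- list(); counts <- list()
  for (sid in names(em$reads)) {
    reads <- c(em$reads[[sid]]$r1, em$reads[[sid]]$r2)
    calls <- genotype_sample(reads, panel, min_unique_support = 5)
    q <- quantify_sample(calls, panel, sample_id = sid)
    phase[[sid]] <- q$phase
    counts[[sid]] <- q$counts
  }
  list(panel = panel, phase = do.call(rbind, phase),
       counts = do.call(rbind, counts))
}

test_that("datasets apply the locus-set and DRB inclusion rules", {
  fx <- quant_fixture()
  ds1 <- build_dataset(fx$counts, fx$phase, 1)
  ds2 <- build_dataset(fx$counts, fx$phase, 2)
  ds3 <- build_dataset(fx$counts, fx$phase, 3)
  ds4 <- build_dataset(fx$counts, fx$phase, 4)

  # hemizygous-DRB sample S002 excluded from sets 1 and 4, kept in 2 and 3
  expect_false("S002" %in% ds1$sample_id)
  expect_false("S002" %in% ds4$sample_id)
  expect_true("S002" %in% ds2$sample_id)
  expect_true("S002" %in% ds3$sample_id)
  expect_true("S002" %in% names(attr(ds1, "excluded")))

  # the two-DRB sample contributes its paralog pair to sets 1 and 4
  expect_setequal(
    ds1$allele[ds1$sample_id == "S001" & ds1$locus %in%
                 c("DRB3", "DRB4", "DRB5")],
    c("DRB3*01:01:01", "DRB4*01:01:01"))

  # class-I-only set: two alleles x three loci per sample
  for (sid in unique(ds2$sample_id)) {
    expect_equal(nrow(ds2[ds2$sample_id == sid, ]), 6)
    expect_setequal(unique(ds2$locus[ds2$sample_id == sid]),
                    c("A", "B", "C"))
  }
  # no DRB paralogs in sets 2 and 3
  expect_false(any(c("DRB3", "DRB4", "DRB5") %in% ds2$locus))
  expect_false(any(c("DRB3", "DRB4", "DRB5") %in% ds3$locus))

  # per-sample, per-set normalization sums to one million
  for (ds in list(ds1, ds2, ds3, ds4)) {
    sums <- tapply(ds$normalized_reads, ds$sample_id, sum)
    expect_true(all(abs(sums - 1e6) / 1e6 < 1e-9))
  }
})

test_that("excluded phase categories never enter a dataset", {
  fx <- quant_fixture()
  # the counts table only carries completely phased units by construction;
  # verify against the phase table for every dataset row
  for (k in 1:4) {
    ds <- build_dataset(fx$counts, fx$phase, k)
    for (i in seq_len(nrow(ds))) {
      unit <- if (ds$locus[i] %in% c("DRB3", "DRB4", "DRB5")) "DRB3/4/5"
              else ds$locus[i]
      st <- fx$phase$status[fx$phase$sample_id == ds$sample_id[i] &
                              fx$phase$unit == unit]
      expect_equal(st, "completely_phased")
    }
  }
})

test_that("simulated 2:1 allelic imbalance is recovered from counts", {
  panel <- synthesize_panel(loci = "B", alleles_per_locus = 2,
                            divergence = 6, seed = 57)
  a <- "B*01:01:01"; b <- "B*01:02:01"
  truth <- data.frame(sample_id = "S001", allele = c(a, b), weight = c(2, 1))
  cfg <- sim_config(n_samples = 1, depth = 2500, error_rate = 0, seed = 58)
  em <- emit_reads(truth, panel, cfg)
  reads <- c(em$reads$S001$r1, em$reads$S001$r2)
  calls <- genotype_sample(reads, panel)
  q <- quantify_sample(calls, panel, sample_id = "S001")
  ds <- build_dataset(q$counts, q$phase, 2)
  ratio <- ds$normalized_reads[ds$allele == a] /
    ds$normalized_reads[ds$allele == b]
  expect_gt(ratio, 1.8)
  expect_lt(ratio, 2.2)
})
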