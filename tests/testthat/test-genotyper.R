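# A small divergent two-locus panel plus reads constructed directly from
# its sequences; used by several blocks below.
geno_fixture <- function(seed = 30) {
  panel <- synthesize_panel(loci = c("A", "DQB1"), alleles_per_locus = 3,
                            divergence = 4, seed = seed)
  panel
}

# A 150-mer of `allele` that covers a position where it differs from every
# other allele at its locus, so the read is private to that allele.
window_read <- function(panel, allele, len = 150) {
  ref <- panel$alleles[[allele]]
  lc <- ref$locus
  others <- setdiff(panel_names <- grep(paste0("^", lc, "\\*"),
                                        names(panel$alleles), value = TRUE),
                    allele)
  w <- strsplit(as.character(extract_window(ref)), "")[[1]]
  priv <- seq_along(w)
  for (o in others) {
    wo <- strsplit(as.character(extract_window(panel$alleles[[o]])), "")[[1]]
    priv <- intersect(priv, which(w != wo))
  }
  stopifnot(length(priv) >= 1)
  st <- min(max(1, priv[1] - (len %/% 2)), length(w) - len + 1)
  win_start <- ref$exons$start[match(mapping_window(lc)$exon_ids[1],
                                     ref$exons$exon_id)]
  substr(ref$sequence, win_start + st, win_start + st + len - 1)
}

test_that("a read occurring in exactly one allele yields a single hit", {
  panel <- geno_fixture()
  # a window-derived 150-mer covering an allele-private position
  r <- window_read(panel, "A*01:01:01")
  hits <- match_reads(c(q = r), panel)
  expect_equal(nrow(hits), 1)
  expect_equal(hits$allele, "A*01:01:01")
  expect_equal(hits$orientation, "+")
  # its reverse complement matches the same allele on the other strand
  hits_rc <- match_reads(c(q = rc_chr(r)), panel)
  expect_equal(hits_rc$allele, "A*01:01:01")
  expect_equal(hits_rc$orientation, "-")
})

test_that("one substitution anywhere defeats the perfect-match filter", {
  panel <- geno_fixture()
  r <- window_read(panel, "A*01:01:01")
  substr(r, 75, 75) <- setdiff(c("A", "C", "G", "T"),
                               substr(r, 75, 75))[1]
  # the mutated read must not equal a substring of any allele
  expect_equal(nrow(match_reads(c(q = r), panel)), 0)
  # reads containing N never match
  rn <- window_read(panel, "A*01:01:01")
  substr(rn, 10, 10) <- "N"
  expect_equal(nrow(match_reads(c(q = rn), panel)), 0)
})

test_that("hit tables equal the literal brute-force oracle on a 20-read set", {
  panel <- toy_panel()
  set.seed(31)
  reads <- c(
    # exact fragments of panel alleles, both strands, width 6
    vapply(1:10, function(i) {
      al <- sample(names(panel$alleles), 1)
      s <- panel$alleles[[al]]$sequence
      st <- sample(nchar(s) - 5, 1)
      r <- substr(s, st, st + 5)
      if (runif(1) < 0.5) rc_chr(r) else r
    }, character(1)),
    # random 6-mers
    vapply(1:10, function(i) rand_seq(6), character(1))
  )
  names(reads) <- sprintf("r%02d", seq_along(reads))
  expect_equal(match_reads(reads, panel), oracle_match_naive(reads, panel))
})

test_that("matching is strand-symmetric", {
  panel <- geno_fixture()
  set.seed(32)
  reads <- vapply(1:30, function(i) {
    al <- sample(names(panel$alleles), 1)
    s <- panel$alleles[[al]]$sequence
    st <- sample(nchar(s) - 149, 1)
    substr(s, st, st + 149)
  }, character(1))
  names(reads) <- sprintf("r%03d", seq_along(reads))
  h1 <- match_reads(reads, panel)
  h2 <- match_reads(setNames(rc_chr_vec(reads), names(reads)), panel)
  flip <- h2
  flip$orientation <- ifelse(h2$orientation == "+", "-", "+")
  expect_equal(sort_hits(h1), sort_hits(flip))
})

test_that("heterozygotes are called from error-free reads", {
  panel <- geno_fixture()
  truth <- data.frame(sample_id = "S001",
                      allele = c("A*01:01:01", "A*01:02:01",
                                 "DQB1*01:01:01", "DQB1*01:03:01"),
                      weight = 1)
  cfg <- sim_config(n_samples = 1, depth = 400, error_rate = 0, seed = 33)
  em <- emit_reads(truth, panel, cfg)
  reads <- c(em$reads$S001$r1, em$reads$S001$r2)
  calls <- genotype_sample(reads, panel)
  expect_equal(sort(calls$A$alleles), c("A*01:01:01", "A*01:02:01"))
  expect_equal(calls$A$zygosity, "heterozygous")
  expect_equal(sort(calls$DQB1$alleles),
               c("DQB1*01:01:01", "DQB1*01:03:01"))
  expect_true(all(calls$A$support >= 10))
})

test_that("reads from a single allele give a homozygous call", {
  panel <- geno_fixture()
  truth <- data.frame(sample_id = "S001", allele = "A*01:02:01", weight = 1)
  cfg <- sim_config(n_samples = 1, depth = 150, error_rate = 0, seed = 34)
  em <- emit_reads(truth, panel, cfg)
  calls <- genotype_sample(c(em$reads$S001$r1, em$reads$S001$r2), panel)
  expect_equal(calls$A$alleles, "A*01:02:01")
  expect_equal(calls$A$zygosity, "homozygous")
  expect_equal(calls$DQB1$zygosity, "absent")
})

test_that("indistinguishable candidates tie deterministically with a note", {
  # X and Y share one sequence; B is divergent. Reads come from B and X,
  # so pairs (B,X) and (B,Y) explain identical read sets.
  base <- rand_seq_fixed(400, seed = 35)
  alt <- base
  for (p in c(120, 180, 240)) {
    substr(alt, p, p) <- setdiff(c("A", "C", "G", "T"), substr(alt, p, p))[1]
  }
  exons <- data.frame(exon_id = 2L, start = 100L, end = 370L)
  panel <- reference_set(list(
    allele_reference("DQB1*01:01:01", alt, exons),    # B (divergent)
    allele_reference("DQB1*01:02:01", base, exons),   # X
    allele_reference("DQB1*01:03:01", base, exons)    # Y, identical to X
  ))
  reads <- c(
    setNames(vapply(0:29, function(i) substr(alt, 100 + i, 249 + i),
                    character(1)), sprintf("b%02d", 0:29)),
    setNames(vapply(0:29, function(i) substr(base, 100 + i, 249 + i),
                    character(1)), sprintf("x%02d", 0:29))
  )
  hits <- match_reads(reads, panel)
  call <- call_genotype(hits, "DQB1")
  expect_equal(call$zygosity, "heterozygous")
  expect_equal(call$alleles, c("DQB1*01:01:01", "DQB1*01:02:01"))
  expect_equal(call$ambiguity, "DQB1*01:01:01/DQB1*01:03:01")
})

test_that("adding reads from a called allele never displaces it", {
  panel <- geno_fixture()
  truth <- data.frame(sample_id = "S001",
                      allele = c("A*01:01:01", "A*01:02:01"), weight = 1)
  cfg <- sim_config(n_samples = 1, depth = 200, error_rate = 0, seed = 36)
  em <- emit_reads(truth, panel, cfg)
  reads <- c(em$reads$S001$r1, em$reads$S001$r2)
  base_call <- genotype_sample(reads, panel)$A
  expect_true("A*01:01:01" %in% base_call$alleles)
  for (k in c(50, 200)) {
    extra_truth <- data.frame(sample_id = "S001", allele = "A*01:01:01",
                              weight = 1)
    cfg2 <- sim_config(n_samples = 1, depth = k, error_rate = 0, seed = 37)
    extra <- emit_reads(extra_truth, panel, cfg2)
    e1 <- extra$reads$S001$r1; e2 <- extra$reads$S001$r2
    names(e1) <- paste0("extra", seq_along(e1), "/1")
    names(e2) <- paste0("extra", seq_along(e2), "/2")
    more <- c(reads, e1, e2)
    call <- genotype_sample(more, panel)$A
    expect_true("A*01:01:01" %in% call$alleles)
  }
})

test_that("a consistent private SNP is flagged; noise is not", {
  panel <- geno_fixture()
  truth <- data.frame(sample_id = "S001",
                      allele = c("A*01:01:01", "A*01:02:01"), weight = 1)
  cfg <- sim_config(n_samples = 1, depth = 300, error_rate = 0, seed = 38)
  em <- emit_reads(truth, panel, cfg)
  reads <- c(em$reads$S001$r1, em$reads$S001$r2)
  calls <- genotype_sample(reads, panel)

  # error-free run: nothing to flag
  expect_equal(nrow(flag_novel_variants(reads, calls, panel,
                                        hits = attr(calls, "hits"))), 0)

  # inject a private SNP at window position 200 of one allele into 30% of
  # that allele's reads (reference position = flank 100 + 200)
  ref <- panel$alleles[["A*01:01:01"]]
  refpos <- 100L + 200L
  src <- grepl("A\\*01:01:01", names(reads))
  rchar <- as.character(reads)
  set.seed(39)
  carriers <- which(src & runif(length(reads)) < 0.3)
  new_base <- setdiff(c("A", "C", "G", "T"),
                      substr(ref$sequence, refpos, refpos))[1]
  n_injected <- 0
  for (i in carriers) {
    h <- match_reads(reads[i], panel)
    h <- h[h$allele == "A*01:01:01", ]
    if (!nrow(h) || h$start[1] > refpos || h$end[1] < refpos) next
    off <- refpos - h$start[1] + 1
    if (h$orientation[1] == "+") {
      substr(rchar[i], off, off) <- new_base
    } else {
      roff <- nchar(rchar[i]) - off + 1
      substr(rchar[i], roff, roff) <- chartr("ACGT", "TGCA", new_base)
    }
    n_injected <- n_injected + 1
  }
  expect_gte(n_injected, 10)
  mutated <- setNames(rchar, names(reads))
  calls2 <- genotype_sample(mutated, panel)
  cand <- flag_novel_variants(mutated, calls2, panel, min_support = 10,
                              hits = attr(calls2, "hits"))
  expect_equal(nrow(cand), 1)
  expect_equal(cand$nearest_allele, "A*01:01:01")
  expect_equal(cand$ref_pos, refpos)
  expect_equal(cand$window_pos, 200L)
  expect_equal(cand$observed_base, new_base)
  expect_gte(cand$supporting_reads, 10)

  # scattered random errors stay below the support threshold
  set.seed(40)
  noisy <- as.character(reads)
  pick <- sample(length(noisy), 40)
  for (i in pick) {
    p <- sample(150, 1)
    substr(noisy[i], p, p) <- sample(c("A", "C", "G", "T"), 1)
  }
  noisy <- setNames(noisy, names(reads))
  calls3 <- genotype_sample(noisy, panel)
  expect_equal(nrow(flag_novel_variants(noisy, calls3, panel,
                                        min_support = 10,
                                        hits = attr(calls3, "hits"))), 0)
})
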