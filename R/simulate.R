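# Paired-end capture RNA-Seq simulator with ground truth.
#
# The generator emulates the structure of the real assay: a per-locus allele
# panel, diploid genotypes with DRB3/DRB4/DRB5 paralog presence/absence per
# haplotype, allele-level expression weights (locus mean x log-normal
# allelic imbalance x log-normal per-allele capture efficiency), and 2x150 bp
# paired reads with uniform per-base substitution errors drawn from the
# window-containing transcript of each expressed allele copy.

# Default relative locus transcript means. Class I >> class II, with
# B > C > A and DRA leading class II; DQA1/DQB1 lowest; DRB4/DRB5 above DRB3.
.DEFAULT_LOCUS_MEANS <- c(
  A = 86788, B = 165092, C = 98672,
  DPA1 = 12585, DPB1 = 20354, DQA1 = 7744, DQB1 = 8096,
  DRA = 36511, DRB1 = 35606, DRB3 = 9972, DRB4 = 15445, DRB5 = 13634
)

# Default per-haplotype secondary-DRB carriage probabilities. Each haplotype
# carries at most one of DRB3/DRB4/DRB5 (or none), mirroring known DR
# haplotype families.
.DEFAULT_DRB_HAPLOTYPES <- c(DRB3 = 0.40, DRB4 = 0.30, DRB5 = 0.15, none = 0.15)

#' Simulator configuration
#'
#' @param n_samples Number of diploid samples.
#' @param depth Target read pairs per sample (allocated across expressed
#'   allele copies proportionally to their weights).
#' @param read_length Read length in bp (default 150, paired).
#' @param fragment_mean,fragment_sd Fragment-length distribution (bp).
#' @param error_rate Per-base substitution probability.
#' @param locus_mean_expression Named positive vector of relative locus
#'   transcript means; defaults reflect the class I over class II ordering
#'   seen in blood (B highest, DQA1/DQB1 lowest).
#' @param allelic_sigma Log-normal sigma of the per-copy allelic-imbalance
#'   multiplier. Scalar, or named per-locus vector; the default is small for
#'   class I (0.15) and larger for class II (0.35), giving class II the
#'   larger allele-level dispersion.
#' @param capture_bias_sigma Log-normal sigma of the per-allele capture
#'   efficiency (constant across fragments and samples; 0 disables bias).
#' @param drb_haplotype_model Named probabilities over
#'   `c("DRB3","DRB4","DRB5","none")` for per-haplotype secondary-DRB
#'   carriage.
#' @param seed Integer seed making every downstream draw reproducible.
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(n_samples = 6,
                       depth = 2000,
                       read_length = 150,
                       fragment_mean = 250,
                       fragment_sd = 50,
                       error_rate = 0.001,
                       locus_mean_expression = NULL,
                       allelic_sigma = NULL,
                       capture_bias_sigma = 0.25,
                       drb_haplotype_model = NULL,
                       seed = 1L) {
  means <- locus_mean_expression %||% .DEFAULT_LOCUS_MEANS
  if (is.null(allelic_sigma)) {
    allelic_sigma <- ifelse(.LOCI %in% .CLASS_I, 0.15, 0.35)
    names(allelic_sigma) <- .LOCI
  }
  drb <- drb_haplotype_model %||% .DEFAULT_DRB_HAPLOTYPES
  cfg <- list(
    n_samples = as.integer(n_samples), depth = as.integer(depth),
    read_length = as.integer(read_length),
    fragment_mean = fragment_mean, fragment_sd = fragment_sd,
    error_rate = error_rate, locus_mean_expression = means,
    allelic_sigma = allelic_sigma, capture_bias_sigma = capture_bias_sigma,
    drb_haplotype_model = drb, seed = as.integer(seed)
  )
  stopifnot(cfg$n_samples >= 1, cfg$depth > 0,
            cfg$read_length >= 1, cfg$read_length <= cfg$fragment_mean,
            cfg$error_rate >= 0, cfg$error_rate <= 1,
            all(means > 0), all(cfg$allelic_sigma >= 0),
            cfg$capture_bias_sigma >= 0,
            abs(sum(drb) - 1) < 1e-8, all(drb >= 0),
            setequal(names(drb), c(.DRB_PARALOGS, "none")))
  structure(cfg, class = "sim_config")
}

#' Synthesize a toy allele reference panel
#'
#' Builds, per locus, a random ancestral window sequence of the exact
#' mapping-window length plus flanking sequence, then derives alleles by
#' placing `divergence` random substitutions inside the window. Alleles
#' within a locus are guaranteed pairwise distinct over the window whenever
#' `divergence >= 1`.
#'
#' @param loci Character vector of locus names (default: all 12).
#' @param alleles_per_locus Alleles per locus (>= 2).
#' @param divergence Substitutions per allele window.
#' @param flank_length Flanking bases on each side of the window.
#' @param seed Integer seed; the same seed reproduces the panel exactly.
#' @return An `hla_panel`. Allele names are `LOCUS*01:<i>:01`.
#' @export
synthesize_panel <- function(loci = .LOCI, alleles_per_locus = 3,
                             divergence = 4, flank_length = 100,
                             seed = NULL) {
  stopifnot(alleles_per_locus >= 2, divergence >= 0, flank_length >= 0)
  vapply(loci, assert_locus, character(1))
  if (divergence == 0 && alleles_per_locus > 1) {
    warning("divergence = 0: alleles within a locus are indistinguishable",
            call. = FALSE)
  }
  with_seed(seed, {
    alleles <- list()
    for (lc in loci) {
      win <- mapping_window(lc)
      anc <- random_dna(win$expected_length_bp)
      fl5 <- if (flank_length > 0) random_dna(flank_length) else ""
      fl3 <- if (flank_length > 0) random_dna(flank_length) else ""
      seen <- character(0)
      for (i in seq_len(alleles_per_locus)) {
        wseq <- mutate_dna(anc, divergence)$seq
        tries <- 0
        while (divergence >= 1 && wseq %in% seen && tries < 50) {
          wseq <- mutate_dna(anc, divergence)$seq
          tries <- tries + 1
        }
        if (divergence >= 1 && wseq %in% seen) {
          warning("could not make allele ", i, " of locus ", lc,
                  " distinct; panel contains indistinguishable alleles",
                  call. = FALSE)
        }
        seen <- c(seen, wseq)
        # split window back into exons and lay out flank5|exons|flank3
        offs <- cumsum(c(0L, win$exon_lengths))
        starts <- flank_length + offs[-length(offs)]
        ends <- flank_length + offs[-1]
        exons <- data.frame(exon_id = win$exon_ids, start = starts, end = ends)
        seq <- paste0(fl5, wseq, fl3)
        nm <- sprintf("%s*01:%02d:01", lc, i)
        alleles[[nm]] <- allele_reference(nm, seq, exons)
      }
    }
    reference_set(unname(alleles))
  })
}

#' Simulate diploid genotypes with DR haplotype structure
#'
#' Each haplotype receives one allele per non-paralog locus in the panel,
#' uniformly at random, and at most one secondary DRB gene (DRB3/DRB4/DRB5
#' or none) drawn from `drb_haplotype_model`.
#'
#' @param panel An `hla_panel`.
#' @param n_samples Number of samples.
#' @param drb_haplotype_model Named probabilities over
#'   `c("DRB3","DRB4","DRB5","none")`; paralogs absent from the panel get
#'   probability 0 (renormalized).
#' @param seed Integer seed.
#' @return Long-format data.frame: `sample_id`, `haplotype` (1/2), `locus`,
#'   `allele`.
#' @export
simulate_genotypes <- function(panel, n_samples,
                               drb_haplotype_model = NULL, seed = NULL) {
  stopifnot(inherits(panel, "hla_panel"), n_samples >= 1)
  drb <- drb_haplotype_model %||% .DEFAULT_DRB_HAPLOTYPES
  loci <- panel_loci(panel)
  core <- setdiff(loci, .DRB_PARALOGS)
  paralogs <- intersect(loci, .DRB_PARALOGS)
  p <- drb[c(paralogs, "none")]
  p <- p / sum(p)
  with_seed(seed, {
    rows <- list()
    for (s in seq_len(n_samples)) {
      sid <- sprintf("S%03d", s)
      for (h in 1:2) {
        for (lc in core) {
          al <- sample(panel_alleles(panel, lc), 1)
          rows[[length(rows) + 1]] <-
            data.frame(sample_id = sid, haplotype = h, locus = lc,
                       allele = al, stringsAsFactors = FALSE)
        }
        if (length(paralogs)) {
          pick <- sample(names(p), 1, prob = p)
          if (pick != "none") {
            al <- sample(panel_alleles(panel, pick), 1)
            rows[[length(rows) + 1]] <-
              data.frame(sample_id = sid, haplotype = h, locus = pick,
                         allele = al, stringsAsFactors = FALSE)
          }
        }
      }
    }
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out
  })
}

#' Simulate allele-level expression weights
#'
#' Weight of an expressed allele copy = locus mean x per-copy log-normal
#' allelic-imbalance multiplier x per-allele log-normal capture efficiency.
#' Capture bias is drawn once per panel allele (probe-affinity differences
#' are a property of the allele, not the sample) and recorded.
#'
#' @param genotypes Output of [simulate_genotypes()].
#' @param config A [sim_config()] (uses `locus_mean_expression`,
#'   `allelic_sigma`, `capture_bias_sigma`, `seed`).
#' @param panel Optional `hla_panel`; when given, capture bias is drawn for
#'   every panel allele (otherwise for the alleles present in `genotypes`).
#' @return Truth data.frame: `sample_id`, `haplotype`, `locus`, `allele`,
#'   `capture_bias`, `weight` (the true relative expression of the copy,
#'   bias included) and `expression` (bias-free true expression).
#' @export
simulate_expression <- function(genotypes, config, panel = NULL) {
  stopifnot(inherits(config, "sim_config"))
  means <- config$locus_mean_expression
  sig <- config$allelic_sigma
  if (length(sig) == 1) {
    sig <- stats::setNames(rep(sig, length(.LOCI)), .LOCI)
  }
  with_seed(config$seed, {
    all_alleles <- if (!is.null(panel)) panel_alleles(panel) else
      sort(unique(genotypes$allele))
    bias <- stats::setNames(
      exp(stats::rnorm(length(all_alleles), 0, config$capture_bias_sigma)),
      all_alleles)
    truth <- genotypes
    imb <- exp(stats::rnorm(nrow(truth), 0, sig[truth$locus]))
    truth$capture_bias <- unname(bias[truth$allele])
    truth$expression <- unname(means[truth$locus]) * imb
    truth$weight <- truth$expression * truth$capture_bias
    truth
  })
}

# substitute bases at random positions with probability `rate`
add_read_errors <- function(reads, rate) {
  if (rate <= 0 || !length(reads)) return(reads)
  L <- nchar(reads)
  stopifnot(length(unique(L)) <= 1)
  n <- length(reads); w <- L[1]
  hits <- which(stats::runif(n * w) < rate)
  if (!length(hits)) return(reads)
  i <- ((hits - 1) %/% w) + 1   # read index
  j <- ((hits - 1) %% w) + 1    # base index
  for (k in seq_along(hits)) {
    old <- substr(reads[i[k]], j[k], j[k])
    substr(reads[i[k]], j[k], j[k]) <-
      sample(setdiff(c("A", "C", "G", "T"), old), 1)
  }
  reads
}

#' Emit paired 150 bp reads from an expression truth table
#'
#' Fragments are drawn per sample from the window-containing transcript of
#' each expressed allele copy, with per-copy fragment counts multinomial in
#' the truth weights; mate 1 is the fragment 5' end, mate 2 the
#' reverse-complemented 3' end; substitution errors are applied at
#' `config$error_rate`. Read names encode sample, fragment index and source
#' allele (`<sample>|f<k>|<allele>/1`), so downstream results can be audited
#' against truth. Byte-identical output under a fixed `config$seed`.
#'
#' @param truth Data.frame with `sample_id`, `allele` and `weight` (e.g. from
#'   [simulate_expression()], or hand-built for controlled experiments).
#' @param panel The `hla_panel` the alleles refer to.
#' @param config A [sim_config()].
#' @param out_dir If non-`NULL`, write `<sample>_R1.fastq`/`_R2.fastq`
#'   (Phred+33, constant quality "I") plus `truth.tsv` there.
#' @return Invisibly, a list with `reads` (per sample: named `DNAStringSet`s
#'   `r1`, `r2`), `truth`, and `files` when written.
#' @export
emit_reads <- function(truth, panel, config, out_dir = NULL) {
  stopifnot(inherits(panel, "hla_panel"), inherits(config, "sim_config"),
            all(c("sample_id", "allele", "weight") %in% names(truth)),
            all(truth$weight > 0), all(is.finite(truth$weight)))
  missing <- setdiff(unique(truth$allele), names(panel$alleles))
  if (length(missing)) {
    stop("truth alleles not in panel: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  rl <- config$read_length
  with_seed(config$seed, {
    out <- list()
    for (sid in unique(truth$sample_id)) {
      tt <- truth[truth$sample_id == sid, ]
      npairs <- stats::rmultinom(1, config$depth, tt$weight)[, 1]
      r1 <- character(0); r2 <- character(0); nms <- character(0)
      frag_i <- 0L
      for (k in seq_len(nrow(tt))) {
        m <- npairs[k]
        if (m == 0) next
        tseq <- panel$alleles[[tt$allele[k]]]$sequence
        tlen <- nchar(tseq)
        fl <- round(stats::rnorm(m, config$fragment_mean, config$fragment_sd))
        too_long <- fl > tlen
        if (any(too_long)) {
          warning("fragment longer than transcript for ", tt$allele[k],
                  "; truncated", call. = FALSE)
          fl[too_long] <- tlen
        }
        fl <- pmax(fl, rl)
        st <- floor(stats::runif(m, 1, tlen - fl + 1 + 1))
        frag <- substring(tseq, st, st + fl - 1)
        r1 <- c(r1, substring(frag, 1, rl))
        r2 <- c(r2, revcomp(substring(frag, fl - rl + 1, fl)))
        nms <- c(nms, sprintf("%s|f%06d|%s", sid, frag_i + seq_len(m),
                              tt$allele[k]))
        frag_i <- frag_i + m
      }
      r1 <- add_read_errors(r1, config$error_rate)
      r2 <- add_read_errors(r2, config$error_rate)
      s1 <- Biostrings::DNAStringSet(r1)
      s2 <- Biostrings::DNAStringSet(r2)
      names(s1) <- paste0(nms, "/1")
      names(s2) <- paste0(nms, "/2")
      out[[sid]] <- list(r1 = s1, r2 = s2)
    }
    files <- NULL
    if (!is.null(out_dir)) {
      dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
      files <- list()
      for (sid in names(out)) {
        f1 <- file.path(out_dir, paste0(sid, "_R1.fastq"))
        f2 <- file.path(out_dir, paste0(sid, "_R2.fastq"))
        write_fastq(out[[sid]]$r1, f1)
        write_fastq(out[[sid]]$r2, f2)
        files[[sid]] <- c(r1 = f1, r2 = f2)
      }
      write_tsv(truth, file.path(out_dir, "truth.tsv"))
      files$truth <- file.path(out_dir, "truth.tsv")
    }
    invisible(list(reads = out, truth = truth, files = files))
  })
}

write_fastq <- function(seqs, path) {
  qual <- Biostrings::BStringSet(strrep("I", Biostrings::width(seqs)))
  Biostrings::writeXStringSet(seqs, path, format = "fastq", qualities = qual)
  invisible(path)
}

read_fastq <- function(path) {
  Biostrings::readDNAStringSet(path, format = "fastq")
}
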