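# Fixtures and independent oracles used across the suite.
# Oracles are deliberately written as a different algorithm from the code
# paths they check (literal scans and manual interpolation, not Biostrings
# dictionaries or stats::quantile).

rand_seq <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

rand_seq_fixed <- function(n, seed) {
  set.seed(seed)
  rand_seq(n)
}

rc_chr <- function(x) {
  chartr("ACGT", "TGCA", vapply(strsplit(x, ""), function(ch)
    paste(rev(ch), collapse = ""), character(1)))
}

# Hand-built panel: one class I locus (A: exons 2+3) and one class II locus
# (DQB1: exon 2), tiny exons, controlled sequences. Layout per allele:
# 5' flank | exon(s) | 3' flank.
toy_panel <- function() {
  mk <- function(name, fl5, exons_seq, fl3, exon_ids) {
    seq <- paste0(fl5, paste(exons_seq, collapse = ""), fl3)
    starts <- nchar(fl5) + cumsum(c(0L, head(nchar(exons_seq), -1)))
    ends <- starts + nchar(exons_seq)
    allele_reference(name, seq,
                     data.frame(exon_id = exon_ids, start = starts,
                                end = ends))
  }
  reference_set(list(
    mk("A*01:01:01", "AAAA", c("ACGT", "TTGG"), "CCCC", c(2L, 3L)),
    mk("A*01:02:01", "AAAA", c("AGGT", "TTCG"), "CCCC", c(2L, 3L)),
    mk("DQB1*01:01:01", "GGGG", "ACACACAC", "TTTT", 2L),
    mk("DQB1*01:02:01", "GGGG", "ACACTCAC", "TTTT", 2L)
  ))
}

# Literal brute-force matcher: for every read, every allele, every offset,
# compare the substring character-by-character (both strands). Only usable
# on tiny inputs.
oracle_match_naive <- function(reads, panel) {
  if (is.null(names(reads)))
    names(reads) <- sprintf("read%06d", seq_along(reads))
  keep <- !grepl("[^ACGT]", reads)
  reads <- reads[keep]
  out <- list()
  for (rid in names(reads)) {
    for (strand in c("+", "-")) {
      q <- if (strand == "+") reads[[rid]] else rc_chr(reads[[rid]])
      w <- nchar(q)
      for (al in names(panel$alleles)) {
        ref <- panel$alleles[[al]]
        L <- nchar(ref$sequence)
        if (w > L) next
        for (st in seq_len(L - w + 1)) {
          if (substr(ref$sequence, st, st + w - 1) == q) {
            out[[length(out) + 1]] <- data.frame(
              read_id = rid, allele = al, locus = ref$locus,
              start = st, end = st + w - 1L, orientation = strand,
              stringsAsFactors = FALSE)
          }
        }
      }
    }
  }
  sort_hits(do.call(rbind, out))
}

# Enumeration oracle: every substring of every allele at every position is
# generated and joined against the read set by string equality. Scales to
# the randomized-panel property while staying independent of the
# dictionary-based implementation.
oracle_match_enum <- function(reads, panel) {
  if (is.null(names(reads)))
    names(reads) <- sprintf("read%06d", seq_along(reads))
  keep <- !grepl("[^ACGT]", reads)
  reads <- reads[keep]
  rc <- rc_chr_vec(reads)
  out <- list()
  for (al in names(panel$alleles)) {
    ref <- panel$alleles[[al]]
    L <- nchar(ref$sequence)
    for (w in unique(nchar(reads))) {
      if (w > L) next
      starts <- seq_len(L - w + 1)
      subs <- substring(ref$sequence, starts, starts + w - 1)
      sel <- which(nchar(reads) == w)
      for (strand in c("+", "-")) {
        q <- if (strand == "+") reads[sel] else rc[sel]
        by_str <- split(names(reads)[sel], q)
        hit <- subs %in% names(by_str)
        if (!any(hit)) next
        for (k in which(hit)) {
          for (rid in by_str[[subs[k]]]) {
            out[[length(out) + 1]] <- data.frame(
              read_id = rid, allele = al, locus = ref$locus,
              start = starts[k], end = starts[k] + w - 1L,
              orientation = strand, stringsAsFactors = FALSE)
          }
        }
      }
    }
  }
  sort_hits(do.call(rbind, out))
}

rc_chr_vec <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

sort_hits <- function(h) {
  if (is.null(h) || !nrow(h)) {
    return(data.frame(read_id = character(0), allele = character(0),
                      locus = character(0), start = integer(0),
                      end = integer(0), orientation = character(0),
                      stringsAsFactors = FALSE))
  }
  h <- h[order(h$read_id, h$allele, h$start, h$orientation), ]
  rownames(h) <- NULL
  h
}

# Manual inclusive-interpolation quantile (independent of stats::quantile).
oracle_quantile <- function(x, p) {
  x <- sort(x)
  n <- length(x)
  vapply(p, function(pp) {
    h <- (n - 1) * pp + 1
    lo <- floor(h); hi <- ceiling(h)
    x[lo] + (h - lo) * (x[hi] - x[lo])
  }, numeric(1))
}

# Brute-force in-phase counter: scans each read against both alleles' full
# sequences at every offset on both strands, records window overlap, and
# applies the unambiguous-assignment rule.
oracle_in_phase <- function(reads, allele_a, allele_b, panel) {
  scan_one <- function(q, ref) {
    # returns matrix of (start, end) exact placements on ref (both strands)
    hits <- NULL
    for (s in c(q, rc_chr(q))) {
      w <- nchar(s); L <- nchar(ref$sequence)
      if (w > L) next
      for (st in seq_len(L - w + 1)) {
        if (substr(ref$sequence, st, st + w - 1) == s) {
          hits <- rbind(hits, c(st, st + w - 1))
        }
      }
    }
    hits
  }
  overlaps_window <- function(hits, ref) {
    if (is.null(hits)) return(FALSE)
    win <- mapping_window(ref$locus)
    ids <- match(win$exon_ids, ref$exons$exon_id)
    ex <- ref$exons[ids, ]
    any(apply(hits, 1, function(h)
      any(h[1] <= ex$end & h[2] >= ex$start + 1)))
  }
  ra <- panel$alleles[[allele_a]]
  rb <- panel$alleles[[allele_b]]
  counts <- c(0, 0)
  for (q in as.character(reads)) {
    ha <- scan_one(q, ra); hb <- scan_one(q, rb)
    a_ok <- overlaps_window(ha, ra) && is.null(hb)
    b_ok <- overlaps_window(hb, rb) && is.null(ha)
    counts <- counts + c(a_ok, b_ok)
  }
  stats::setNames(counts, c(allele_a, allele_b))
}

# Pair counts by source allele recovered from simulator read names.
truth_pair_counts <- function(reads_r1) {
  src <- sub("/1$", "", sub("^[^|]+\\|f[0-9]+\\|", "", names(reads_r1)))
  table(src)
}
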