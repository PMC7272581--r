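# Perfect-match genotyping.
#
# A read supports an allele iff the full read (or its reverse complement)
# occurs as an exact substring of the allele's reference sequence: the
# 100%-match rule that prevents mismapping between the highly similar HLA
# loci and suppresses PCR crossover artifacts. Matching is exact-substring
# by contract; the implementation uses Biostrings' preprocessed dictionary
# (PDict/matchPDict) over equal-width read batches.

.HIT_PROTO <- list(read_id = character, allele = character, locus = character,
                   start = integer, end = integer, orientation = character)

#' Match reads against a reference panel at 100% identity
#'
#' Reports every exact full-length occurrence of each read, on either
#' strand, across all panel alleles. Reads containing non-ACGT characters
#' (e.g. N) never match.
#'
#' @param reads A named `DNAStringSet` or named character vector. Names are
#'   the read ids carried into the hit table.
#' @param panel An `hla_panel`.
#' @return Hit data.frame: `read_id`, `allele`, `locus`, `start`, `end`
#'   (1-based inclusive span on the allele sequence), `orientation`
#'   (`"+"` read matches forward, `"-"` its reverse complement matches).
#' @export
match_reads <- function(reads, panel) {
  stopifnot(inherits(panel, "hla_panel"))
  if (!length(panel$alleles)) stop("empty reference panel", call. = FALSE)
  if (is.character(reads)) {
    nm <- names(reads)
    reads <- Biostrings::DNAStringSet(reads)
    names(reads) <- nm
  }
  if (is.null(names(reads))) {
    names(reads) <- sprintf("read%06d", seq_along(reads))
  }
  if (!length(reads)) return(empty_df(.HIT_PROTO))
  # drop reads with any ambiguous base: the perfect-match rule excludes them
  freq <- Biostrings::alphabetFrequency(reads, baseOnly = TRUE)
  clean <- freq[, "other"] == 0
  reads <- reads[clean]
  if (!length(reads)) return(empty_df(.HIT_PROTO))

  allele_names <- names(panel$alleles)
  loci <- vapply(panel$alleles, `[[`, character(1), "locus")
  subjects <- lapply(panel$alleles,
                     function(a) Biostrings::DNAString(a$sequence))
  out <- list()
  widths <- Biostrings::width(reads)
  for (w in unique(widths)) {
    grp <- reads[widths == w]
    ids <- names(grp)
    pd_f <- Biostrings::PDict(grp)
    pd_r <- Biostrings::PDict(Biostrings::reverseComplement(grp))
    for (ai in seq_along(allele_names)) {
      subj <- subjects[[ai]]
      if (length(subj) < w) next
      for (ori in c("+", "-")) {
        pd <- if (ori == "+") pd_f else pd_r
        mi <- Biostrings::matchPDict(pd, subj)
        st <- Biostrings::startIndex(mi)
        cnt <- lengths(st)
        if (!sum(cnt)) next
        starts <- unlist(st[cnt > 0], use.names = FALSE)
        out[[length(out) + 1]] <- data.frame(
          read_id = rep(ids[cnt > 0], cnt[cnt > 0]),
          allele = allele_names[ai], locus = unname(loci[ai]),
          start = starts, end = starts + w - 1L, orientation = ori,
          stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(out)) return(empty_df(.HIT_PROTO))
  res <- do.call(rbind, out)
  res <- res[order(res$read_id, res$allele, res$start, res$orientation), ]
  rownames(res) <- NULL
  res
}

# pair id: mate suffix stripped, so a read pair supports an allele once
pair_ids <- function(read_id) sub("/[12]$", "", read_id)

#' Call a genotype for one locus from perfect-match hits
#'
#' Builds, per read pair, the set of alleles it matches; pairs matching
#' alleles of more than one locus are excluded (cross-locus mismapping
#' guard). The call selects the allele pair maximizing the number of
#' explained pairs (pairs hitting either allele), breaking ties by total
#' unique support (pairs hitting exactly one of the two) and then by
#' lexicographic pair name; remaining exact ties are reported in
#' `ambiguity`. A heterozygous call requires unique support of at least
#' `min_unique_support` on both alleles; otherwise the best single allele is
#' called (homozygous, or hemizygous for the secondary DRB paralogs, whose
#' single-copy state cannot be distinguished from homozygosity by reads).
#'
#' @param hits Hit table from [match_reads()] (all loci; the function
#'   filters).
#' @param locus Locus to call.
#' @param min_unique_support Minimum unique read pairs per heterozygous
#'   allele (default 10).
#' @return An object of class `genotype_call`: list with `locus`, `alleles`
#'   (0-2 names), `zygosity` (`"heterozygous"`, `"homozygous"`,
#'   `"hemizygous"`, `"absent"`), `support` (named unique-pair counts),
#'   `ambiguity` (character vector of tied alternative pairs), `n_pairs`,
#'   `n_cross_locus`.
#' @export
call_genotype <- function(hits, locus, min_unique_support = 10) {
  assert_locus(locus)
  paralog <- locus %in% .DRB_PARALOGS
  empty <- structure(list(locus = locus, alleles = character(0),
                          zygosity = "absent", support = integer(0),
                          ambiguity = character(0), n_pairs = 0L,
                          n_cross_locus = 0L),
                     class = "genotype_call")
  if (!nrow(hits)) return(empty)
  pid <- pair_ids(hits$read_id)
  nl <- tapply(hits$locus, pid, function(z) length(unique(z)))
  cross <- names(nl)[nl > 1]
  keep <- !(pid %in% cross) & hits$locus == locus
  h <- hits[keep, ]
  empty$n_cross_locus <- sum(unique(pid) %in% cross)
  if (!nrow(h)) return(empty)

  pid <- pair_ids(h$read_id)
  alleles <- sort(unique(h$allele))
  M <- table(pid, factor(h$allele, levels = alleles)) > 0
  M <- matrix(as.numeric(M), nrow = nrow(M), dimnames = dimnames(M))
  total <- nrow(M)
  co <- crossprod(M)            # co[a,b] = pairs hitting both a and b
  ca <- diag(co)                # pairs hitting a

  single_call <- function(allele, support) {
    structure(list(locus = locus, alleles = allele,
                   zygosity = if (paralog) "hemizygous" else "homozygous",
                   support = stats::setNames(as.integer(support), allele),
                   ambiguity = character(0), n_pairs = as.integer(total),
                   n_cross_locus = empty$n_cross_locus),
              class = "genotype_call")
  }

  # a single allele explaining every locus read: homozygous (hemizygous for
  # the secondary DRB paralogs)
  full <- alleles[ca == total]
  if (length(full)) {
    a <- sort(full)[1]
    out <- single_call(a, ca[a])
    if (length(full) > 1) out$ambiguity <- setdiff(sort(full), a)
    return(out)
  }

  best <- NULL
  if (length(alleles) >= 2) {
    cmb <- utils::combn(alleles, 2)
    pa <- cmb[1, ]; pb <- cmb[2, ]
    overlap <- co[cbind(pa, pb)]
    expl <- ca[pa] + ca[pb] - overlap
    ua <- ca[pa] - overlap
    ub <- ca[pb] - overlap
    valid <- ua >= min_unique_support & ub >= min_unique_support
    if (any(valid)) {
      expl <- expl[valid]; usum <- (ua + ub)[valid]
      pa <- pa[valid]; pb <- pb[valid]
      ua <- ua[valid]; ub <- ub[valid]
      key <- order(-expl, -usum, pa, pb)
      top <- key[1]
      ties <- which(expl == expl[top] & usum == usum[top])
      best <- list(a = pa[top], b = pb[top], ua = ua[top], ub = ub[top],
                   ties = setdiff(paste0(pa[ties], "/", pb[ties]),
                                  paste0(pa[top], "/", pb[top])))
    }
  }
  if (is.null(best)) {
    # no pair with two-sided unique support; fall back to best single allele
    a <- sort(alleles[ca == max(ca)])[1]
    return(single_call(a, ca[a]))
  }
  structure(list(
    locus = locus, alleles = c(best$a, best$b), zygosity = "heterozygous",
    support = stats::setNames(as.integer(c(best$ua, best$ub)),
                              c(best$a, best$b)),
    ambiguity = best$ties, n_pairs = as.integer(total),
    n_cross_locus = empty$n_cross_locus
  ), class = "genotype_call")
}

#' @export
print.genotype_call <- function(x, ...) {
  cat(sprintf("<genotype_call> HLA-%s: %s (%s; support %s)\n", x$locus,
              if (length(x$alleles)) paste(x$alleles, collapse = " / ")
              else "-",
              x$zygosity, paste(x$support, collapse = "/")))
  if (length(x$ambiguity))
    cat("  tied alternatives:", paste(x$ambiguity, collapse = ", "), "\n")
  invisible(x)
}

#' Genotype every panel locus of one sample
#'
#' Convenience wrapper: matches the sample's reads once and calls
#' [call_genotype()] for each locus in the panel.
#'
#' @param reads Named `DNAStringSet`/character vector of this sample's reads
#'   (both mates together), or a precomputed hit table via `hits`.
#' @param panel An `hla_panel`.
#' @param min_unique_support Passed to [call_genotype()].
#' @param hits Optional precomputed [match_reads()] table.
#' @return Named list of `genotype_call`s, one per panel locus, with the hit
#'   table attached as attribute `hits`.
#' @export
genotype_sample <- function(reads = NULL, panel, min_unique_support = 10,
                            hits = NULL) {
  hits <- hits %||% match_reads(reads, panel)
  calls <- lapply(panel_loci(panel), function(lc)
    call_genotype(hits, lc, min_unique_support))
  names(calls) <- panel_loci(panel)
  attr(calls, "hits") <- hits
  calls
}

#' Tabulate genotype calls
#'
#' @param calls Named list of `genotype_call`s (e.g. per-sample output of
#'   [genotype_sample()]), or a list of such lists keyed by sample id.
#' @return Data.frame: `sample_id` (when nested), `locus`, `allele1`,
#'   `allele2`, `zygosity`, `support1`, `support2`, `ambiguity`.
#' @export
genotype_table <- function(calls) {
  one <- function(cl, sid = NA_character_) {
    do.call(rbind, lapply(cl, function(x) {
      data.frame(
        sample_id = sid, locus = x$locus,
        allele1 = if (length(x$alleles) >= 1) x$alleles[1] else NA_character_,
        allele2 = if (length(x$alleles) >= 2) x$alleles[2] else NA_character_,
        zygosity = x$zygosity,
        support1 = if (length(x$support) >= 1) x$support[[1]] else NA_integer_,
        support2 = if (length(x$support) >= 2) x$support[[2]] else NA_integer_,
        ambiguity = if (length(x$ambiguity))
          paste(x$ambiguity, collapse = ";") else "",
        stringsAsFactors = FALSE)
    }))
  }
  nested <- length(calls) && inherits(calls[[1]], "list") &&
    !inherits(calls[[1]], "genotype_call")
  out <- if (nested) {
    do.call(rbind, lapply(names(calls), function(s) one(calls[[s]], s)))
  } else {
    one(calls)
  }
  rownames(out) <- NULL
  out
}

#' Flag candidate novel single-nucleotide variants
#'
#' Reads that fail the perfect-match filter everywhere but match a called
#' allele with exactly one substitution, agreeing in position and base
#' across at least `min_support` reads, are reported as novel-SNP
#' candidates. Only positions inside the mapping window (the analysis
#' region) are reported; candidates would be confirmed by targeted
#' re-sequencing in practice.
#'
#' @param reads Named `DNAStringSet`/character vector of a sample's reads.
#' @param calls `genotype_call` or list of calls whose alleles are screened.
#' @param panel An `hla_panel`.
#' @param min_support Minimum concordant reads (default 10).
#' @param hits Optional precomputed [match_reads()] table for `reads`.
#' @return Data.frame: `locus`, `nearest_allele`, `ref_pos` (1-based on the
#'   reference), `window_pos` (1-based within the concatenated window),
#'   `ref_base`, `observed_base`, `supporting_reads`.
#' @export
flag_novel_variants <- function(reads, calls, panel, min_support = 10,
                                hits = NULL) {
  if (inherits(calls, "genotype_call")) calls <- list(calls)
  called <- unique(unlist(lapply(calls, `[[`, "alleles")))
  proto <- list(locus = character, nearest_allele = character,
                ref_pos = integer, window_pos = integer,
                ref_base = character, observed_base = character,
                supporting_reads = integer)
  if (!length(called)) return(empty_df(proto))
  if (is.character(reads)) {
    nm <- names(reads)
    reads <- Biostrings::DNAStringSet(reads)
    names(reads) <- nm
  }
  hits <- hits %||% match_reads(reads, panel)
  unmatched <- reads[!names(reads) %in% hits$read_id]
  if (!length(unmatched)) return(empty_df(proto))

  recs <- list()
  for (al in called) {
    ref <- panel$alleles[[al]]
    subj <- Biostrings::DNAString(ref$sequence)
    refchars <- strsplit(ref$sequence, "", fixed = TRUE)[[1]]
    wins <- window_intervals(ref)
    if (is.null(wins)) next
    for (ri in seq_along(unmatched)) {
      for (ori in c("+", "-")) {
        q <- if (ori == "+") unmatched[[ri]]
             else Biostrings::reverseComplement(unmatched[[ri]])
        m <- Biostrings::matchPattern(q, subj, max.mismatch = 1)
        if (!length(m)) next
        qchars <- strsplit(as.character(q), "", fixed = TRUE)[[1]]
        for (k in seq_along(m)) {
          st <- Biostrings::start(m)[k]
          span <- refchars[st:(st + length(qchars) - 1)]
          diffpos <- which(span != qchars)
          if (length(diffpos) != 1) next  # exact matches were filtered; want 1
          rp <- st + diffpos - 1L
          recs[[length(recs) + 1]] <- data.frame(
            locus = ref$locus, nearest_allele = al, ref_pos = rp,
            ref_base = refchars[rp], observed_base = qchars[diffpos],
            stringsAsFactors = FALSE)
        }
      }
    }
  }
  if (!length(recs)) return(empty_df(proto))
  d <- do.call(rbind, recs)
  agg <- stats::aggregate(
    list(supporting_reads = rep(1L, nrow(d))),
    by = d[, c("locus", "nearest_allele", "ref_pos", "ref_base",
               "observed_base")],
    FUN = sum)
  agg <- agg[agg$supporting_reads >= min_support, ]
  if (!nrow(agg)) return(empty_df(proto))
  # reference position -> window coordinate; drop positions outside window
  agg$window_pos <- NA_integer_
  for (i in seq_len(nrow(agg))) {
    ref <- panel$alleles[[agg$nearest_allele[i]]]
    wins <- window_intervals(ref)
    off <- 0L
    for (j in seq_len(nrow(wins))) {
      if (agg$ref_pos[i] >= wins$start[j] && agg$ref_pos[i] <= wins$end[j]) {
        agg$window_pos[i] <- off + (agg$ref_pos[i] - wins$start[j] + 1L)
        break
      }
      off <- off + (wins$end[j] - wins$start[j] + 1L)
    }
  }
  agg <- agg[!is.na(agg$window_pos),
             c("locus", "nearest_allele", "ref_pos", "window_pos",
               "ref_base", "observed_base", "supporting_reads")]
  agg <- agg[order(agg$locus, agg$nearest_allele, agg$ref_pos), ]
  rownames(agg) <- NULL
  agg
}
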