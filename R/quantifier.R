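# Phase-aware allele-level read counting and locus-set normalization.
#
# Only completely phased heterozygous allele pairs are quantified: a read
# counts for an allele iff it perfectly matches that allele's reference,
# overlaps the mapping window by at least one base, and does not perfectly
# match the partner allele anywhere (unambiguous, "in-phase" assignment).
# Raw counts are divided by the allele's window length (target size) and
# scaled so a sample's selected locus set sums to one million.

#' Classify the phase status of a genotype call
#'
#' A heterozygous pair whose window sequences differ in every window exon is
#' completely phased (reads from each exon can be assigned); a pair
#' differing in only some window exons is partially phased (the identical
#' exon's reads cannot be split); identical window sequences, or a single
#' allele, are homozygous-equivalent; a single secondary-DRB copy is
#' hemizygous. Alleles lacking a window exon (partial references) make the
#' pair partially phased. Only completely phased pairs enter the
#' comparative datasets.
#'
#' @param call A `genotype_call`.
#' @param panel An `hla_panel`.
#' @return One of `"completely_phased"`, `"partially_phased"`,
#'   `"homozygous"`, `"hemizygous"`, `"absent"`.
#' @export
classify_phase <- function(call, panel) {
  stopifnot(inherits(call, "genotype_call"))
  if (call$zygosity == "absent") return("absent")
  if (call$zygosity == "hemizygous") return("hemizygous")
  if (call$zygosity == "homozygous") return("homozygous")
  a <- panel$alleles[[call$alleles[1]]]
  b <- panel$alleles[[call$alleles[2]]]
  ea <- tryCatch(extract_window(a, per_exon = TRUE), error = function(e) NULL)
  eb <- tryCatch(extract_window(b, per_exon = TRUE), error = function(e) NULL)
  if (is.null(ea) || is.null(eb)) return("partially_phased")
  differ <- ea != eb
  if (all(differ)) "completely_phased"
  else if (any(differ)) "partially_phased"
  else "homozygous"
}

#' Count in-phase reads for a phased allele pair
#'
#' Each mate is counted independently. A mate counts for allele X iff it has
#' a perfect-match hit on X overlapping X's mapping window by >= 1 base and
#' no perfect-match hit anywhere on the partner allele; mates matching both
#' alleles are out of phase and discarded (or split 0.5/0.5 with
#' `split_ambiguous = TRUE`, a sensitivity mode, default off).
#'
#' @param hits Hit table from [match_reads()] covering this sample's reads.
#' @param allele_a,allele_b The phased pair (may be two alleles of one locus
#'   or, for the secondary DRB paralogs, of two paralog loci).
#' @param panel An `hla_panel`.
#' @param split_ambiguous Count both-allele mates 0.5 to each side.
#' @return Named numeric vector of raw in-phase counts for the two alleles.
#' @export
count_in_phase <- function(hits, allele_a, allele_b, panel,
                           split_ambiguous = FALSE) {
  stopifnot(allele_a != allele_b)
  in_window <- function(allele) {
    ref <- panel$alleles[[allele]]
    wins <- window_intervals(ref)
    h <- hits[hits$allele == allele, ]
    if (!nrow(h) || is.null(wins)) return(character(0))
    ok <- rep(FALSE, nrow(h))
    for (j in seq_len(nrow(wins))) {
      ok <- ok | (h$start <= wins$end[j] & h$end >= wins$start[j])
    }
    unique(h$read_id[ok])
  }
  matches_any <- function(allele) unique(hits$read_id[hits$allele == allele])
  wa <- in_window(allele_a)
  wb <- in_window(allele_b)
  ma <- matches_any(allele_a)
  mb <- matches_any(allele_b)
  only_a <- setdiff(wa, mb)
  only_b <- setdiff(wb, ma)
  out <- c(length(only_a), length(only_b))
  if (split_ambiguous) {
    both <- union(intersect(wa, mb), intersect(wb, ma))
    out <- out + length(both) / 2
  }
  stats::setNames(out, c(allele_a, allele_b))
}

#' Size-standardize a raw count
#'
#' @param raw Raw in-phase read count (>= 0).
#' @param target_size_bp Mapping-window length of the allele in bp.
#' @return Reads per base: `raw / target_size_bp`.
#' @examples
#' standardize_by_size(546, 546)  # 1
#' @export
standardize_by_size <- function(raw, target_size_bp) {
  stopifnot(all(raw >= 0))
  if (any(target_size_bp <= 0)) stop("target_size_bp must be positive")
  raw / target_size_bp
}

#' Scale a sample's size-standardized counts to one million
#'
#' @param x Non-negative size-standardized values of one sample's locus set;
#'   at least one must be positive.
#' @return `x * 1e6 / sum(x)`; sums to 1,000,000 exactly up to floating
#'   tolerance.
#' @examples
#' normalize_to_million(c(1, 1, 2))
#' @export
normalize_to_million <- function(x) {
  stopifnot(is.numeric(x), length(x) >= 1, all(x >= 0))
  s <- sum(x)
  if (s <= 0) stop("all-zero input: sample cannot be normalized",
                   call. = FALSE)
  x * (1e6 / s)
}

#' Locus-set configurations for the comparative datasets
#'
#' Set 1: all 12 loci (requires two distinguishable secondary-DRB copies);
#' set 2: class I (A, B, C); set 3: class II excluding DRB3/DRB4/DRB5;
#' set 4: class II including them (same DRB requirement as set 1).
#'
#' @param set_id Integer 1-4.
#' @return List with `set_id`, `loci`, `drb345_included`.
#' @export
locus_set_config <- function(set_id) {
  stopifnot(length(set_id) == 1, set_id %in% 1:4)
  info <- hla_loci()
  loci <- switch(set_id,
    info$name,
    .CLASS_I,
    setdiff(info$name[info$hla_class == "II"], .DRB_PARALOGS),
    info$name[info$hla_class == "II"]
  )
  list(set_id = as.integer(set_id), loci = loci,
       drb345_included = set_id %in% c(1L, 4L))
}

# Combine the per-paralog DRB3/4/5 calls of one sample into one composite
# quantification unit: at most two expressed copies exist per diploid
# genome. Two distinct copies (same paralog heterozygous, or two different
# paralogs) form a phaseable pair; one copy is hemizygous; none is absent.
drb_composite <- function(calls, panel) {
  paralog_calls <- calls[intersect(names(calls), .DRB_PARALOGS)]
  copies <- list()
  for (cl in paralog_calls) {
    if (cl$zygosity == "heterozygous") {
      copies <- c(copies, as.list(cl$alleles))
    } else if (cl$zygosity %in% c("homozygous", "hemizygous") &&
               length(cl$alleles)) {
      copies <- c(copies, list(cl$alleles[1]))
    }
  }
  copies <- unlist(copies)
  if (length(copies) == 0) return(list(status = "absent", alleles = character(0)))
  if (length(copies) == 1) return(list(status = "hemizygous", alleles = copies))
  if (length(copies) > 2) return(list(status = "partially_phased",
                                      alleles = copies))
  a <- panel$alleles[[copies[1]]]; b <- panel$alleles[[copies[2]]]
  if (a$locus == b$locus) {
    st <- classify_phase(calls[[a$locus]], panel)
    return(list(status = st, alleles = copies))
  }
  # different paralog loci: each copy has its own reference; the pair is
  # phaseable provided both windows are extractable
  ok <- !is.null(window_intervals(a)) && !is.null(window_intervals(b))
  list(status = if (ok) "completely_phased" else "partially_phased",
       alleles = sort(copies))
}

#' Quantify one sample: phase statuses and in-phase counts
#'
#' Classifies every called locus, treats DRB3/DRB4/DRB5 as one composite
#' unit (`"DRB3/4/5"` in the phase table), and computes raw in-phase counts
#' with target sizes for every completely phased pair.
#'
#' @param calls Per-locus `genotype_call` list (from [genotype_sample()]).
#' @param panel An `hla_panel`.
#' @param hits Hit table for the sample (defaults to `attr(calls, "hits")`).
#' @param sample_id Sample label carried into the output.
#' @param split_ambiguous Passed to [count_in_phase()].
#' @return List of data.frames: `phase` (`sample_id`, `unit`, `status`,
#'   `alleles`) and `counts` (`sample_id`, `locus`, `allele`, `raw_reads`,
#'   `target_size_bp`).
#' @export
quantify_sample <- function(calls, panel, hits = attr(calls, "hits"),
                            sample_id = "S1", split_ambiguous = FALSE) {
  stopifnot(!is.null(hits))
  phase <- list(); counts <- list()
  units <- setdiff(names(calls), .DRB_PARALOGS)
  for (lc in units) {
    st <- classify_phase(calls[[lc]], panel)
    phase[[lc]] <- data.frame(
      sample_id = sample_id, unit = lc, status = st,
      alleles = paste(calls[[lc]]$alleles, collapse = "/"),
      stringsAsFactors = FALSE)
    if (st == "completely_phased") {
      counts[[lc]] <- count_pair(hits, calls[[lc]]$alleles, panel,
                                 sample_id, split_ambiguous)
    }
  }
  if (any(names(calls) %in% .DRB_PARALOGS)) {
    comp <- drb_composite(calls, panel)
    phase[["DRB3/4/5"]] <- data.frame(
      sample_id = sample_id, unit = "DRB3/4/5", status = comp$status,
      alleles = paste(comp$alleles, collapse = "/"), stringsAsFactors = FALSE)
    if (comp$status == "completely_phased") {
      counts[["DRB3/4/5"]] <- count_pair(hits, comp$alleles, panel,
                                         sample_id, split_ambiguous)
    }
  }
  proto <- list(sample_id = character, locus = character, allele = character,
                raw_reads = numeric, target_size_bp = integer)
  list(
    phase = do.call(rbind, c(phase, list(make.row.names = FALSE))),
    counts = if (length(counts))
      do.call(rbind, c(counts, list(make.row.names = FALSE)))
    else empty_df(proto)
  )
}

count_pair <- function(hits, pair, panel, sample_id, split_ambiguous) {
  raw <- count_in_phase(hits, pair[1], pair[2], panel, split_ambiguous)
  data.frame(
    sample_id = sample_id,
    locus = vapply(pair, function(a) panel$alleles[[a]]$locus, character(1)),
    allele = pair,
    raw_reads = as.numeric(raw),
    target_size_bp = vapply(pair, function(a) {
      w <- extract_window(panel$alleles[[a]])
      attr(w, "target_size_bp")
    }, integer(1)),
    stringsAsFactors = FALSE, row.names = NULL)
}

#' Build a normalized comparative dataset for one locus set
#'
#' Restricts each sample to the completely phased loci of the set,
#' size-standardizes, and renormalizes within the set to one million per
#' sample. For sets including the secondary DRB genes (1 and 4) a sample
#' qualifies only if it carries two distinguishable DRB3/DRB4/DRB5 copies;
#' otherwise the sample is excluded from that set. Samples with no
#' qualifying loci (or all-zero counts) are omitted and listed in the
#' `excluded` attribute.
#'
#' @param counts Combined `counts` data.frame from [quantify_sample()] runs.
#' @param phase Combined `phase` data.frame from the same runs.
#' @param set_config A [locus_set_config()] (or integer set id 1-4).
#' @return Long-format data.frame: `sample_id`, `set_id`, `locus`, `allele`,
#'   `raw_reads`, `target_size_bp`, `size_standardized`, `normalized_reads`;
#'   attribute `excluded` names omitted samples and the reason.
#' @export
build_dataset <- function(counts, phase, set_config) {
  if (is.numeric(set_config)) set_config <- locus_set_config(set_config)
  loci <- set_config$loci
  excluded <- character(0)
  rows <- list()
  for (sid in unique(phase$sample_id)) {
    cnt <- counts[counts$sample_id == sid & counts$locus %in% loci, ]
    if (set_config$drb345_included) {
      ph <- phase[phase$sample_id == sid & phase$unit == "DRB3/4/5", ]
      two_drb <- nrow(ph) == 1 && ph$status == "completely_phased"
      if (!two_drb) {
        excluded[sid] <- "no phased DRB3/4/5 allele pair"
        next
      }
    } else {
      cnt <- cnt[!cnt$locus %in% .DRB_PARALOGS, ]
    }
    if (!nrow(cnt)) {
      excluded[sid] <- "no completely phased locus in set"
      next
    }
    ss <- standardize_by_size(cnt$raw_reads, cnt$target_size_bp)
    if (sum(ss) <= 0) {
      excluded[sid] <- "all-zero counts in set"
      next
    }
    cnt$size_standardized <- ss
    cnt$normalized_reads <- normalize_to_million(ss)
    cnt$set_id <- set_config$set_id
    rows[[sid]] <- cnt
  }
  proto <- list(sample_id = character, set_id = integer, locus = character,
                allele = character, raw_reads = numeric,
                target_size_bp = integer, size_standardized = numeric,
                normalized_reads = numeric)
  out <- if (length(rows)) {
    do.call(rbind, c(rows, list(make.row.names = FALSE)))
  } else {
    empty_df(proto)
  }
  out <- out[, c("sample_id", "set_id", "locus", "allele", "raw_reads",
                 "target_size_bp", "size_standardized", "normalized_reads")]
  attr(out, "excluded") <- excluded
  out
}
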