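# Allele reference sequences with exon annotations.
#
# An allele reference is the transcript-side sequence of one HLA allele
# (window exons plus any flanking sequence present in the source reference)
# together with an exon table locating each annotated exon on the sequence.
# Exon coordinates are 0-based half-open throughout; on-sequence intervals
# handed to Biostrings are converted to 1-based at the point of use.

#' Construct a single allele reference
#'
#' @param name Allele name (validated against the HLA nomenclature grammar).
#' @param sequence Nucleotide string over A/C/G/T. Ambiguity codes are
#'   rejected: the perfect-match counting rule is undefined for them.
#' @param exons data.frame with columns `exon_id`, `start`, `end` (0-based
#'   half-open on `sequence`), one row per annotated exon, ordered.
#' @param full_length Logical; `FALSE` marks a partial reference covering
#'   only some region of the gene.
#' @return An object of class `allele_reference`.
#' @examples
#' allele_reference("DRA*01:01", strrep("ACGT", 100),
#'                  data.frame(exon_id = 2L, start = 10L, end = 249L))
#' @export
allele_reference <- function(name, sequence, exons, full_length = TRUE) {
  parsed <- parse_allele_name(name)
  stopifnot(is.character(sequence), length(sequence) == 1, nzchar(sequence))
  if (grepl("[^ACGT]", sequence)) {
    stop("reference sequence for ", name,
         " contains non-ACGT characters; ambiguity codes are not allowed",
         call. = FALSE)
  }
  stopifnot(is.data.frame(exons),
            all(c("exon_id", "start", "end") %in% names(exons)))
  exons <- exons[order(exons$start), c("exon_id", "start", "end")]
  rownames(exons) <- NULL
  exons$exon_id <- as.integer(exons$exon_id)
  exons$start <- as.integer(exons$start)
  exons$end <- as.integer(exons$end)
  n <- nchar(sequence)
  with(exons, {
    if (any(start < 0 | end > n | start >= end))
      stop("exon interval out of bounds for ", name, call. = FALSE)
    if (nrow(exons) > 1 && any(start[-1] < end[-nrow(exons)]))
      stop("overlapping exon intervals for ", name, call. = FALSE)
    if (anyDuplicated(exon_id))
      stop("duplicated exon_id for ", name, call. = FALSE)
  })
  structure(
    list(name = render_allele_name(parsed), locus = parsed$locus,
         sequence = sequence, exons = exons, full_length = full_length),
    class = "allele_reference"
  )
}

#' @export
print.allele_reference <- function(x, ...) {
  cat(sprintf("<allele_reference> %s (%d bp, exons %s%s)\n",
              x$name, nchar(x$sequence),
              paste(x$exons$exon_id, collapse = ","),
              if (x$full_length) "" else ", partial"))
  invisible(x)
}

#' Bundle allele references into a reference panel
#'
#' @param alleles List of [allele_reference()] objects.
#' @return An object of class `hla_panel`: list with an `alleles` list keyed
#'   by rendered allele name.
#' @export
reference_set <- function(alleles) {
  stopifnot(is.list(alleles), length(alleles) >= 1)
  ok <- vapply(alleles, inherits, logical(1), "allele_reference")
  if (!all(ok)) stop("all elements must be allele_reference objects")
  nms <- vapply(alleles, `[[`, character(1), "name")
  if (anyDuplicated(nms)) {
    stop("duplicate allele names in reference set: ",
         paste(unique(nms[duplicated(nms)]), collapse = ", "), call. = FALSE)
  }
  names(alleles) <- nms
  loci <- vapply(alleles, `[[`, character(1), "locus")
  # exon ids must be consistent within a locus (ignoring partial references)
  for (lc in unique(loci)) {
    ids <- lapply(alleles[loci == lc], function(a) sort(a$exons$exon_id))
    full <- vapply(alleles[loci == lc], `[[`, logical(1), "full_length")
    ids <- ids[full]
    if (length(ids) > 1 && !all(vapply(ids, identical, logical(1), ids[[1]]))) {
      stop("inconsistent exon annotation across full-length alleles of locus ",
           lc, call. = FALSE)
    }
  }
  structure(list(alleles = alleles), class = "hla_panel")
}

#' @export
print.hla_panel <- function(x, ...) {
  loci <- panel_loci(x)
  cat(sprintf("<hla_panel> %d alleles over %d loci (%s)\n",
              length(x$alleles), length(loci), paste(loci, collapse = ", ")))
  invisible(x)
}

panel_loci <- function(panel) {
  sort(unique(vapply(panel$alleles, `[[`, character(1), "locus")))
}

panel_alleles <- function(panel, locus = NULL) {
  nms <- names(panel$alleles)
  if (!is.null(locus)) {
    loci <- vapply(panel$alleles, `[[`, character(1), "locus")
    nms <- nms[loci %in% locus]
  }
  sort(nms)
}

#' Extract a mapping-window subsequence
#'
#' Concatenates, in exon order, the subsequences of the annotated window
#' exons of one allele reference. The result's length is the allele's
#' "target size" used for size standardization.
#'
#' @param ref An [allele_reference()].
#' @param window An `exon_window` from [mapping_window()]; defaults to the
#'   window of the allele's locus.
#' @param per_exon If `TRUE`, return a named character vector of per-exon
#'   subsequences instead of the concatenation.
#' @return Character scalar (the window sequence) with attribute
#'   `target_size_bp`, or a named vector when `per_exon = TRUE`.
#' @export
extract_window <- function(ref, window = NULL, per_exon = FALSE) {
  stopifnot(inherits(ref, "allele_reference"))
  window <- window %||% mapping_window(ref$locus)
  hit <- match(window$exon_ids, ref$exons$exon_id)
  if (anyNA(hit)) {
    stop("partial reference: allele ", ref$name, " lacks window exon(s) ",
         paste(window$exon_ids[is.na(hit)], collapse = ","), call. = FALSE)
  }
  ex <- ref$exons[hit, ]
  seqs <- substring(ref$sequence, ex$start + 1L, ex$end)
  names(seqs) <- ex$exon_id
  if (per_exon) return(seqs)
  out <- paste(seqs, collapse = "")
  attr(out, "target_size_bp") <- nchar(out)
  out
}

# 1-based closed intervals of the window exons on the reference sequence
window_intervals <- function(ref, window = NULL) {
  window <- window %||% mapping_window(ref$locus)
  hit <- match(window$exon_ids, ref$exons$exon_id)
  if (anyNA(hit)) return(NULL)
  ex <- ref$exons[hit, ]
  data.frame(exon_id = ex$exon_id, start = ex$start + 1L, end = ex$end)
}

#' Read a reference panel from FASTA plus exon annotation
#'
#' FASTA headers must be rendered allele names; the annotation is a
#' tab-separated table with header row and columns `allele`, `exon_id`,
#' `start`, `end` (0-based half-open coordinates on the allele sequence) and
#' optionally `full_length` (`TRUE`/`FALSE`, default `TRUE`).
#'
#' @param fasta_path Path to the allele FASTA.
#' @param annotation_path Path to the exon annotation TSV.
#' @return An `hla_panel`.
#' @seealso [write_reference_set()]
#' @export
load_reference_set <- function(fasta_path, annotation_path) {
  seqs <- Biostrings::readDNAStringSet(fasta_path)
  ann <- read_tsv(annotation_path)
  need <- c("allele", "exon_id", "start", "end")
  if (!all(need %in% names(ann))) {
    stop("annotation must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  nms <- sub("\\s.*$", "", names(seqs))
  if (anyDuplicated(nms)) {
    stop("duplicate FASTA headers: ",
         paste(unique(nms[duplicated(nms)]), collapse = ", "), call. = FALSE)
  }
  missing_seq <- setdiff(unique(ann$allele), nms)
  missing_ann <- setdiff(nms, unique(ann$allele))
  if (length(missing_seq) || length(missing_ann)) {
    stop("FASTA/annotation mismatch; missing sequences: ",
         paste(missing_seq, collapse = ", "), "; missing annotations: ",
         paste(missing_ann, collapse = ", "), call. = FALSE)
  }
  alleles <- lapply(nms, function(nm) {
    rows <- ann[ann$allele == nm, ]
    fl <- if ("full_length" %in% names(ann)) all(as.logical(rows$full_length)) else TRUE
    allele_reference(nm, as.character(seqs[[match(nm, nms)]]),
                     rows[, c("exon_id", "start", "end")], full_length = fl)
  })
  reference_set(alleles)
}

#' Write a reference panel as FASTA plus exon annotation
#'
#' @param panel An `hla_panel`.
#' @param fasta_path,annotation_path Output paths (TSV dialect of
#'   [load_reference_set()]).
#' @return Invisibly, the two paths.
#' @export
write_reference_set <- function(panel, fasta_path, annotation_path) {
  stopifnot(inherits(panel, "hla_panel"))
  seqs <- Biostrings::DNAStringSet(
    vapply(panel$alleles, `[[`, character(1), "sequence"))
  names(seqs) <- names(panel$alleles)
  Biostrings::writeXStringSet(seqs, fasta_path)
  ann <- do.call(rbind, lapply(panel$alleles, function(a) {
    data.frame(allele = a$name, exon_id = a$exons$exon_id,
               start = a$exons$start, end = a$exons$end,
               full_length = a$full_length, stringsAsFactors = FALSE)
  }))
  rownames(ann) <- NULL
  write_tsv(ann, annotation_path)
  invisible(c(fasta = fasta_path, annotation = annotation_path))
}

#' Validate a capture probe set table
#'
#' Probes are 50-100 base subsequences of panel alleles; the table is used
#' only by the simulator's capture-bias model and is validated here.
#'
#' @param probes data.frame with columns `sequence` and `source_allele`.
#' @return The validated data.frame, invisibly classed `probe_set`.
#' @export
probe_set <- function(probes) {
  stopifnot(is.data.frame(probes),
            all(c("sequence", "source_allele") %in% names(probes)))
  len <- nchar(probes$sequence)
  if (any(len < 50 | len > 100)) {
    stop("probe lengths must be within [50, 100] bases", call. = FALSE)
  }
  parse_allele_name(probes$source_allele)  # validates names
  class(probes) <- c("probe_set", "data.frame")
  invisible(probes)
}
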