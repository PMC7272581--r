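# The 12 classical HLA loci and their polymorphic-exon mapping windows.
#
# Read counting is restricted to the most polymorphic exons of each locus:
# exons 2 and 3 for class I (546 bp in total), exon 2 alone for class II
# (239-270 bp depending on the locus). These windows carry the bulk of the
# allele-distinguishing substitutions and can be phased unambiguously.

.CLASS_I <- c("A", "B", "C")
.DRB_PARALOGS <- c("DRB3", "DRB4", "DRB5")
.LOCI <- c("A", "B", "C", "DPA1", "DPB1", "DQA1", "DQB1",
           "DRA", "DRB1", "DRB3", "DRB4", "DRB5")

# exon ids and per-exon lengths of each locus' mapping window
.WINDOW_SPECS <- list(
  A    = list(exon_ids = c(2L, 3L), exon_lengths = c(270L, 276L)),
  B    = list(exon_ids = c(2L, 3L), exon_lengths = c(270L, 276L)),
  C    = list(exon_ids = c(2L, 3L), exon_lengths = c(270L, 276L)),
  DPA1 = list(exon_ids = 2L, exon_lengths = 246L),
  DPB1 = list(exon_ids = 2L, exon_lengths = 264L),
  DQA1 = list(exon_ids = 2L, exon_lengths = 249L),
  DQB1 = list(exon_ids = 2L, exon_lengths = 270L),
  DRA  = list(exon_ids = 2L, exon_lengths = 239L),
  DRB1 = list(exon_ids = 2L, exon_lengths = 270L),
  DRB3 = list(exon_ids = 2L, exon_lengths = 270L),
  DRB4 = list(exon_ids = 2L, exon_lengths = 270L),
  DRB5 = list(exon_ids = 2L, exon_lengths = 270L)
)

#' The 12 classical HLA loci
#'
#' @return A data.frame with one row per classical locus: `name`, `hla_class`
#'   (`"I"` or `"II"`) and `drb_paralog` (`TRUE` for the secondary DRB genes
#'   DRB3/DRB4/DRB5, which are present on at most one copy per haplotype).
#' @examples
#' hla_loci()
#' @export
hla_loci <- function() {
  data.frame(
    name = .LOCI,
    hla_class = ifelse(.LOCI %in% .CLASS_I, "I", "II"),
    drb_paralog = .LOCI %in% .DRB_PARALOGS,
    stringsAsFactors = FALSE
  )
}

assert_locus <- function(locus) {
  if (length(locus) != 1 || !locus %in% .LOCI) {
    stop("unknown HLA locus: ", paste(locus, collapse = ", "),
         " (expected one of ", paste(.LOCI, collapse = ", "), ")",
         call. = FALSE)
  }
  locus
}

#' Polymorphic-exon mapping window of a locus
#'
#' Returns the fixed mapping window used for read counting: exons 2 and 3
#' (546 bp) for the class I loci, exon 2 for class II (239 bp DRA, 246 bp
#' DPA1, 249 bp DQA1, 264 bp DPB1, 270 bp for DQB1 and the DRB genes).
#'
#' @param locus Locus name, e.g. `"A"` or `"DQB1"`.
#' @return An object of class `exon_window`: list with `locus`, `exon_ids`,
#'   `exon_lengths` and `expected_length_bp`.
#' @examples
#' mapping_window("A")$expected_length_bp    # 546
#' mapping_window("DRA")$expected_length_bp  # 239
#' @export
mapping_window <- function(locus) {
  assert_locus(locus)
  spec <- .WINDOW_SPECS[[locus]]
  structure(
    list(locus = locus,
         exon_ids = spec$exon_ids,
         exon_lengths = spec$exon_lengths,
         expected_length_bp = sum(spec$exon_lengths)),
    class = "exon_window"
  )
}

#' @export
print.exon_window <- function(x, ...) {
  cat(sprintf("<exon_window> HLA-%s: exon%s %s, %d bp\n",
              x$locus, if (length(x$exon_ids) > 1) "s" else "",
              paste(x$exon_ids, collapse = "+"), x$expected_length_bp))
  invisible(x)
}
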