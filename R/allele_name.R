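# HLA allele nomenclature: locus*f1:f2[:f3[:f4]][suffix]
#
# Field 1 is the allele group, field 2 the protein (non-synonymous) variant,
# field 3 a synonymous coding variant, field 4 a non-coding variant. An
# optional trailing expression suffix (N null, L low, S secreted, Q
# questionable, C cytoplasmic, A aberrant) marks expression status.

.SUFFIXES <- c("N", "L", "S", "Q", "C", "A")

.ALLELE_RE <- paste0(
  "^([A-Z][A-Z0-9]*)\\*",            # locus
  "([0-9]+):([0-9]+)",               # fields 1-2 (required)
  "(?::([0-9]+))?(?::([0-9]+))?",    # fields 3-4 (optional)
  "([NLSQCA])?$"                     # expression suffix
)

#' Parse HLA allele names
#'
#' Parses names such as `"A*02:15N"` or `"DQB1*05:02:01"` into their locus,
#' numeric fields 1-4 and expression suffix. Parsing and
#' [render_allele_name()] are exact inverses for every valid name.
#'
#' @param text Character vector of allele names.
#' @return A data.frame with columns `text`, `locus`, `field1`..`field4`
#'   (integer, `NA` when absent) and `suffix` (`NA` when absent).
#' @examples
#' parse_allele_name(c("A*02:15N", "DQB1*05:02:01"))
#' @export
parse_allele_name <- function(text) {
  stopifnot(is.character(text), length(text) >= 1)
  m <- regmatches(text, regexec(.ALLELE_RE, text, perl = TRUE))
  bad <- vapply(m, length, integer(1)) == 0
  if (any(bad)) {
    stop("malformed HLA allele name: '", text[which(bad)[1]], "'",
         call. = FALSE)
  }
  parts <- do.call(rbind, m)
  locus <- parts[, 2]
  unknown <- !locus %in% .LOCI
  if (any(unknown)) {
    stop("unknown locus in allele name: '", text[which(unknown)[1]], "'",
         call. = FALSE)
  }
  to_int <- function(v) ifelse(v == "", NA_integer_, as.integer(v))
  out <- data.frame(
    text = text,
    locus = locus,
    field1 = to_int(parts[, 3]),
    field2 = to_int(parts[, 4]),
    field3 = to_int(parts[, 5]),
    field4 = to_int(parts[, 6]),
    suffix = ifelse(parts[, 7] == "", NA_character_, parts[, 7]),
    stringsAsFactors = FALSE
  )
  if (any(!is.na(out$field4) & is.na(out$field3))) {
    stop("field 4 without field 3 in allele name", call. = FALSE)
  }
  out
}

#' Render HLA allele names
#'
#' Inverse of [parse_allele_name()]: rebuilds the canonical
#' `locus*f1:f2[:f3[:f4]][suffix]` string. Fields are zero-padded to two
#' digits, matching standard nomenclature.
#'
#' @param parsed A data.frame as returned by [parse_allele_name()] (columns
#'   `locus`, `field1`..`field4`, `suffix`).
#' @return Character vector of rendered names.
#' @examples
#' render_allele_name(parse_allele_name("A*02:15N"))
#' @export
render_allele_name <- function(parsed) {
  stopifnot(is.data.frame(parsed),
            all(c("locus", "field1", "field2") %in% names(parsed)))
  fmt <- function(f) sprintf("%02d", f)
  out <- paste0(parsed$locus, "*", fmt(parsed$field1), ":", fmt(parsed$field2))
  has3 <- !is.na(parsed$field3)
  out[has3] <- paste0(out[has3], ":", fmt(parsed$field3[has3]))
  has4 <- !is.na(parsed$field4)
  out[has4] <- paste0(out[has4], ":", fmt(parsed$field4[has4]))
  hass <- !is.na(parsed$suffix)
  out[hass] <- paste0(out[hass], parsed$suffix[hass])
  out
}

#' Resolution level of allele names
#'
#' Truncates allele names to a given field resolution (e.g. field-3 for
#' genotype reporting). Names with fewer fields than requested are returned
#' unchanged; the expression suffix is kept.
#'
#' @param text Character vector of allele names.
#' @param fields Resolution (1-4).
#' @return Character vector of truncated names.
#' @examples
#' allele_resolution("DQB1*05:02:01", fields = 2)
#' @export
allele_resolution <- function(text, fields = 3) {
  stopifnot(fields %in% 1:4)
  p <- parse_allele_name(text)
  if (fields < 4) p$field4 <- NA_integer_
  if (fields < 3) p$field3 <- NA_integer_
  if (fields < 2) stop("field-1-only names are not valid HLA allele names")
  render_allele_name(p)
}

allele_locus <- function(text) parse_allele_name(text)$locus
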