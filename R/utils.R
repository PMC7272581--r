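# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Round half away from zero
#'
#' Fixed-precision rounding where ties go up (`round_half_up(2.25, 1)` is
#' 2.3), the convention used for all reported fold changes, hinge ratios and
#' percentages. Base R's `round()` rounds ties to even, which changes printed
#' table values.
#'
#' @param x Numeric vector.
#' @param digits Number of decimal places to keep.
#' @return `x` rounded to `digits` decimals, ties away from zero.
#' @examples
#' round_half_up(c(1.25, 1.35), 1)
#' @export
round_half_up <- function(x, digits = 1) {
  stopifnot(is.numeric(x), is.numeric(digits), length(digits) == 1)
  scale <- 10^digits
  # small relative guard against representation error (e.g. 2.05 * 10)
  sign(x) * floor(abs(x) * scale + 0.5 + 1e-9) / scale
}

# Evaluate `code` under a temporary RNG state seeded with `seed`; the caller's
# RNG stream is untouched. seed = NULL runs on the current stream.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  has_old <- exists(".Random.seed", envir = .GlobalEnv, inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = .GlobalEnv) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = .GlobalEnv)
    else if (exists(".Random.seed", envir = .GlobalEnv, inherits = FALSE))
      rm(".Random.seed", envir = .GlobalEnv)
  })
  set.seed(seed)
  force(code)
}

# Uniform random DNA string(s).
random_dna <- function(width, n = 1) {
  vapply(seq_len(n), function(i) {
    paste(sample(c("A", "C", "G", "T"), width, replace = TRUE), collapse = "")
  }, character(1))
}

# Substitute `k` positions (distinct, uniform) of a DNA string with a
# different base each; returns list(seq, positions).
mutate_dna <- function(seq, k) {
  if (k <= 0) return(list(seq = seq, positions = integer(0)))
  n <- nchar(seq)
  k <- min(k, n)
  pos <- sort(sample.int(n, k))
  chars <- strsplit(seq, "", fixed = TRUE)[[1]]
  for (p in pos) {
    chars[p] <- sample(setdiff(c("A", "C", "G", "T"), chars[p]), 1)
  }
  list(seq = paste(chars, collapse = ""), positions = pos)
}

# Reverse complement for plain character vectors.
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# Empty data.frame with given column name -> class prototype list.
empty_df <- function(proto) {
  as.data.frame(lapply(proto, function(f) f(0)), stringsAsFactors = FALSE)
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

read_tsv <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
}
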