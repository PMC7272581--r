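# Differential allelic expression (DAE) statistics.
#
# Summaries follow spreadsheet conventions deliberately: quartiles by
# inclusive linear interpolation (stats::quantile type 7), hinge ratios and
# fold changes rounded half-up to one decimal, whiskers at 1.5 interquartile
# ranges. No multiple-testing correction is applied by default; a
# Bonferroni option exists for sensitivity analysis.

#' Five-number summary
#'
#' Minimum, first quartile, median, third quartile and maximum, with
#' quartiles by inclusive linear interpolation on the sorted values.
#'
#' @param values Numeric vector, `n >= 1`.
#' @return Object of class `five_number`: list with `minimum`, `q1`,
#'   `median`, `q3`, `maximum`, `n`.
#' @examples
#' five_number(1:5)
#' @export
five_number <- function(values) {
  stopifnot(is.numeric(values), length(values) >= 1, !anyNA(values))
  q <- stats::quantile(values, probs = c(0, 0.25, 0.5, 0.75, 1),
                       type = 7, names = FALSE)
  structure(list(minimum = q[1], q1 = q[2], median = q[3], q3 = q[4],
                 maximum = q[5], n = length(values)),
            class = "five_number")
}

#' @export
print.five_number <- function(x, ...) {
  cat(sprintf("<five_number> n=%d: %g | %g | %g | %g | %g\n",
              x$n, x$minimum, x$q1, x$median, x$q3, x$maximum))
  invisible(x)
}

#' Ratio of hinges
#'
#' Third quartile divided by first quartile, rounded half-up to one decimal;
#' a per-locus dispersion measure. Undefined (`NA`) when the first quartile
#' is zero.
#'
#' @param f A [five_number()] object.
#' @return Numeric scalar (1 decimal) or `NA`.
#' @examples
#' f <- five_number(c(2083, 5201, 8096, 18605, 43870))
#' ratio_of_hinges(f)
#' @export
ratio_of_hinges <- function(f) {
  stopifnot(inherits(f, "five_number"))
  if (f$q1 <= 0) return(NA_real_)
  round_half_up(f$q3 / f$q1, 1)
}

#' Fold change between the lowest and highest expressed allele
#'
#' Median reads of the highest expressed allele divided by those of the
#' lowest, rounded half-up to one decimal.
#'
#' @param median_low,median_high Group medians, `median_low > 0` and
#'   `median_high >= median_low`.
#' @return Numeric scalar (1 decimal), always `>= 1`.
#' @examples
#' fold_change(17371, 99929)
#' @export
fold_change <- function(median_low, median_high) {
  if (median_low <= 0) stop("median_low must be positive", call. = FALSE)
  if (median_high < median_low)
    stop("median_high must be >= median_low", call. = FALSE)
  round_half_up(median_high / median_low, 1)
}

#' One-way fixed-effects ANOVA
#'
#' Standard one-way ANOVA over two or more groups via [stats::aov()]. With
#' two groups, F equals the square of the pooled-variance t statistic. The
#' degenerate all-values-identical case returns `F = 0, p = 1`; zero
#' within-group variance with differing means returns `F = Inf, p = 0`.
#'
#' @param groups List of >= 2 numeric vectors, each with >= 2 values.
#' @return List with `F`, `p`, `df_between`, `df_within`.
#' @export
anova_one_way <- function(groups) {
  stopifnot(is.list(groups), length(groups) >= 2,
            all(vapply(groups, length, integer(1)) >= 2))
  values <- unlist(groups, use.names = FALSE)
  g <- factor(rep(seq_along(groups), lengths(groups)))
  fit <- stats::aov(values ~ g)
  tab <- summary(fit)[[1]]
  ssb <- tab$`Sum Sq`[1]; ssw <- tab$`Sum Sq`[2]
  dfb <- tab$Df[1]; dfw <- tab$Df[2]
  eps <- 1e-12 * max(1, sum(values^2))
  if (ssw <= eps) {
    if (ssb <= eps) {
      F <- 0; p <- 1
    } else {
      F <- Inf; p <- 0
    }
  } else {
    F <- tab$`F value`[1]
    p <- tab$`Pr(>F)`[1]
  }
  list(F = F, p = p, df_between = dfb, df_within = dfw)
}

#' Coefficient of variation
#'
#' Sample standard deviation (n-1 denominator) divided by the mean.
#'
#' @param values Numeric vector, `n >= 2`, positive mean.
#' @return Numeric scalar.
#' @examples
#' coefficient_of_variation(c(2, 4))
#' @export
coefficient_of_variation <- function(values) {
  stopifnot(is.numeric(values), length(values) >= 2)
  m <- mean(values)
  if (m <= 0) stop("mean must be positive", call. = FALSE)
  stats::sd(values) / m
}

#' Pearson correlation and coefficient of determination
#'
#' @param x,y Numeric vectors of equal length >= 3 with non-zero variance.
#' @return List with `r` and `r2`; both `NA` (with a warning) when either
#'   variable has zero variance.
#' @examples
#' pearson_r2(1:10, 2 * (1:10) + 1)
#' @export
pearson_r2 <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 3)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    warning("zero variance: correlation undefined", call. = FALSE)
    return(list(r = NA_real_, r2 = NA_real_))
  }
  r <- stats::cor(x, y)
  list(r = r, r2 = r^2)
}

#' Expression of an allele relative to its locus average median
#'
#' Used to quantify residual transcript levels of null (suffix N) or
#' low-expression alleles: the allele's median normalized reads as a
#' percentage of the locus' average median, rounded half-up to one decimal.
#'
#' @param allele_median_reads Median normalized reads of the allele.
#' @param locus_average_median_reads Average of the allele medians at the
#'   locus (> 0).
#' @return Percentage, one decimal.
#' @examples
#' null_allele_fraction(41242, 120366)
#' @export
null_allele_fraction <- function(allele_median_reads,
                                 locus_average_median_reads) {
  if (locus_average_median_reads <= 0)
    stop("locus average median must be positive", call. = FALSE)
  round_half_up(100 * allele_median_reads / locus_average_median_reads, 1)
}

#' Box-and-whisker summary
#'
#' Box from the first to third quartile (inclusive-interpolation
#' convention); whiskers extend to the most extreme data points within 1.5
#' interquartile ranges of the box; points beyond are outliers.
#'
#' @param values Numeric vector, `n >= 1`.
#' @return List with `five_number`, `whisker_low`, `whisker_high`,
#'   `outliers`.
#' @examples
#' box_whisker(c(1, 2, 3, 4, 100))
#' @export
box_whisker <- function(values) {
  f <- five_number(values)
  iqr <- f$q3 - f$q1
  lo <- f$q1 - 1.5 * iqr
  hi <- f$q3 + 1.5 * iqr
  inside <- values[values >= lo & values <= hi]
  list(five_number = f,
       whisker_low = min(inside),
       whisker_high = max(inside),
       outliers = sort(values[values < lo | values > hi]))
}

#' Compare expression between groups
#'
#' Drops groups below `min_n` observations, then runs one-way ANOVA across
#' the remaining groups. Grouping can be any labelling of the observations:
#' by allele, by DR haplotype label, or by a user-supplied allele-to-class
#' map (e.g. a DPB1 allele to expression-class map standing in for a 3'UTR
#' SNP genotype).
#'
#' @param values Numeric vector of normalized reads.
#' @param groups Group label per value.
#' @param min_n Minimum observations per group (default 3).
#' @param bonferroni If `TRUE`, also report the p-value multiplied by the
#'   number of comparisons performed so far in the caller's hands; default
#'   off (no multiplicity adjustment).
#' @return List of class `group_comparison` with `groups` (per-group
#'   [five_number()]s), `anova` (`F`, `p`), `dropped` (labels below
#'   `min_n`), or `NULL` (with a message) when fewer than 2 groups qualify.
#' @export
compare_groups <- function(values, groups, min_n = 3, bonferroni = FALSE) {
  stopifnot(length(values) == length(groups))
  groups <- as.character(groups)
  n <- table(groups)
  keep <- names(n)[n >= min_n]
  dropped <- setdiff(names(n), keep)
  if (length(keep) < 2) {
    message("fewer than 2 groups with n >= ", min_n, "; comparison skipped")
    return(NULL)
  }
  sel <- groups %in% keep
  values <- values[sel]; groups <- groups[sel]
  split_vals <- split(values, groups)
  an <- anova_one_way(split_vals)
  if (bonferroni) an$p_bonferroni <- min(1, an$p * length(split_vals))
  structure(list(
    groups = lapply(split_vals, five_number),
    anova = an,
    dropped = dropped
  ), class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("<group_comparison> %d groups, F = %.4g, p = %.3g\n",
              length(x$groups), x$anova$F, x$anova$p))
  for (nm in names(x$groups)) {
    g <- x$groups[[nm]]
    cat(sprintf("  %-24s n=%-4d median %.1f\n", nm, g$n, g$median))
  }
  invisible(x)
}

#' Per-locus summary of normalized RNA levels
#'
#' Five-number summary, hinge ratio and coefficient of variation of the
#' normalized reads at each locus of a comparative dataset.
#'
#' @param dataset Long-format dataset from [build_dataset()].
#' @return Data.frame: `locus`, `n`, `minimum`, `q1`, `median`, `q3`,
#'   `maximum`, `hinge_ratio`, `cv`.
#' @export
locus_summary <- function(dataset) {
  stopifnot(all(c("locus", "normalized_reads") %in% names(dataset)))
  out <- do.call(rbind, lapply(split(dataset$normalized_reads, dataset$locus),
    function(v) {
      f <- five_number(v)
      data.frame(n = f$n, minimum = f$minimum, q1 = f$q1, median = f$median,
                 q3 = f$q3, maximum = f$maximum,
                 hinge_ratio = ratio_of_hinges(f),
                 cv = if (length(v) >= 2 && mean(v) > 0)
                   coefficient_of_variation(v) else NA_real_)
    }))
  out <- cbind(locus = rownames(out), out)
  rownames(out) <- NULL
  out$locus <- as.character(out$locus)
  out[order(out$locus), ]
}

#' Per-locus lowest/highest expressed alleles and fold change
#'
#' For each locus: allele medians over samples (alleles observed in at
#' least `min_n` samples), the locus' average median, the lowest and
#' highest expressed alleles, their fold change, and the ANOVA p-value
#' either between the two extreme allele groups (`p_mode = "extremes"`) or
#' across all allele groups (`p_mode = "all"`).
#'
#' @param dataset Long-format dataset from [build_dataset()].
#' @param min_n Minimum samples per allele (default 3).
#' @param p_mode `"extremes"` (default) or `"all"`.
#' @return Data.frame: `locus`, `n_alleles`, `average_median`,
#'   `lowest_allele`, `lowest_median`, `highest_allele`, `highest_median`,
#'   `fold_change`, `p_value`.
#' @export
allele_summary <- function(dataset, min_n = 3,
                           p_mode = c("extremes", "all")) {
  p_mode <- match.arg(p_mode)
  stopifnot(all(c("locus", "allele", "normalized_reads") %in% names(dataset)))
  rows <- list()
  for (lc in sort(unique(dataset$locus))) {
    d <- dataset[dataset$locus == lc, ]
    by_allele <- split(d$normalized_reads, d$allele)
    by_allele <- by_allele[lengths(by_allele) >= min_n]
    if (length(by_allele) < 2) next
    med <- vapply(by_allele, stats::median, numeric(1))
    lo <- names(med)[which.min(med)]
    hi <- names(med)[which.max(med)]
    p <- if (p_mode == "extremes") {
      if (lo == hi) NA_real_ else anova_one_way(by_allele[c(lo, hi)])$p
    } else {
      anova_one_way(by_allele)$p
    }
    rows[[lc]] <- data.frame(
      locus = lc, n_alleles = length(by_allele),
      average_median = mean(med),
      lowest_allele = lo, lowest_median = med[[lo]],
      highest_allele = hi, highest_median = med[[hi]],
      fold_change = fold_change(med[[lo]], med[[hi]]),
      p_value = p, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
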