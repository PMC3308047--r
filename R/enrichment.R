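#' Minor-allele-frequency bins for functional contrasts
#'
#' Assigns each site to exactly one of three bins by minor allele frequency
#' computed over non-missing genotypes: low (< 1\%), intermediate (1\% to
#' 10\%, both boundaries included), common (> 10\%). The boundary
#' conventions follow the printed labels "<0.01" and ">0.1" and are
#' configurable through \code{breaks}.
#'
#' @param cohort a \linkS4class{CohortDataset}, or \code{NULL} when
#'   \code{maf} is given directly.
#' @param classes per-site class labels; defaults to the cohort's
#'   \code{fclass} column.
#' @param maf optional minor-allele-frequency vector.
#' @param errorRates optional named numeric(3) per-bin variant error rates
#'   (e.g. \code{c(low = 0.062, intermediate = 0.032, common = 0.034)}).
#' @param breaks numeric(2): the low/intermediate and intermediate/common
#'   boundaries (defaults 0.01 and 0.1).
#' @return list(counts = class x bin matrix, bins = per-site bin factor,
#'   errorRates).
#' @export
binByAF <- function(cohort = NULL, classes = NULL, maf = NULL,
                    errorRates = NULL, breaks = c(0.01, 0.1)) {
  if (is.null(maf)) {
    stopIfNot1(!is.null(cohort), "need a cohort or maf vector")
    cnt <- altAlleleCounts(assay(cohort, "genotype"))
    af <- ifelse(cnt$an > 0, cnt$ac / cnt$an, NA)
    maf <- pmin(af, 1 - af)
    if (is.null(classes)) classes <- mcols(rowRanges(cohort))$fclass
  }
  stopIfNot1(length(maf) == length(classes),
             "classes must have one label per site")
  bin <- ifelse(maf < breaks[1], "low",
                ifelse(maf <= breaks[2], "intermediate", "common"))
  bin <- factor(bin, levels = c("low", "intermediate", "common"))
  keep <- !is.na(maf) & !is.na(classes)
  counts <- table(class = classes[keep], bin = bin[keep])
  counts <- unclass(counts)[, c("low", "intermediate", "common"), drop = FALSE]
  list(counts = counts, bins = bin, errorRates = errorRates)
}

#' Deflate per-bin counts by estimated error rates
#'
#' Multiplies each bin's counts by (1 - e_b), the expected true-positive
#' fraction given the bin's variant error rate; corrected counts are
#' fractional and never larger than the raw counts.
#'
#' @param binned result of \code{\link{binByAF}} (or a class x bin count
#'   matrix).
#' @param errorRates named numeric per bin in [0, 1); defaults to the rates
#'   stored in \code{binned}.
#' @return corrected counts in the same shape as the input.
#' @export
correctCounts <- function(binned, errorRates = NULL) {
  counts <- if (is.list(binned)) binned$counts else binned
  if (is.null(errorRates) && is.list(binned)) errorRates <- binned$errorRates
  stopIfNot1(!is.null(errorRates),
             "configuration error: per-bin error rates required")
  stopIfNot1(all(colnames(counts) %in% names(errorRates)),
             "configuration error: error rate missing for a bin")
  stopIfNot1(all(errorRates >= 0 & errorRates < 1),
             "configuration error: error rates must lie in [0, 1)")
  sweep(counts, 2, 1 - errorRates[colnames(counts)], `*`)
}

# chi-square homogeneity statistic on a (possibly fractional) contingency
# table; columns with zero total are dropped
.chisqHomogeneity <- function(tab) {
  tab <- tab[, colSums(tab) > 0, drop = FALSE]
  stopIfNot1(all(rowSums(tab) > 0), "degenerate table: a class has no sites")
  E <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  stat <- sum((tab - E)^2 / E)
  df <- (nrow(tab) - 1L) * (ncol(tab) - 1L)
  list(statistic = stat, df = df, p.value = pchisq(stat, df, lower.tail = FALSE))
}

#' Frequency-distribution contrast between two functional classes
#'
#' Chi-square test of homogeneity on the 2 x 3 class-by-frequency-bin table
#' (raw counts, or error-rate-corrected counts used as a score), plus each
#' class's fraction of sites in the low-frequency bin — the quantity in
#' which amino-acid-changing and damaging-predicted variants are enriched.
#'
#' @param binned result of \code{\link{binByAF}}.
#' @param classA,classB row names to contrast.
#' @param corrected use error-rate-corrected counts.
#' @return list(statistic, df, p.value, lowFraction (named numeric(2)),
#'   table).
#' @export
classContrast <- function(binned, classA, classB, corrected = FALSE) {
  counts <- if (corrected) correctCounts(binned) else binned$counts
  stopIfNot1(all(c(classA, classB) %in% rownames(counts)),
             "both classes must be present in the binned counts")
  tab <- counts[c(classA, classB), , drop = FALSE]
  res <- .chisqHomogeneity(tab)
  lowFrac <- tab[, "low"] / rowSums(tab)
  c(res, list(lowFraction = lowFrac, table = tab))
}
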