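#' Plan validation series by stratified random sampling
#'
#' Draws the requested number of sites per stratum without replacement,
#' deterministically under the seed. When a stratum holds fewer sites than
#' requested, all of it is returned with a shortfall warning.
#'
#' @param strata factor or character vector assigning each site to a stratum
#'   (e.g. "singleton", "AC2-5", by call-set partition or functional class).
#' @param sizes named numeric vector: requested sites per stratum.
#' @param seed RNG seed.
#' @return named list of integer site indices per stratum.
#' @export
planSeries <- function(strata, sizes, seed = 1L) {
  stopIfNot1(!is.null(names(sizes)), "sizes must be named by stratum")
  withSeed(seed, {
    out <- lapply(names(sizes), function(st) {
      avail <- which(strata == st)
      k <- sizes[[st]]
      if (length(avail) < k) {
        warning(sprintf("stratum '%s': only %d of %d requested sites available",
                        st, length(avail), k))
        return(avail)
      }
      sort(sample(avail, k))
    })
    names(out) <- names(sizes)
    out
  })
}

#' Validation rate from conclusive assay outcomes
#'
#' 100 * confirmed / (confirmed + non-variant); inconclusive assays are
#' excluded from the denominator. Display convention is one decimal; full
#' precision is returned.
#'
#' @param confirmed assays confirming the variant.
#' @param nonVariant assays refuting it.
#' @return percentage (vectorized).
#' @examples
#' validationRate(544, 19)  # 96.6
#' @export
validationRate <- function(confirmed, nonVariant) {
  stopIfNot1(all(confirmed + nonVariant >= 1),
             "undefined result: no conclusive assays")
  100 * confirmed / (confirmed + nonVariant)
}

#' Genotype accuracy and error rates from a called-vs-assayed table
#'
#' From the 3 x 3 contingency table of called (rows) versus assayed
#' (columns) genotype classes: per-called-class accuracy (diagonal over row
#' total), overall accuracy (trace over total), the false discovery rate of
#' variant genotypes (miscalled fraction among called het/hom-alt), the
#' missed-variant rate (assayed variant genotypes called reference), and the
#' per-true-class miscall rates (off-diagonal over column total), which
#' recover the error rates of a simulated corruption.
#'
#' @param table an \linkS4class{AssayTable} or a 3x3 matrix (rows called,
#'   columns assayed; order hom-ref, het, hom-alt).
#' @return list(perClass, overall, variantFdr, missedRate, miscallByTruth),
#'   accuracies as percentages, rates as fractions.
#' @examples
#' tab <- diag(c(100, 50, 10))
#' genotypeAccuracy(tab)$overall  # 100
#' @export
genotypeAccuracy <- function(table) {
  m <- if (is(table, "AssayTable")) table@genotypes else table
  stopIfNot1(all(dim(m) == c(3L, 3L)), "need a 3x3 called-vs-assayed table")
  tot <- sum(m)
  stopIfNot1(tot > 0, "undefined result: empty table")
  rows <- rowSums(m); cols <- colSums(m)
  perClass <- ifelse(rows > 0, 100 * diag(m) / rows, NA_real_)
  names(perClass) <- GT_LEVELS
  overall <- 100 * sum(diag(m)) / tot
  calledVar <- rows[2] + rows[3]
  variantFdr <- if (calledVar > 0)
    (rows[2] - m[2, 2] + rows[3] - m[3, 3]) / calledVar else NA_real_
  assayedVar <- cols[2] + cols[3]
  missedRate <- if (assayedVar > 0) (m[1, 2] + m[1, 3]) / assayedVar else NA_real_
  miscallByTruth <- ifelse(cols > 0, 1 - diag(m) / cols, NA_real_)
  names(miscallByTruth) <- GT_LEVELS
  list(perClass = perClass, overall = overall,
       variantFdr = unname(variantFdr), missedRate = unname(missedRate),
       miscallByTruth = miscallByTruth)
}
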