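#' Callability mask under depth and chromosome-count rules
#'
#' A base is callable when at least \code{minChroms} chromosomes (two per
#' diploid sample) are covered at \code{minDepth} or more.
#'
#' @param depths integer matrix, bases (or sites) x samples.
#' @param minDepth per-sample depth floor (default 10).
#' @param minChroms minimum number of qualifying chromosomes (default 100).
#' @return logical vector, one per row of \code{depths}.
#' @examples
#' callableMask(matrix(12L, 1, 60))  # 120 chromosomes at >= 10x: callable
#' @export
callableMask <- function(depths, minDepth = 10L, minChroms = 100L) {
  stopIfNot1(is.matrix(depths), "dimension error: depths must be a matrix")
  2L * rowSums(!is.na(depths) & depths >= minDepth) >= minChroms
}

#' Per-site pairwise heterozygosity
#'
#' The fraction of chromosome pairs differing at the site:
#' \eqn{2 j (n - j) / (n (n - 1))} for allele count \eqn{j} among \eqn{n}
#' chromosomes.
#'
#' @param j allele count(s), 0 <= j <= n.
#' @param n chromosome count(s), n >= 2.
#' @return numeric vector.
#' @examples
#' siteHet(1, 2)   # 1
#' siteHet(5, 10)  # 25/45
#' @export
siteHet <- function(j, n) {
  stopIfNot1(all(n >= 2), "domain error: need n >= 2 chromosomes")
  stopIfNot1(all(j >= 0 & j <= n), "domain error: need 0 <= j <= n")
  2 * j * (n - j) / (n * (n - 1))
}

#' Per-base heterozygosity of a functional site class
#'
#' Sums per-site pairwise heterozygosity over the callable variant sites of
#' one class within one population and divides by the number of callable
#' bases of that class (monomorphic callable bases contribute zero to the
#' numerator and one to the denominator). Chromosome counts per site use
#' non-missing genotypes only.
#'
#' @param cohort a \linkS4class{CohortDataset}.
#' @param siteClass functional class label (matched against the \code{fclass}
#'   site column); \code{NULL} = all sites.
#' @param population population code; \code{NULL} = all samples.
#' @param nBases number of callable bases of the class. Defaults to the
#'   simulation truth (\code{classBases}) when present.
#' @param callable optional logical per-site mask (e.g. from
#'   \code{\link{callableMask}}).
#' @param scale multiplier for reporting (default 1e4, the conventional
#'   "heterozygosity per 10 kb" display); set 1 for the raw per-base value.
#' @return list(het = scaled estimate, raw = per-base value,
#'   nSites, nBases).
#' @export
perBaseHet <- function(cohort, siteClass = NULL, population = NULL,
                       nBases = NULL, callable = NULL, scale = 1e4) {
  mc <- mcols(rowRanges(cohort))
  keep <- rep(TRUE, nrow(cohort))
  if (!is.null(siteClass)) keep <- keep & !is.na(mc$fclass) & mc$fclass == siteClass
  if (!is.null(callable)) keep <- keep & callable
  samples <- if (is.null(population)) colnames(cohort)
             else colnames(cohort)[colData(cohort)$population == population]
  if (is.null(nBases)) {
    cb <- metadata(cohort)$truth$classBases
    stopIfNot1(!is.null(cb) && (is.null(siteClass) || siteClass %in% names(cb)),
               "nBases not given and no truth classBases available")
    nBases <- if (is.null(siteClass)) sum(cb) else cb[[siteClass]]
  }
  stopIfNot1(nBases > 0, "undefined result: zero callable bases")
  g <- assay(cohort, "genotype")[keep, samples, drop = FALSE]
  cnt <- altAlleleCounts(g)
  ok <- cnt$an >= 2 & cnt$ac > 0 & cnt$ac < cnt$an
  hets <- siteHet(cnt$ac[ok], cnt$an[ok])
  raw <- sum(hets) / nBases
  list(het = raw * scale, raw = raw, nSites = sum(ok), nBases = nBases)
}

#' Build an allele frequency spectrum
#'
#' Unfolded (\code{polarize = TRUE}): bins count derived alleles, where the
#' derived allele is whichever of ref/alt differs from the ancestral base;
#' sites with unknown ancestral state, or an ancestral base matching neither
#' allele, are excluded. Folded: bins count minor alleles. Sites whose
#' non-missing chromosome count differs from \code{n} are projected to
#' \code{n} hypergeometrically (fractional counts); sites with fewer
#' chromosomes than \code{n} available are dropped unless projected down.
#'
#' @param cohort a \linkS4class{CohortDataset}.
#' @param population population code; \code{NULL} = all samples.
#' @param polarize build the unfolded (derived-allele) spectrum.
#' @param n target chromosome count; default = 2 x number of samples used.
#'   Per-site counts at other chromosome numbers are hypergeometrically
#'   projected onto \code{n} (only downward; sites with fewer than \code{n}
#'   non-missing chromosomes are excluded).
#' @return An \linkS4class{AFSpectrum}.
#' @export
buildAFS <- function(cohort, population = NULL, polarize = TRUE, n = NULL) {
  mc <- mcols(rowRanges(cohort))
  samples <- if (is.null(population)) colnames(cohort)
             else colnames(cohort)[colData(cohort)$population == population]
  g <- assay(cohort, "genotype")[, samples, drop = FALSE]
  cnt <- altAlleleCounts(g)
  j <- cnt$ac; ns <- cnt$an
  if (polarize) {
    anc <- mc$ancestral
    stopIfNot1(!all(is.na(anc) | anc == "N"),
               "annotation error: polarization requested without ancestral alleles")
    use <- !is.na(anc) & anc != "N" & (anc == mc$ref | anc == mc$alt)
    ancIsAlt <- anc == mc$alt
    j <- ifelse(ancIsAlt, ns - j, j)       # derived = non-ancestral allele
  } else {
    use <- rep(TRUE, length(j))
    j <- pmin(j, ns - j)                   # minor allele
  }
  if (is.null(n)) n <- 2L * length(samples)
  n <- as.integer(n)
  counts <- numeric(n + 1L)
  idx <- which(use & ns >= n & ns >= 2)
  for (i in idx) {
    if (ns[i] == n) {
      counts[j[i] + 1L] <- counts[j[i] + 1L] + 1
    } else {                               # project this site down to n
      kk <- 0:n
      counts <- counts + dhyper(kk, j[i], ns[i] - j[i], n)
    }
  }
  if (!polarize) {                         # re-fold fractional projections
    k <- 0:n
    over <- which(k > n / 2)
    tgt <- n - k[over] + 1L
    counts[tgt] <- counts[tgt] + counts[over]
    counts[over] <- 0
  }
  AFSpectrum(n = n, counts = counts, polarized = polarize)
}

#' Hypergeometric projection of an allele frequency spectrum
#'
#' Projects each allele-count bin of a spectrum at \eqn{n} chromosomes onto a
#' smaller sample of \eqn{m} chromosomes:
#' \deqn{c'_i = \sum_j c_j \, {j \choose i}{n-j \choose m-i} / {n \choose m}.}
#' Projected counts are fractional (expected values, no rounding); the mass
#' landing in the monomorphic bins 0 and \eqn{m} is reported in the
#' \code{lost} slot rather than among the segregating bins.
#'
#' @param afs an \linkS4class{AFSpectrum}.
#' @param m target chromosome count, m <= n.
#' @return An \linkS4class{AFSpectrum} at \code{m} chromosomes.
#' @export
projectAFS <- function(afs, m) {
  m <- as.integer(m)
  n <- afs@n
  stopIfNot1(m <= n, "domain error: m must be <= n")
  stopIfNot1(m >= 1, "domain error: m must be >= 1")
  proj <- numeric(m + 1L)
  for (j in 0:n) {
    cj <- afs@counts[j + 1L]
    if (cj == 0) next
    proj <- proj + cj * dhyper(0:m, j, n - j, m)
  }
  lost <- c(proj[1L], proj[m + 1L]) + afs@lost
  inner <- proj
  inner[c(1L, m + 1L)] <- 0
  out <- AFSpectrum(n = m, counts = inner, polarized = afs@polarized,
                    lost = lost)
  if (!afs@polarized) {
    k <- 0:m
    over <- which(k > m / 2)
    cnts <- out@counts
    tgt <- m - k[over] + 1L
    cnts[tgt] <- cnts[tgt] + cnts[over]
    cnts[over] <- 0
    out@counts <- cnts
  }
  out
}

#' Watterson's theta
#'
#' \eqn{\theta_W = S / a_{n-1}} with \eqn{a_{n-1} = \sum_{i=1}^{n-1} 1/i},
#' for \eqn{S} segregating sites among \eqn{n} chromosomes. Divide by the
#' number of bases surveyed for a per-site value.
#'
#' @param S number of segregating sites.
#' @param n chromosome count (>= 2).
#' @return theta (same units as S).
#' @examples
#' wattersonTheta(10, 5)  # 10 / (1 + 1/2 + 1/3 + 1/4) = 4.8
#' @export
wattersonTheta <- function(S, n) {
  stopIfNot1(n >= 2, "domain error: need n >= 2")
  S / harmonicNumber(n)
}

#' Neutral constant-size expectation of the unfolded spectrum
#'
#' Expected counts \eqn{\theta / i} for derived allele count
#' \eqn{i = 1..n-1}; a line of slope -1 on a log-log plot.
#'
#' @param theta diversity parameter (counts scale).
#' @param n chromosome count.
#' @return An \linkS4class{AFSpectrum} of expected (fractional) counts.
#' @export
neutralExpectation <- function(theta, n) {
  stopIfNot1(theta > 0, "theta must be > 0")
  counts <- c(0, theta / seq_len(n - 1L), 0)
  AFSpectrum(n = n, counts = counts, polarized = TRUE)
}

#' Fraction of sites per allele-frequency bin (plus fraction known)
#'
#' @param cohort a \linkS4class{CohortDataset} (frequencies over non-missing
#'   genotypes), or a numeric vector of frequencies via \code{af}.
#' @param breaks right-closed bin breaks on [0, 1]; defaults to the
#'   rare/intermediate/common convention (boundaries 1\% and 10\%).
#' @param af optional frequency vector overriding the cohort computation.
#' @param known optional logical vector (per site).
#' @return data.frame(bin, n, fraction, fractionKnown).
#' @export
fractionInBins <- function(cohort = NULL, breaks = c(0, 0.01, 0.1, 1),
                           af = NULL, known = NULL) {
  if (is.null(af)) {
    stopIfNot1(!is.null(cohort), "need a cohort or af vector")
    cnt <- altAlleleCounts(assay(cohort, "genotype"))
    ok <- cnt$an > 0
    af <- (cnt$ac / cnt$an)[ok]
    if (is.null(known)) known <- mcols(rowRanges(cohort))$known[ok]
  }
  stopIfNot1(length(af) > 0, "undefined result: no sites")
  bin <- cut(af, breaks, include.lowest = TRUE, right = FALSE,
             labels = FALSE)
  bin[af >= breaks[length(breaks)]] <- length(breaks) - 1L
  labs <- paste0("[", breaks[-length(breaks)], ",", breaks[-1], ")")
  n <- tabulate(bin, nbins = length(breaks) - 1L)
  fk <- if (!is.null(known))
    vapply(seq_along(n), function(b)
      if (n[b]) mean(known[bin == b]) else NA_real_, numeric(1))
  else rep(NA_real_, length(n))
  data.frame(bin = labs, n = n, fraction = n / sum(n), fractionKnown = fk)
}
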