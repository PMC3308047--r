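# ordered-pair category sums for minor-allele counts d (per population) and a
# continent index; returns c(same, cont, diff) numerators over D*(D-1)
.pairNumerators <- function(d, contIdx) {
  D <- sum(d)
  sameN <- sum(d * (d - 1))
  sC <- tapply(d, contIdx, sum)
  contN <- sum(sC^2) - sum(tapply(d^2, contIdx, sum))
  diffN <- D^2 - sum(sC^2)
  c(same = sameN, cont = contN, diff = diffN)
}

#' Probability that two minor alleles share a population / continent
#'
#' For per-population minor-allele counts \eqn{c_p} (total \eqn{C \ge 2}),
#' the probability that two minor alleles drawn at random without
#' replacement come from the same population is
#' \eqn{\sum_p c_p (c_p - 1) / (C (C - 1))}; from different populations of
#' the same continent, \eqn{\sum_{p \ne q, same} c_p c_q / (C (C-1))};
#' from different continents, the remainder. Exact combinatorics, no
#' sampling.
#'
#' @param counts named numeric vector of minor-allele counts per population.
#' @param continents named character vector mapping population -> continent.
#' @return named numeric(3): \code{same}, \code{cont}, \code{diff};
#'   sums to 1.
#' @examples
#' siteSharing(c(A = 2, B = 1), c(A = "AFR", B = "EUR"))  # (1/3, 0, 2/3)
#' @export
siteSharing <- function(counts, continents) {
  C <- sum(counts)
  stopIfNot1(C >= 2,
             "singleton error: a single minor allele cannot be shared")
  contIdx <- factor(continents[names(counts)])
  .pairNumerators(counts, contIdx) / (C * (C - 1))
}

#' Panmictic expectation of the sharing probabilities
#'
#' The sharing probabilities implied by the sample sizes alone when every
#' chromosome is equally likely to carry a minor allele: the same formulas
#' as \code{\link{siteSharing}} with panel chromosome counts in place of
#' allele counts. A combinatorial property of the sample sizes, independent
#' of allele frequency.
#'
#' @param sizes named numeric vector of (down-sampled) chromosome counts per
#'   population.
#' @param continents named character vector mapping population -> continent.
#' @return named numeric(3): \code{same}, \code{cont}, \code{diff}.
#' @export
panmicticExpectation <- function(sizes, continents) {
  stopIfNot1(sum(sizes) >= 2, "need at least two chromosomes")
  siteSharing(sizes, continents)
}

# weighted category averages over down-sampling outcomes: rows of dmat are
# joint minor-allele counts for the active populations, contAct the matching
# population-by-continent indicator matrix
.categoryAverages <- function(dmat, prob, contAct) {
  D <- rowSums(dmat)
  ok <- D >= 2
  a <- c(same = 0, cont = 0, diff = 0)
  w <- sum(prob[ok])
  if (any(ok)) {
    dmat <- dmat[ok, , drop = FALSE]
    prob <- prob[ok]; D <- D[ok]
    denom <- D * (D - 1)
    sameN <- rowSums(dmat * (dmat - 1))
    sC <- dmat %*% contAct
    sumSC2 <- rowSums(sC^2)
    s2 <- rowSums(dmat^2)
    a["same"] <- sum(prob * sameN / denom)
    a["cont"] <- sum(prob * (sumSC2 - s2) / denom)
    a["diff"] <- sum(prob * (D^2 - sumSC2) / denom)
  }
  list(a = a, w = w)
}

# per-site expected category numerators and weight under down-sampling:
# a = E[1(D>=2) * (pair fractions)], w = P(D >= 2); exact enumeration when
# the total minor count is small, Monte Carlo otherwise
.siteDownsampled <- function(cp, np, m, contIdx, spec) {
  act <- which(cp > 0L)
  ci <- as.integer(contIdx)
  contAct <- matrix(0, length(ci), max(ci))
  contAct[cbind(seq_along(ci), ci)] <- 1
  contAct <- contAct[act, , drop = FALSE]
  exact <- spec@method == "exact" && sum(cp) <= spec@exactLimit
  if (exact) {
    grids <- lapply(act, function(p) 0:min(cp[p], m[p]))
    combos <- as.matrix(expand.grid(grids))
    prob <- rep(1, nrow(combos))
    for (j in seq_along(act)) {
      p <- act[j]
      prob <- prob * dhyper(combos[, j], cp[p], np[p] - cp[p], m[p])
    }
  } else {
    R <- spec@replicates
    combos <- matrix(0, R, length(act))
    for (j in seq_along(act)) {
      p <- act[j]
      combos[, j] <- rhyper(R, cp[p], np[p] - cp[p], m[p])
    }
    prob <- rep(1 / R, R)
  }
  .categoryAverages(combos, prob, contAct)
}

#' Percentile bootstrap CI for a site-weighted ratio estimator
#'
#' Resamples sites with replacement and recomputes
#' \eqn{\sum_s a_s / \sum_s w_s} per bootstrap replicate; returns the 2.5
#' and 97.5 percent quantiles. Deterministic under \code{seed}.
#'
#' @param a numeric matrix sites x categories of weighted numerators.
#' @param w numeric vector of site weights (denominator terms).
#' @param B bootstrap replicates (>= 100).
#' @param seed RNG seed.
#' @return matrix categories x c(lo, hi).
#' @export
bootstrapRatioCI <- function(a, w, B = 1000L, seed = 1L) {
  stopIfNot1(B >= 100, "need B >= 100 bootstrap replicates")
  stopIfNot1(nrow(a) >= 2, "undefined CI: fewer than 2 sites")
  S <- nrow(a)
  withSeed(seed, {
    counts <- rmultinom(B, S, rep(1 / S, S))       # S x B resample weights
    num <- t(counts) %*% a                         # B x categories
    den <- as.vector(t(counts) %*% w)
    est <- num / den
    t(apply(est, 2, quantile, probs = c(0.025, 0.975), names = FALSE))
  })
}

#' Down-sampled cross-population minor-allele sharing with bootstrap CIs
#'
#' Implements the sharing analysis: the minor allele is fixed per site from
#' the global frequency; singletons (total minor count < 2) are excluded;
#' each population panel is down-sampled to \code{spec@m} chromosomes by
#' independent hypergeometric reduction; per site the sharing probabilities
#' are averaged over down-sampling outcomes conditional on at least two
#' minor alleles surviving, and sites are combined weighted by that survival
#' probability. Estimates are reported per minor-allele-frequency bin with
#' percentile bootstrap CIs over sites, next to the panmictic expectation
#' implied by the down-sampled panel sizes.
#'
#' @param cohort a \linkS4class{CohortDataset}.
#' @param spec a \linkS4class{DownsampleSpec}; populations missing from
#'   \code{spec@m} default to their full chromosome count.
#' @param bins minor-AF bin breaks (default <0.01, 0.01-0.1, 0.1-0.5).
#' @param B bootstrap replicates.
#' @param excludeSamples optional sample names to drop (e.g. low-coverage
#'   individuals).
#' @param callable optional logical per-site mask of high-coverage sites.
#' @return A \linkS4class{SharingEstimate}.
#' @export
downsampledSharing <- function(cohort, spec, bins = c(0, 0.01, 0.1, 0.5),
                               B = 1000L, excludeSamples = NULL,
                               callable = NULL) {
  if (!is.null(excludeSamples))
    cohort <- cohort[, !colnames(cohort) %in% excludeSamples]
  if (!is.null(callable)) cohort <- cohort[callable, ]
  cd <- colData(cohort)
  pops <- unique(cd$population)
  continents <- setNames(cd$continent[match(pops, cd$population)], pops)
  contIdx <- factor(continents[pops])
  sampleSets <- lapply(pops, function(p) which(cd$population == p))
  names(sampleSets) <- pops
  fullChrom <- vapply(sampleSets, function(ix) 2L * length(ix), integer(1))
  m <- fullChrom
  if (length(spec@m)) {
    stopIfNot1(all(names(spec@m) %in% pops),
               "spec error: unknown population in down-sampling spec")
    m[names(spec@m)] <- spec@m
  }
  stopIfNot1(all(m <= fullChrom),
             "spec error: target chromosomes exceed available chromosomes")

  g <- assay(cohort, "genotype")
  acP <- sapply(sampleSets, function(ix) rowSums(g[, ix, drop = FALSE], na.rm = TRUE))
  anP <- sapply(sampleSets, function(ix)
    2L * rowSums(!is.na(g[, ix, drop = FALSE])))
  if (nrow(cohort) == 1L) { acP <- matrix(acP, 1); anP <- matrix(anP, 1) }
  acT <- rowSums(acP); anT <- rowSums(anP)
  minorIsAlt <- acT <= anT / 2
  cP <- ifelse(matrix(minorIsAlt, nrow(acP), ncol(acP)), acP, anP - acP)
  C <- rowSums(cP)
  maf <- ifelse(anT > 0, C / anT, NA)

  usable <- C >= 2 & apply(anP >= matrix(m, nrow(anP), ncol(anP), byrow = TRUE),
                           1, all)
  idx <- which(usable)
  stopIfNot1(length(idx) >= 2, "fewer than 2 usable (non-singleton) sites")

  aMat <- matrix(0, length(idx), 3,
                 dimnames = list(NULL, c("same", "cont", "diff")))
  wVec <- numeric(length(idx))
  withSeed(spec@seed, {
    cache <- new.env(parent = emptyenv())  # many sites share a count pattern
    for (r in seq_along(idx)) {
      s <- idx[r]
      key <- paste(c(cP[s, ], anP[s, ]), collapse = ",")
      res <- cache[[key]]
      if (is.null(res)) {
        res <- .siteDownsampled(cP[s, ], anP[s, ], m, contIdx, spec)
        cache[[key]] <- res
      }
      aMat[r, ] <- res$a
      wVec[r] <- res$w
    }
  })

  binIdx <- cut(maf[idx], bins, include.lowest = TRUE, right = FALSE,
                labels = FALSE)
  binIdx[maf[idx] >= bins[length(bins)]] <- length(bins) - 1L
  labs <- paste0("[", bins[-length(bins)], ",", bins[-1], ")")
  rows <- list()
  for (b in seq_len(length(bins) - 1L)) {
    sel <- which(binIdx == b)
    if (length(sel) == 0) next
    est <- colSums(aMat[sel, , drop = FALSE]) / sum(wVec[sel])
    ci <- if (length(sel) >= 2)
      bootstrapRatioCI(aMat[sel, , drop = FALSE], wVec[sel], B = B,
                       seed = spec@seed + b)
    else matrix(NA_real_, 3, 2)
    rows[[b]] <- data.frame(bin = labs[b],
                            category = c("same", "cont", "diff"),
                            estimate = as.numeric(est),
                            lo = ci[, 1], hi = ci[, 2],
                            nSites = length(sel))
  }
  tab <- do.call(rbind, rows)
  rownames(tab) <- NULL
  new("SharingEstimate", table = tab,
      expectation = panmicticExpectation(m, continents))
}
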