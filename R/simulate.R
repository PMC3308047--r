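#' @importFrom stats rbeta rbinom rgamma rlnorm rnorm runif setNames dhyper
#'   rhyper pchisq quantile rmultinom
NULL

## Seed offsets deriving per-operation substreams from the root seed, so each
## generator stage can be re-run independently yet reproducibly.
.SEED_SITES <- 11L
.SEED_DEPTH <- 13L
.SEED_CORRUPT <- 19L

# Ancestral (derived-allele) frequencies from the neutral 1/x density,
# truncated to (eps, 1); inverse-CDF sampling.
rAncestralFreq <- function(n, eps) {
  eps^(1 - runif(n))
}

# Balding-Nichols draw: Beta with mean p and variance F*p*(1-p).
rBaldingNichols <- function(p, F) {
  if (F <= 0) return(p)
  out <- p
  inner <- p > 0 & p < 1
  a <- p[inner] * (1 - F) / F
  b <- (1 - p[inner]) * (1 - F) / F
  out[inner] <- rbeta(sum(inner), a, b)
  out
}

# Shared core of the coverage model: per-target log-normal effect (mean 1,
# shared across samples) times per-sample gamma effect (mean 1) times the
# configured mean depth, rounded to integer reads.
depthMatrixCore <- function(nTargets, sampleNames, coverage) {
  nS <- length(sampleNames)
  t_j <- if (coverage$targetSdLog > 0)
    rlnorm(nTargets, meanlog = -coverage$targetSdLog^2 / 2,
           sdlog = coverage$targetSdLog)
  else rep(1, nTargets)
  s_i <- if (is.finite(coverage$sampleShape))
    rgamma(nS, shape = coverage$sampleShape, rate = coverage$sampleShape)
  else rep(1, nS)
  d <- round(coverage$meanDepth * outer(t_j, s_i))
  storage.mode(d) <- "integer"
  dimnames(d) <- list(NULL, sampleNames)
  d
}

#' Simulate per-target read depths
#'
#' Emulates the strongly heterogeneous coverage of hybrid-capture targets:
#' each target has a log-normal affinity effect shared by all samples, and
#' each sample a gamma-distributed scaling; the marginal mean equals the
#' configured mean depth.
#'
#' @param config a \linkS4class{SimulationConfig}.
#' @param nTargets number of capture targets (>= 1).
#' @return integer matrix, targets x samples.
#' @examples
#' d <- simulateDepths(SimulationConfig(seed = 7L), nTargets = 50)
#' mean(d)
#' @export
simulateDepths <- function(config, nTargets) {
  validObject(config)
  stopIfNot1(nTargets >= 1, "nTargets must be >= 1")
  samples <- samplesFromPanel(config@populations)
  withSeed(config@seed + .SEED_DEPTH,
           depthMatrixCore(as.integer(nTargets), samples$sample, config@coverage))
}

samplesFromPanel <- function(populations) {
  sample <- unlist(mapply(function(nm, n) sprintf("%s%04d", nm, seq_len(n)),
                          populations$name, populations$n, SIMPLIFY = FALSE),
                   use.names = FALSE)
  data.frame(sample = sample,
             population = rep(populations$name, populations$n),
             continent = rep(populations$continent, populations$n),
             stringsAsFactors = FALSE)
}

# Draw one class worth of sites: ancestral frequencies from the truncated 1/x
# density, optional selection skew, two-level Balding-Nichols divergence, and
# binomial genotypes; keeps exactly `need` sites polymorphic in the realized
# sample and reports the total number of draws consumed (for the implied
# sequence length).
drawClassSites <- function(need, config, selected, panel) {
  eps <- 1 / (2 * config@ne)
  pops <- config@populations
  nPop <- nrow(pops)
  contOf <- match(pops$continent, unique(pops$continent))
  nChromTot <- 2L * sum(pops$n)
  Fhalf <- config@fst / 2

  got <- 0L; draws <- 0L
  genoList <- list(); ancList <- list(); popFreqList <- list()
  while (got < need) {
    M <- max(1000L, as.integer(ceiling((need - got) * 2.5)))
    x <- rAncestralFreq(M, eps)
    if (selected) x <- pmax(x * config@selectionSkew, eps)
    contFreq <- matrix(0, M, max(contOf))
    for (cc in seq_len(max(contOf)))
      contFreq[, cc] <- rBaldingNichols(x, Fhalf)
    popFreq <- matrix(0, M, nPop, dimnames = list(NULL, pops$name))
    geno <- matrix(0L, M, sum(pops$n))
    col0 <- 0L
    for (p in seq_len(nPop)) {
      popFreq[, p] <- rBaldingNichols(contFreq[, contOf[p]], Fhalf)
      np <- pops$n[p]
      geno[, col0 + seq_len(np)] <-
        matrix(rbinom(M * np, 2L, rep(popFreq[, p], times = np)), nrow = M)
      col0 <- col0 + np
    }
    ac <- rowSums(geno)
    poly <- which(ac > 0L & ac < nChromTot)
    take <- poly[seq_len(min(length(poly), need - got))]
    if (length(take)) {
      genoList[[length(genoList) + 1L]] <- geno[take, , drop = FALSE]
      ancList[[length(ancList) + 1L]] <- x[take]
      popFreqList[[length(popFreqList) + 1L]] <- popFreq[take, , drop = FALSE]
    }
    # draws consumed: the whole batch, or up to the draw yielding the last
    # site we needed
    draws <- draws + if (length(poly) >= need - got) take[length(take)] else M
    got <- got + length(take)
  }
  list(genotype = do.call(rbind, genoList),
       ancestralFreq = unlist(ancList),
       popFreq = do.call(rbind, popFreqList),
       draws = draws)
}

# Random ref/alt SNP alleles with a transition-rich substitution profile
# (coding call sets have Ts/Tv near 3).
drawAlleles <- function(n, tsProb = 0.76) {
  bases <- c("A", "C", "G", "T")
  transition <- c(A = "G", G = "A", C = "T", T = "C")
  ref <- bases[sample.int(4L, n, replace = TRUE)]
  isTs <- runif(n) < tsProb
  alt <- character(n)
  alt[isTs] <- transition[ref[isTs]]
  if (any(!isTs)) {
    tv <- lapply(ref[!isTs], function(b) setdiff(bases, c(b, transition[[b]])))
    alt[!isTs] <- vapply(tv, function(v) v[sample.int(2L, 1L)], character(1))
  }
  list(ref = ref, alt = alt)
}

#' Simulate a multi-population exome cohort with known ground truth
#'
#' Sites are drawn per functional class from a neutral 1/x ancestral
#' frequency density truncated below at 1/(2 Ne); classes listed in
#' \code{selectedClasses} have their frequencies multiplied by
#' \code{selectionSkew} (then re-truncated), enriching rare alleles the way
#' purifying selection does. Per-population frequencies follow a two-level
#' (continent, then population) Balding-Nichols model, each level carrying
#' half of \code{fst} on the variance scale; genotypes are binomial
#' (Hardy-Weinberg) per sample. Only sites polymorphic in the realized sample
#' are kept, and the number of rejected draws fixes the implied sequence
#' length per class (stored in the truth metadata as \code{classBases}), so
#' diversity estimators can be checked against the configured \eqn{\theta}.
#' Read depths come from the shared coverage model; genotypes at zero-depth
#' sample-sites are missing. Site quality, QD, genotype qualities and allele
#' depths are filled in at levels consistent with the depths so the filtering
#' stages run end to end.
#'
#' Deterministic under the config seed.
#'
#' @param config a \linkS4class{SimulationConfig}.
#' @return A \linkS4class{CohortDataset}; \code{metadata(x)$truth} holds
#'   \code{ancestralFreq}, \code{popFreq}, \code{classBases}, \code{targets}
#'   (a GRanges of simulated capture targets) and the config.
#' @examples
#' cfg <- SimulationConfig(
#'   populations = data.frame(name = "POP1", continent = "AFR", n = 20L),
#'   nSites = c(silent = 100L), theta = c(silent = 1e-3),
#'   fst = 0, selectionSkew = 1, selectedClasses = character(), seed = 42L)
#' cohort <- simulateCohort(cfg)
#' cohort
#' @export
simulateCohort <- function(config) {
  validObject(config)
  panel <- samplesFromPanel(config@populations)
  nS <- nrow(panel)
  classes <- names(config@nSites)
  eps <- 1 / (2 * config@ne)

  sim <- withSeed(config@seed + .SEED_SITES, {
    per <- lapply(classes, function(k)
      drawClassSites(config@nSites[[k]], config,
                     k %in% config@selectedClasses, panel))
    names(per) <- classes
    geno <- do.call(rbind, lapply(per, `[[`, "genotype"))
    fclass <- rep(classes, vapply(per, function(z) nrow(z$genotype), 1L))
    ancFreq <- unlist(lapply(per, `[[`, "ancestralFreq"), use.names = FALSE)
    popFreq <- do.call(rbind, lapply(per, `[[`, "popFreq"))
    draws <- vapply(per, `[[`, numeric(1), "draws")
    classBases <- draws / (config@theta[classes] * log(1 / eps))
    names(classBases) <- classes

    nTot <- nrow(geno)
    ord <- sample.int(nTot)            # interleave classes along the chromosome
    geno <- geno[ord, , drop = FALSE]
    fclass <- fclass[ord]; ancFreq <- ancFreq[ord]
    popFreq <- popFreq[ord, , drop = FALSE]

    # lay sites onto capture targets: 120-bp targets, up to 8 sites each
    sitesPerTarget <- 8L
    nTargets <- as.integer(ceiling(nTot / sitesPerTarget))
    targetIdx <- rep(seq_len(nTargets), each = sitesPerTarget)[seq_len(nTot)]
    targetStart <- (seq_len(nTargets) - 1L) * 400L + 1L
    offs <- unlist(lapply(table(targetIdx), function(k)
      sort(sample.int(120L, k))), use.names = FALSE)
    pos <- targetStart[targetIdx] + offs - 1L

    al <- drawAlleles(nTot)
    ac <- rowSums(geno)
    af <- ac / (2 * nS)
    known <- runif(nTot) < pmin(0.95, 0.05 + 0.9 * pmin(1, 10 * af))
    qd <- rgamma(nTot, shape = 8, rate = 8 / 15)
    list(geno = geno, fclass = fclass, ancFreq = ancFreq, popFreq = popFreq,
         classBases = classBases, pos = pos, targetIdx = targetIdx,
         nTargets = nTargets, targetStart = targetStart,
         ref = al$ref, alt = al$alt, known = known, qd = qd)
  })

  depthTargets <- withSeed(config@seed + .SEED_DEPTH,
                           depthMatrixCore(sim$nTargets, panel$sample,
                                           config@coverage))
  depth <- depthTargets[sim$targetIdx, , drop = FALSE]

  geno <- sim$geno
  geno[depth == 0L] <- NA_integer_
  gq <- pmin(depth * 3L, 99L)

  ad <- withSeed(config@seed + .SEED_SITES + 1L, {
    n <- length(depth)
    dv <- as.vector(depth); gv <- as.vector(geno)
    adAlt <- integer(n)
    het <- !is.na(gv) & gv == 1L
    adAlt[het] <- rbinom(sum(het), dv[het], 0.5)
    ha <- !is.na(gv) & gv == 2L
    adAlt[ha] <- dv[ha] - rbinom(sum(ha), dv[ha], 0.005)
    hr <- !is.na(gv) & gv == 0L
    adAlt[hr] <- rbinom(sum(hr), dv[hr], 0.005)
    adAlt[is.na(gv)] <- 0L
    list(alt = matrix(adAlt, nrow(depth)), ref = depth - matrix(adAlt, nrow(depth)))
  })

  carrierDepth <- rowSums(depth * (!is.na(geno) & geno > 0L))
  quality <- round(sim$qd * pmax(carrierDepth, 1), 2)

  sites <- GRanges("1", IRanges::IRanges(sim$pos, width = 1L),
                   ref = sim$ref, alt = sim$alt, vtype = "SNP",
                   quality = quality, qd = round(sim$qd, 2),
                   ancestral = sim$ref, known = sim$known, fclass = sim$fclass)
  targets <- GRanges("1", IRanges::IRanges(sim$targetStart, width = 120L))
  rownames(sim$popFreq) <- NULL
  truth <- list(ancestralFreq = sim$ancFreq, popFreq = sim$popFreq,
                classBases = sim$classBases, targets = targets,
                config = config)
  rownames(panel) <- panel$sample
  cohort <- CohortDataset(sites = sites, genotype = geno, depth = depth,
                          panel = panel[, c("population", "continent")],
                          gq = gq, adRef = ad$ref, adAlt = ad$alt,
                          truth = truth)
  names(rowRanges(cohort)) <- sprintf("site%05d", seq_along(sites))
  cohort
}

#' Corrupt genotype calls at configured per-class miscall rates
#'
#' Applies the row-stochastic miscall matrix to every non-missing genotype
#' and returns both the corrupted dataset and the called-vs-true contingency
#' table, emulating a validation assay in which the original (true) genotypes
#' play the role of the assay results.
#'
#' @param cohort a \linkS4class{CohortDataset}.
#' @param rates 3x3 row-stochastic matrix, rows = true class (hom-ref, het,
#'   hom-alt), columns = called class.
#' @param seed RNG seed (default derives from the simulation config when the
#'   cohort carries one).
#' @return list(cohort = corrupted \linkS4class{CohortDataset},
#'   assay = \linkS4class{AssayTable} with the 3x3 called-vs-assayed counts).
#' @export
corruptGenotypes <- function(cohort, rates = defaultErrorRates(), seed = NULL) {
  stopIfNot1(all(dim(rates) == c(3L, 3L)) && all(rates >= 0) && all(rates <= 1),
             "rates must be a 3x3 matrix with entries in [0, 1]")
  stopIfNot1(all(abs(rowSums(rates) - 1) < 1e-8),
             "rates rows must sum to 1")
  if (is.null(seed)) {
    cfg <- metadata(cohort)$truth$config
    seed <- if (!is.null(cfg)) cfg@seed + .SEED_CORRUPT else 1L
  }
  g <- assay(cohort, "genotype")
  called <- withSeed(seed, {
    gv <- as.vector(g)
    out <- gv
    u <- runif(length(gv))
    for (tc in 0:2) {
      idx <- which(!is.na(gv) & gv == tc)
      cum <- cumsum(rates[tc + 1L, ])
      out[idx] <- findInterval(u[idx], cum, left.open = TRUE)  # 0,1,2
    }
    matrix(as.integer(out), nrow(g), dimnames = dimnames(g))
  })
  tab <- matrix(0, 3, 3, dimnames = list(called = GT_LEVELS, assayed = GT_LEVELS))
  ok <- !is.na(g)
  t2 <- table(factor(called[ok], levels = 0:2), factor(g[ok], levels = 0:2))
  tab[] <- as.numeric(t2)
  corrupted <- cohort
  assays(corrupted)$genotype <- called
  list(cohort = corrupted, assay = AssayTable(genotypes = tab))
}

#' @importFrom SummarizedExperiment assays assays<-
NULL
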