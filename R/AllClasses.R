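#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<- mcols mcols<-
#' @importFrom GenomicRanges GRanges
#' @importFrom SummarizedExperiment SummarizedExperiment assay assays assays<-
#'   rowRanges rowRanges<- colData
NULL

## Genotype coding used throughout: 0 = hom-ref, 1 = het, 2 = hom-alt, NA = missing.
GT_LEVELS <- c("homref", "het", "homalt")

#' Simulation configuration for the synthetic exome cohort generator
#'
#' Holds every knob of the multi-population cohort simulator: the population
#' panel layout, the per-functional-class number of polymorphic sites and
#' scaled diversity \eqn{\theta} (per site), the divergence parameter
#' \code{fst} of the two-level Balding-Nichols model, the rare-allele
#' enrichment multiplier for selected classes, the coverage model, the
#' genotype miscall matrix used by \code{\link{corruptGenotypes}}, and the
#' root RNG seed.
#'
#' @slot populations data.frame with columns \code{name}, \code{continent},
#'   \code{n} (diploid sample count per population panel).
#' @slot nSites named integer; polymorphic sites to generate per functional
#'   class (names are class labels such as \code{"silent"}).
#' @slot theta named numeric; per-site Watterson diversity parameter per class.
#' @slot fst numeric in [0,1); total divergence, split evenly (on the variance
#'   scale) between the continent and population levels.
#' @slot selectionSkew numeric in (0,1]; multiplier applied to ancestral
#'   frequencies of the classes in \code{selectedClasses}.
#' @slot selectedClasses character; classes subject to the skew.
#' @slot ne numeric; effective population size setting the low-frequency
#'   truncation point 1/(2*ne) of the 1/x ancestral frequency density.
#' @slot coverage list with \code{meanDepth}, \code{targetSdLog} (log-normal
#'   sd of the shared per-target effect) and \code{sampleShape} (gamma shape
#'   of the per-sample scaling; larger = less sample-to-sample variation).
#' @slot errorRates 3x3 row-stochastic matrix; row = true genotype class
#'   (hom-ref, het, hom-alt), entry = probability a call of that class is
#'   emitted.
#' @slot seed integer root seed; fixed offsets derive per-operation substreams.
#' @aliases SimulationConfig-class
#' @exportClass SimulationConfig
setClass("SimulationConfig", representation(
  populations = "data.frame",
  nSites = "integer",
  theta = "numeric",
  fst = "numeric",
  selectionSkew = "numeric",
  selectedClasses = "character",
  ne = "numeric",
  coverage = "list",
  errorRates = "matrix",
  seed = "integer"
))

setValidity("SimulationConfig", function(object) {
  msg <- character()
  p <- object@populations
  if (!all(c("name", "continent", "n") %in% names(p)))
    msg <- c(msg, "populations must have columns name, continent, n")
  else if (any(p$n < 1)) msg <- c(msg, "populations: all sample counts must be >= 1")
  if (anyDuplicated(p$name)) msg <- c(msg, "populations: duplicate population names")
  if (is.null(names(object@nSites)) || any(!nzchar(names(object@nSites))))
    msg <- c(msg, "nSites must be named by functional class")
  if (any(object@nSites < 1)) msg <- c(msg, "nSites: all counts must be >= 1")
  if (!identical(sort(names(object@nSites)), sort(names(object@theta))))
    msg <- c(msg, "theta must be named like nSites")
  if (any(object@theta <= 0)) msg <- c(msg, "theta: must be > 0")
  if (length(object@fst) != 1L || object@fst < 0 || object@fst >= 1)
    msg <- c(msg, "fst must lie in [0, 1)")
  if (object@selectionSkew <= 0 || object@selectionSkew > 1)
    msg <- c(msg, "selectionSkew must lie in (0, 1]")
  if (!all(object@selectedClasses %in% names(object@nSites)))
    msg <- c(msg, "selectedClasses must be a subset of the nSites classes")
  cov <- object@coverage
  if (is.null(cov$meanDepth) || cov$meanDepth <= 0)
    msg <- c(msg, "coverage$meanDepth must be > 0")
  if (is.null(cov$targetSdLog) || cov$targetSdLog < 0)
    msg <- c(msg, "coverage$targetSdLog must be >= 0")
  if (is.null(cov$sampleShape) || cov$sampleShape <= 0)
    msg <- c(msg, "coverage$sampleShape must be > 0")
  er <- object@errorRates
  if (!all(dim(er) == c(3L, 3L)) || any(er < 0) || any(er > 1) ||
      any(abs(rowSums(er) - 1) > 1e-8))
    msg <- c(msg, "errorRates must be a 3x3 row-stochastic matrix")
  if (object@ne < 2) msg <- c(msg, "ne must be >= 2")
  if (length(msg)) msg else TRUE
})

#' Construct a SimulationConfig
#'
#' Defaults emulate the study conditions of a seven-population, three-continent
#' deep exome-capture cohort: panel sizes of the order of a few hundred samples
#' spread over Africa, Asia and Europe; a neutral 1/x ancestral frequency
#' spectrum; moderate continental divergence; an excess-rare skew on the
#' amino-acid-changing classes; and strongly heterogeneous per-target coverage
#' around a mean depth in the tens.
#'
#' @param populations data.frame(name, continent, n).
#' @param nSites named integer vector of polymorphic site counts per class.
#' @param theta named numeric vector of per-site diversity per class.
#' @param fst divergence parameter in [0,1).
#' @param selectionSkew frequency multiplier in (0,1] for selected classes.
#' @param selectedClasses classes the skew applies to.
#' @param ne effective population size for the frequency floor 1/(2*ne).
#' @param coverage list(meanDepth, targetSdLog, sampleShape).
#' @param errorRates 3x3 row-stochastic genotype miscall matrix
#'   (rows/cols: hom-ref, het, hom-alt).
#' @param seed integer root seed.
#' @return A \linkS4class{SimulationConfig}.
#' @examples
#' cfg <- SimulationConfig(seed = 1L)
#' cfg
#' @export
SimulationConfig <- function(populations = data.frame(
                               name = c("YRI", "LWK", "CHB", "CHD", "JPT", "CEU", "TSI"),
                               continent = c("AFR", "AFR", "ASN", "ASN", "ASN", "EUR", "EUR"),
                               n = c(112L, 108L, 109L, 107L, 105L, 90L, 66L)),
                             nSites = c(silent = 2000L, missense = 2800L, nonsense = 200L),
                             theta = c(silent = 1e-3, missense = 4e-4, nonsense = 5e-5),
                             fst = 0.08,
                             selectionSkew = 0.5,
                             selectedClasses = intersect(c("missense", "nonsense"),
                                                         names(nSites)),
                             ne = 10000,
                             coverage = list(meanDepth = 48, targetSdLog = 0.7,
                                             sampleShape = 10),
                             errorRates = defaultErrorRates(),
                             seed = 1L) {
  populations$name <- as.character(populations$name)
  populations$continent <- as.character(populations$continent)
  populations$n <- as.integer(populations$n)
  ns <- as.integer(nSites); names(ns) <- names(nSites)
  new("SimulationConfig", populations = populations, nSites = ns,
      theta = theta, fst = fst, selectionSkew = selectionSkew,
      selectedClasses = selectedClasses, ne = ne, coverage = coverage,
      errorRates = errorRates, seed = as.integer(seed))
}

#' Default genotype miscall matrix
#'
#' Per-true-class call probabilities mirroring the accuracy levels a deep
#' exome cohort attains: hom-ref calls nearly always right, heterozygotes
#' miscalled a few percent of the time (mostly dropped to hom-ref), hom-alt
#' the least accurate class.
#' @return 3x3 row-stochastic matrix, rows/cols hom-ref, het, hom-alt.
#' @export
defaultErrorRates <- function() {
  m <- rbind(c(0.999, 0.001, 0.000),
             c(0.025, 0.970, 0.005),
             c(0.002, 0.075, 0.923))
  dimnames(m) <- list(true = GT_LEVELS, called = GT_LEVELS)
  m
}

setMethod("show", "SimulationConfig", function(object) {
  p <- object@populations
  cat("SimulationConfig:", nrow(p), "populations /",
      length(unique(p$continent)), "continents,",
      sum(p$n), "samples\n")
  cat("  sites per class:",
      paste(names(object@nSites), object@nSites, sep = "=", collapse = ", "), "\n")
  cat("  theta:", paste(names(object@theta), signif(object@theta, 3),
                        sep = "=", collapse = ", "), "\n")
  cat(sprintf("  fst=%.3g, selectionSkew=%.3g (%s), Ne=%g, seed=%d\n",
              object@fst, object@selectionSkew,
              paste(object@selectedClasses, collapse = "+"),
              object@ne, object@seed))
})

#' Multi-population cohort of variant sites with genotypes and depths
#'
#' A \linkS4class{SummarizedExperiment}-style container: rows are variant
#' sites (a \code{GRanges} with allele/annotation metadata columns), columns
#' are samples (with \code{population} and \code{continent} in the colData).
#' Assays: \code{genotype} (0 = hom-ref, 1 = het, 2 = hom-alt, NA = missing),
#' \code{depth} (read depth), \code{gq} (genotype quality), \code{adRef} and
#' \code{adAlt} (per-allele read depths). Simulated cohorts additionally carry
#' a \code{truth} list in \code{metadata()} (ancestral and per-population true
#' frequencies, per-class callable-base counts, the config).
#'
#' Site metadata columns: \code{ref}, \code{alt}, \code{vtype} (\code{"SNP"},
#' \code{"insertion"}, \code{"deletion"}), \code{quality}, \code{qd},
#' \code{ancestral} (\code{"N"} = unknown), \code{known}, \code{fclass}.
#'
#' @aliases CohortDataset-class
#' @exportClass CohortDataset
setClass("CohortDataset", contains = "RangedSummarizedExperiment")

setValidity("CohortDataset", function(object) {
  msg <- character()
  need <- c("genotype", "depth")
  if (!all(need %in% names(assays(object))))
    msg <- c(msg, "assays must include 'genotype' and 'depth'")
  if (!all(c("population", "continent") %in% names(colData(object))))
    msg <- c(msg, "colData must include 'population' and 'continent'")
  mc <- mcols(rowRanges(object))
  if (!all(c("ref", "alt", "vtype") %in% names(mc)))
    msg <- c(msg, "site metadata must include ref, alt, vtype")
  if ("genotype" %in% names(assays(object))) {
    g <- assay(object, "genotype")
    if (!all(g[!is.na(g)] %in% 0:2))
      msg <- c(msg, "genotype assay values must be 0, 1, 2 or NA")
  }
  if ("depth" %in% names(assays(object))) {
    d <- assay(object, "depth")
    if (any(d[!is.na(d)] < 0)) msg <- c(msg, "depths must be >= 0")
  }
  if (length(msg)) msg else TRUE
})

#' Construct a CohortDataset
#'
#' @param sites GRanges of variant sites with metadata columns \code{ref},
#'   \code{alt}, \code{vtype} (and optionally \code{quality}, \code{qd},
#'   \code{ancestral}, \code{known}, \code{fclass}).
#' @param genotype integer matrix sites x samples (0/1/2/NA).
#' @param depth integer matrix of read depths.
#' @param panel data.frame/DataFrame with columns \code{population},
#'   \code{continent}, rownames = sample names.
#' @param gq,adRef,adAlt optional matrices (genotype quality, ref/alt allele
#'   depths).
#' @param truth optional list of ground-truth metadata.
#' @return A \linkS4class{CohortDataset}.
#' @export
CohortDataset <- function(sites, genotype, depth, panel,
                          gq = NULL, adRef = NULL, adAlt = NULL, truth = list()) {
  mc <- mcols(sites)
  for (col in c("quality", "qd")) if (is.null(mc[[col]])) mc[[col]] <- NA_real_
  if (is.null(mc$ancestral)) mc$ancestral <- "N"
  if (is.null(mc$known)) mc$known <- FALSE
  if (is.null(mc$fclass)) mc$fclass <- NA_character_
  mcols(sites) <- mc
  a <- list(genotype = genotype, depth = depth)
  if (!is.null(gq)) a$gq <- gq
  if (!is.null(adRef)) a$adRef <- adRef
  if (!is.null(adAlt)) a$adAlt <- adAlt
  se <- SummarizedExperiment(assays = a, rowRanges = sites,
                             colData = DataFrame(panel))
  obj <- new("CohortDataset", se)
  metadata(obj)$truth <- truth
  obj
}

#' @describeIn CohortDataset-class ground-truth metadata of a simulated
#'   cohort (empty list for real data)
#' @param x a CohortDataset
#' @export
truthInfo <- function(x) metadata(x)$truth

setMethod("show", "CohortDataset", function(object) {
  cat("CohortDataset:", nrow(object), "sites x", ncol(object), "samples\n")
  pop <- table(colData(object)$population)
  cat("  populations:", paste(names(pop), pop, sep = ":", collapse = " "), "\n")
  fc <- mcols(rowRanges(object))$fclass
  if (!all(is.na(fc))) {
    tab <- table(fc, useNA = "no")
    cat("  classes:", paste(names(tab), tab, sep = ":", collapse = " "), "\n")
  }
  cat("  assays:", paste(names(assays(object)), collapse = ", "), "\n")
})

#' Allele frequency spectrum
#'
#' Counts of variant sites by allele count i = 0..n in a sample of n
#' chromosomes. Unfolded (polarized) spectra count derived alleles; folded
#' spectra count minor alleles (bins above n/2 empty). Projected spectra hold
#' fractional expected counts; mass that projection moves into the
#' monomorphic bins 0 and m is kept in the \code{lost} slot.
#'
#' @slot n chromosome count.
#' @slot counts numeric length n+1; counts[i+1] = sites with allele count i.
#' @slot polarized logical; TRUE = derived-allele (unfolded).
#' @slot lost numeric length 2; projection mass in bins 0 and m.
#' @aliases AFSpectrum-class
#' @exportClass AFSpectrum
setClass("AFSpectrum", representation(
  n = "integer", counts = "numeric", polarized = "logical", lost = "numeric"
))

setValidity("AFSpectrum", function(object) {
  msg <- character()
  if (length(object@counts) != object@n + 1L)
    msg <- c(msg, "counts must have length n + 1")
  if (any(object@counts < -1e-9)) msg <- c(msg, "counts must be >= 0")
  if (!object@polarized) {
    i <- seq_along(object@counts) - 1L
    if (any(object@counts[i > object@n / 2] > 1e-9))
      msg <- c(msg, "folded spectrum must be empty above n/2")
  }
  if (length(msg)) msg else TRUE
})

#' @rdname AFSpectrum-class
#' @param n chromosome count.
#' @param counts numeric length n+1 of site counts per allele count 0..n.
#' @param polarized logical.
#' @param lost numeric(2): projection mass lost to bins 0 and m.
#' @return An \linkS4class{AFSpectrum}.
#' @export
AFSpectrum <- function(n, counts, polarized = TRUE, lost = c(0, 0)) {
  new("AFSpectrum", n = as.integer(n), counts = as.numeric(counts),
      polarized = polarized, lost = as.numeric(lost))
}

#' @describeIn AFSpectrum-class chromosome count n
#' @param x,object an AFSpectrum
#' @export
chromosomeCount <- function(x) x@n

#' @describeIn AFSpectrum-class counts vector indexed by allele count 0..n
#' @export
spectrumCounts <- function(x) stats::setNames(x@counts, 0:x@n)

#' @describeIn AFSpectrum-class number of segregating sites
#'   (sum over allele counts 1..n-1)
#' @export
segregatingSites <- function(x) sum(x@counts[seq(2L, x@n)])

setMethod("show", "AFSpectrum", function(object) {
  cat(sprintf("AFSpectrum: n=%d chromosomes, %s, S=%.6g\n",
              object@n, if (object@polarized) "unfolded (derived)" else "folded (minor)",
              segregatingSites(object)))
  if (any(object@lost > 0))
    cat(sprintf("  projection mass in monomorphic bins: %.4g (0), %.4g (n)\n",
                object@lost[1], object@lost[2]))
})

#' Site-filter thresholds of the two SNP calling pipelines
#'
#' Bundles the site-level heuristics of both calling pipelines: the
#' quality-based filter of the joint-calling pipeline (site quality and
#' supporting genotype quality), the covariate filters of the per-population
#' pipeline (quality/depth ratio QD, adjacent homopolymer run HRun, mean
#' reference allele balance AB over heterozygotes, SNP cluster density), and
#' the indel merge/filter parameters.
#'
#' @slot bcMinQuality PHRED site quality floor (default 40).
#' @slot bcMinGenotypeQuality PHRED genotype quality a supporting non-reference
#'   genotype must reach (default 10).
#' @slot biMinQd minimum QD (default 5); QD >= threshold is the pass condition.
#' @slot biMaxHrun maximum adjacent allele-sharing homopolymer run (default 3).
#' @slot biMaxAb sites with mean reference allele balance >= this fail
#'   (default 0.75).
#' @slot biClusterN,biClusterWindow a site fails if >= N called variants span
#'   <= window bases (defaults 3 within 10).
#' @slot indelMergeWindow same-type indels within this many bp merge
#'   (default 5).
#' @slot indelMinReads a site needs >= this many variant reads in some sample
#'   (default 2).
#' @aliases FilterConfig-class
#' @exportClass FilterConfig
setClass("FilterConfig", representation(
  bcMinQuality = "numeric", bcMinGenotypeQuality = "numeric",
  biMinQd = "numeric", biMaxHrun = "numeric", biMaxAb = "numeric",
  biClusterN = "integer", biClusterWindow = "integer",
  indelMergeWindow = "integer", indelMinReads = "integer"
))

setValidity("FilterConfig", function(object) {
  msg <- character()
  vals <- c(object@bcMinQuality, object@bcMinGenotypeQuality, object@biMinQd,
            object@biMaxHrun, object@biClusterN, object@biClusterWindow,
            object@indelMergeWindow, object@indelMinReads)
  if (any(vals <= 0)) msg <- c(msg, "all thresholds must be positive")
  if (object@biMaxAb <= 0 || object@biMaxAb > 1)
    msg <- c(msg, "biMaxAb must lie in (0, 1]")
  if (length(msg)) msg else TRUE
})

#' @rdname FilterConfig-class
#' @param bcMinQuality,bcMinGenotypeQuality,biMinQd,biMaxHrun,biMaxAb
#'   scalar thresholds; see slots.
#' @param biClusterN,biClusterWindow,indelMergeWindow,indelMinReads
#'   scalar thresholds; see slots.
#' @return A \linkS4class{FilterConfig}.
#' @export
FilterConfig <- function(bcMinQuality = 40, bcMinGenotypeQuality = 10,
                         biMinQd = 5, biMaxHrun = 3, biMaxAb = 0.75,
                         biClusterN = 3L, biClusterWindow = 10L,
                         indelMergeWindow = 5L, indelMinReads = 2L) {
  new("FilterConfig", bcMinQuality = bcMinQuality,
      bcMinGenotypeQuality = bcMinGenotypeQuality, biMinQd = biMinQd,
      biMaxHrun = biMaxHrun, biMaxAb = biMaxAb,
      biClusterN = as.integer(biClusterN),
      biClusterWindow = as.integer(biClusterWindow),
      indelMergeWindow = as.integer(indelMergeWindow),
      indelMinReads = as.integer(indelMinReads))
}

setMethod("show", "FilterConfig", function(object) {
  cat("FilterConfig\n")
  cat(sprintf("  joint-calling pipeline: quality >= %g with a non-ref genotype of GQ >= %g\n",
              object@bcMinQuality, object@bcMinGenotypeQuality))
  cat(sprintf("  covariate pipeline: QD >= %g, HRun <= %g, AB < %g, cluster < %d in %d bp\n",
              object@biMinQd, object@biMaxHrun, object@biMaxAb,
              object@biClusterN, object@biClusterWindow))
  cat(sprintf("  indels: merge window %d bp, >= %d variant reads in a sample\n",
              object@indelMergeWindow, object@indelMinReads))
})

#' Down-sampling specification for allele sharing
#'
#' @slot m named integer; target chromosome count per population.
#' @slot method "exact" (joint hypergeometric enumeration where feasible) or
#'   "monte-carlo".
#' @slot replicates Monte Carlo replicates per site.
#' @slot exactLimit maximum total minor-allele count C for which exact
#'   enumeration is used when method = "exact".
#' @slot seed RNG seed for the Monte Carlo path.
#' @aliases DownsampleSpec-class
#' @exportClass DownsampleSpec
setClass("DownsampleSpec", representation(
  m = "integer", method = "character", replicates = "integer",
  exactLimit = "integer", seed = "integer"
))

#' @rdname DownsampleSpec-class
#' @param m named integer vector of target chromosome counts per population.
#' @param method "exact" or "monte-carlo".
#' @param replicates Monte Carlo replicates per site.
#' @param exactLimit enumeration cutoff on the total minor count.
#' @param seed RNG seed.
#' @return A \linkS4class{DownsampleSpec}.
#' @export
DownsampleSpec <- function(m, method = c("exact", "monte-carlo"),
                           replicates = 10000L, exactLimit = 12L, seed = 1L) {
  method <- match.arg(method)
  mm <- as.integer(m); names(mm) <- names(m)
  new("DownsampleSpec", m = mm, method = method,
      replicates = as.integer(replicates), exactLimit = as.integer(exactLimit),
      seed = as.integer(seed))
}

#' Cross-population minor-allele sharing estimate
#'
#' Per minor-allele-frequency bin: the probability that two minor alleles
#' drawn at random without replacement come from the same population, from
#' different populations on the same continent, or from different continents,
#' with bootstrap confidence intervals; plus the panmictic expectation implied
#' by the (down-sampled) panel sizes.
#'
#' @slot table data.frame(bin, category, estimate, lo, hi, nSites).
#' @slot expectation named numeric(3): panmictic expectation.
#' @aliases SharingEstimate-class
#' @exportClass SharingEstimate
setClass("SharingEstimate", representation(
  table = "data.frame", expectation = "numeric"
))

#' @describeIn SharingEstimate-class the estimate table
#' @param x a SharingEstimate
#' @export
sharingTable <- function(x) x@table

setMethod("show", "SharingEstimate", function(object) {
  cat("SharingEstimate (minor-allele sharing)\n")
  print(object@table, row.names = FALSE, digits = 4)
  cat("  panmictic expectation:",
      paste(names(object@expectation), sprintf("%.4f", object@expectation),
            sep = "=", collapse = " "), "\n")
})

#' Validation assay contingency counts
#'
#' Per validation series, the counts of assays confirming a variant,
#' refuting it, and inconclusive assays; plus a 3x3 called-vs-assayed
#' genotype comparison table (rows = called class, columns = assayed class;
#' classes hom-ref, het, hom-alt).
#'
#' @slot series data.frame(series, confirmed, nonVariant, inconclusive).
#' @slot genotypes 3x3 numeric matrix, rows called, columns assayed.
#' @aliases AssayTable-class
#' @exportClass AssayTable
setClass("AssayTable", representation(
  series = "data.frame", genotypes = "matrix"
))

setValidity("AssayTable", function(object) {
  msg <- character()
  s <- object@series
  if (nrow(s) && (any(s$confirmed < 0) || any(s$nonVariant < 0) ||
                  any(s$inconclusive < 0)))
    msg <- c(msg, "series counts must be >= 0")
  g <- object@genotypes
  if (length(g) && (!all(dim(g) == c(3L, 3L)) || any(g < 0)))
    msg <- c(msg, "genotypes must be a non-negative 3x3 matrix")
  if (length(msg)) msg else TRUE
})

#' @rdname AssayTable-class
#' @param series data.frame(series, confirmed, nonVariant, inconclusive);
#'   may be empty.
#' @param genotypes 3x3 matrix of called-vs-assayed genotype counts.
#' @return An \linkS4class{AssayTable}.
#' @export
AssayTable <- function(series = data.frame(series = character(),
                                           confirmed = numeric(),
                                           nonVariant = numeric(),
                                           inconclusive = numeric()),
                       genotypes = matrix(0, 3, 3,
                                          dimnames = list(called = GT_LEVELS,
                                                          assayed = GT_LEVELS))) {
  dimnames(genotypes) <- list(called = GT_LEVELS, assayed = GT_LEVELS)
  new("AssayTable", series = series, genotypes = genotypes)
}

setMethod("show", "AssayTable", function(object) {
  cat("AssayTable\n")
  if (nrow(object@series)) {
    s <- object@series
    s$rate <- ifelse(s$confirmed + s$nonVariant > 0,
                     sprintf("%.1f%%", 100 * s$confirmed / (s$confirmed + s$nonVariant)),
                     NA)
    print(s, row.names = FALSE)
  }
  if (sum(object@genotypes) > 0) {
    cat("  called vs assayed genotypes:\n")
    print(object@genotypes)
  }
})

#' Gene model: ordered CDS intervals of one transcript
#'
#' @slot txId transcript identifier.
#' @slot cds GRanges of CDS intervals, sorted in transcription order
#'   (5' to 3' on the coding strand).
#' @slot strand "+" or "-".
#' @slot frame integer 0..2; offset of the first complete codon within the
#'   first interval (transcription order).
#' @aliases GeneModel-class
#' @exportClass GeneModel
setClass("GeneModel", representation(
  txId = "character", cds = "GRanges", strand = "character", frame = "integer"
))

setValidity("GeneModel", function(object) {
  msg <- character()
  if (!object@strand %in% c("+", "-")) msg <- c(msg, "strand must be '+' or '-'")
  if (!object@frame %in% 0:2) msg <- c(msg, "frame must be 0, 1 or 2")
  w <- sum(GenomicRanges::width(object@cds))
  if ((w - object@frame) %% 3 != 0)
    msg <- c(msg, "total CDS length minus frame offset must be divisible by 3")
  if (length(object@cds) > 1) {
    s <- GenomicRanges::start(object@cds)
    ordOk <- if (object@strand == "+") !is.unsorted(s, strictly = TRUE)
             else !is.unsorted(rev(s), strictly = TRUE)
    if (!ordOk) msg <- c(msg, "cds intervals must be sorted in transcription order")
  }
  if (length(msg)) msg else TRUE
})

#' @rdname GeneModel-class
#' @param txId transcript id.
#' @param cds GRanges of CDS intervals in transcription order.
#' @param strand "+" or "-" (defaults to the strand of \code{cds}).
#' @param frame frame offset of the first interval.
#' @return A \linkS4class{GeneModel}.
#' @export
GeneModel <- function(txId, cds, strand = NULL, frame = 0L) {
  if (is.null(strand)) {
    s <- unique(as.character(GenomicRanges::strand(cds)))
    strand <- if (length(s) == 1 && s %in% c("+", "-")) s else "+"
  }
  new("GeneModel", txId = as.character(txId), cds = cds,
      strand = strand, frame = as.integer(frame))
}

setMethod("show", "GeneModel", function(object) {
  cat(sprintf("GeneModel %s (%s strand): %d CDS intervals, %d coding bases, frame %d\n",
              object@txId, object@strand, length(object@cds),
              sum(GenomicRanges::width(object@cds)), object@frame))
})
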