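#' Synthetic reference sequence consistent with a simulated cohort
#'
#' Random background sequence (deterministic under the cohort's config seed)
#' with the cohort's reference alleles patched in at the variant positions;
#' long enough to cover every site with margin, so homopolymer-context
#' filters can run on simulated data.
#'
#' @param cohort a simulated \linkS4class{CohortDataset} (must carry its
#'   config in the truth metadata).
#' @param margin extra bases beyond the last site.
#' @return named \code{DNAStringSet}, one entry per chromosome.
#' @export
syntheticReference <- function(cohort, margin = 200L) {
  cfg <- metadata(cohort)$truth$config
  stopIfNot1(!is.null(cfg), "cohort carries no simulation config")
  gr <- rowRanges(cohort)
  out <- lapply(split(gr, as.character(seqnames(gr))), function(g) {
    L <- max(end(g)) + margin
    s <- withSeed(cfg@seed + 23L,
                  sample(c("A", "C", "G", "T"), L, replace = TRUE))
    s[start(g)] <- mcols(g)$ref
    paste(s, collapse = "")
  })
  DNAStringSet(unlist(out))
}

#' Run the full synthetic analysis pipeline
#'
#' Executes the stages in dependency order on a simulated cohort: simulate;
#' write the cohort inputs (VCF, panel, targets BED); apply both site-filter
#' suites and intersect the surviving call sets; summarize each partition
#' (size, fraction known, Ts/Tv); build and project the allele frequency
#' spectrum; estimate down-sampled allele sharing; contrast functional
#' classes across frequency bins; corrupt genotypes and report validation
#' arithmetic. Every output file is listed in a manifest with md5 checksums
#' and the seeds used; re-running with the same configuration reproduces the
#' outputs byte for byte.
#'
#' @param config list (or path to a YAML file) with optional entries
#'   \code{seed}, \code{outDir}, \code{simulation} (arguments to
#'   \code{\link{SimulationConfig}}), \code{projectTo} (chromosomes for AFS
#'   projection), \code{downsample} (fraction of the smallest panel, default
#'   0.9), \code{bootstrap} (replicates), \code{errorRates} (per-bin variant
#'   error rates).
#' @return the manifest, invisibly.
#' @export
runPipeline <- function(config = list()) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  seed <- as.integer(config$seed %||% 1L)
  outDir <- config$outDir %||% stop("configuration error: outDir is required",
                                    call. = FALSE)
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  simArgs <- config$simulation %||% list()
  simArgs$seed <- seed
  if (!is.null(simArgs$populations))
    simArgs$populations <- as.data.frame(simArgs$populations)
  scfg <- do.call(SimulationConfig, simArgs)

  files <- character(0)
  put <- function(name) { f <- file.path(outDir, name); files[[name]] <<- f; f }

  ## stage: simulate + write inputs
  cohort <- simulateCohort(scfg)
  writeCohortVcf(cohort, put("cohort.vcf"))
  writePanel(colData(cohort), put("panel.tsv"))
  writeTargetsBed(metadata(cohort)$truth$targets, put("targets.bed"))

  ## stage: filters + intersection
  reference <- syntheticReference(cohort)
  fc <- do.call(FilterConfig, config$filters %||% list())
  bc <- bcFilter(cohort, fc)
  bi <- biFilter(cohort, reference, fc)
  parts <- intersectCallsets(bc, bi)
  summ <- rbind(cbind(set = "both", summarizeCallset(parts$both)),
                cbind(set = "onlyBC", summarizeCallset(parts$onlyA)),
                cbind(set = "onlyBI", summarizeCallset(parts$onlyB)))
  write.table(summ, put("callset_summary.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  release <- parts$both

  ## stage: diversity / AFS
  m <- as.integer(config$projectTo %||% 100L)
  afs <- buildAFS(release, polarize = TRUE)
  proj <- projectAFS(afs, m)
  spec <- data.frame(alleleCount = 0:m, count = spectrumCounts(proj))
  write.table(spec, put("afs_projected.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  theta <- wattersonTheta(segregatingSites(afs), chromosomeCount(afs))

  ## stage: allele sharing
  frac <- config$downsample %||% 0.9
  sizes <- table(colData(release)$population)
  mShare <- setNames(as.integer(floor(2 * as.numeric(sizes) * frac)),
                     names(sizes))
  dspec <- DownsampleSpec(m = mShare, seed = seed + 31L)
  sharing <- downsampledSharing(release, dspec,
                                B = as.integer(config$bootstrap %||% 200L))
  write.table(sharingTable(sharing), put("sharing.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)

  ## stage: functional enrichment
  er <- unlist(config$errorRates %||%
                 c(low = 0.062, intermediate = 0.032, common = 0.034))
  binned <- binByAF(release, errorRates = er)
  contrast <- classContrast(binned, "missense", "silent", corrected = TRUE)
  enrich <- data.frame(class = rownames(binned$counts), binned$counts,
                       lowFractionCorrected = correctCounts(binned)[, "low"] /
                         rowSums(correctCounts(binned)))
  write.table(enrich, put("enrichment.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)

  ## stage: validation arithmetic on corrupted genotypes
  corr <- corruptGenotypes(release, scfg@errorRates, seed = seed + 19L)
  acc <- genotypeAccuracy(corr$assay)
  val <- data.frame(metric = c("overallAccuracyPct",
                               sprintf("accuracyPct.%s", GT_LEVELS),
                               "variantFdr", "missedRate"),
                    value = c(acc$overall, acc$perClass, acc$variantFdr,
                              acc$missedRate))
  write.table(val, put("validation.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)

  manifest <- list(seed = seed,
                   nSites = nrow(cohort), nSamples = ncol(cohort),
                   releaseSites = nrow(release),
                   wattersonTheta = theta,
                   missenseVsSilentP = contrast$p.value,
                   files = lapply(files, function(f)
                     list(path = basename(f),
                          md5 = unname(tools::md5sum(f)))))
  jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(manifest)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
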