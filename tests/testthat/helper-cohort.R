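# Shared fixture builders: tiny cohorts, gene models and references built in
# code so every test runs from first principles.

suppressPackageStartupMessages({
  library(GenomicRanges)
  library(SummarizedExperiment)
  library(S4Vectors)
  library(Biostrings)
})

# A hand-specified cohort: `geno` is a sites x samples matrix of 0/1/2/NA.
makeToyCohort <- function(geno, pos = seq_len(nrow(geno)) * 10L,
                          ref = rep("A", nrow(geno)),
                          alt = rep("G", nrow(geno)),
                          chrom = "1",
                          quality = rep(99, nrow(geno)),
                          qd = rep(15, nrow(geno)),
                          vtype = NULL,
                          ancestral = ref,
                          fclass = rep("silent", nrow(geno)),
                          known = rep(FALSE, nrow(geno)),
                          population = rep("P1", ncol(geno)),
                          continent = rep("AFR", ncol(geno)),
                          depth = NULL, gq = NULL,
                          adRef = NULL, adAlt = NULL) {
  n <- nrow(geno); s <- ncol(geno)
  if (is.null(vtype)) vtype <- variantType(ref, alt)
  if (is.null(depth)) depth <- matrix(30L, n, s)
  if (is.null(gq)) gq <- matrix(99L, n, s)
  if (is.null(adAlt)) {
    adAlt <- matrix(0L, n, s)
    adAlt[!is.na(geno) & geno == 1L] <- 15L
    adAlt[!is.na(geno) & geno == 2L] <- 30L
  }
  if (is.null(adRef)) adRef <- depth - adAlt
  samples <- sprintf("S%02d", seq_len(s))
  colnames(geno) <- colnames(depth) <- colnames(gq) <- samples
  colnames(adRef) <- colnames(adAlt) <- samples
  sites <- GRanges(chrom, IRanges(pos, width = nchar(ref)),
                   ref = ref, alt = alt, vtype = vtype, quality = quality,
                   qd = qd, ancestral = ancestral, known = known,
                   fclass = fclass)
  panel <- data.frame(population = population, continent = continent,
                      row.names = samples)
  CohortDataset(sites = sites, genotype = geno, depth = depth, panel = panel,
                gq = gq, adRef = adRef, adAlt = adAlt)
}

variantType <- ExomePopGen:::variantType

# Small multi-population simulation config for recovery/calibration tests.
smallConfig <- function(seed, populations = data.frame(
                          name = c("A1", "A2", "B1"),
                          continent = c("AFR", "AFR", "EUR"),
                          n = c(20L, 20L, 20L)),
                        nSites = c(silent = 200L),
                        theta = c(silent = 1e-3),
                        fst = 0, selectionSkew = 1, ...) {
  SimulationConfig(populations = populations, nSites = nSites, theta = theta,
                   fst = fst, selectionSkew = selectionSkew, seed = seed, ...)
}

# Single-exon gene model on a synthetic reference whose CDS is the whole
# sequence.
makeGeneModel <- function(seqstr, strand = "+", chrom = "chr1", frame = 0L) {
  ref <- DNAStringSet(setNames(seqstr, chrom))
  gm <- GeneModel("tx1", GRanges(chrom, IRanges(1L, nchar(seqstr)),
                                 strand = strand), strand = strand,
                  frame = frame)
  list(model = gm, reference = ref)
}

# Independent degeneracy oracle: enumerate the genetic code directly.
oracleDegeneracy <- function(codon, codonPos) {
  code <- Biostrings::GENETIC_CODE
  refBase <- substr(codon, codonPos, codonPos)
  aa <- code[[codon]]
  syn <- 0L
  for (b in setdiff(c("A", "C", "G", "T"), refBase)) {
    alt <- codon
    substr(alt, codonPos, codonPos) <- b
    if (code[[alt]] == aa) syn <- syn + 1L
  }
  c("non-degenerate", "two-fold", "three-fold", "four-fold")[syn + 1L]
}

# Independent sharing oracle: enumerate every ordered pair of minor alleles.
oracleSharing <- function(counts, continents) {
  labels <- rep(names(counts), counts)
  conts <- continents[labels]
  n <- length(labels)
  same <- cont <- diff <- 0L
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    if (labels[i] == labels[j]) same <- same + 1L
    else if (conts[i] == conts[j]) cont <- cont + 1L
    else diff <- diff + 1L
  }
  tot <- n * (n - 1L)
  c(same = same / tot, cont = cont / tot, diff = diff / tot)
}
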