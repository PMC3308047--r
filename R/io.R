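#' @importFrom GenomicRanges GRanges seqnames start end width strand reduce
#'   findOverlaps
#' @importFrom IRanges IRanges overlapsAny DataFrameList
#' @importFrom Biostrings DNAStringSet DNAStringSetList
#' @importFrom VariantAnnotation readVcf geno info alt ref qual VCF VCFHeader
#'   writeVcf header geno<- info<- meta<- fixed<-
#' @importFrom rtracklayer import export
#' @importFrom utils read.table write.table
NULL

#' Site keys (chrom:pos:ref:alt) identifying variants across call sets
#' @param x a \linkS4class{CohortDataset} or a GRanges with \code{ref}/\code{alt}
#'   metadata columns.
#' @return character vector of keys.
#' @export
siteKeys <- function(x) {
  gr <- if (is(x, "CohortDataset")) rowRanges(x) else x
  paste(as.character(seqnames(gr)), start(gr), mcols(gr)$ref, mcols(gr)$alt,
        sep = ":")
}

#' Read and write the sample panel (sample, population, continent)
#'
#' Tab-separated, three columns with a header line. The panel is a total map
#' sample -> population and population -> continent.
#'
#' @param path file path.
#' @return data.frame with rownames = sample and columns \code{population},
#'   \code{continent}.
#' @export
readPanel <- function(path) {
  p <- read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  stopIfNot1(all(c("sample", "population", "continent") %in% names(p)),
             "panel file must have columns sample, population, continent")
  stopIfNot1(!anyDuplicated(p$sample), "panel error: duplicated sample names")
  byPop <- unique(p[, c("population", "continent")])
  stopIfNot1(!anyDuplicated(byPop$population),
             "panel error: a population maps to several continents")
  rownames(p) <- p$sample
  p[, c("population", "continent")]
}

#' @rdname readPanel
#' @param panel data.frame with rownames = sample names.
#' @export
writePanel <- function(panel, path) {
  out <- data.frame(sample = rownames(panel),
                    population = panel$population,
                    continent = panel$continent)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read/write target regions as BED
#'
#' BED is 0-based half-open on disk; in memory targets are a 1-based closed
#' \code{GRanges} (the conversion is done by \pkg{rtracklayer}).
#'
#' @param path BED file path.
#' @return GRanges of targets.
#' @export
readTargetsBed <- function(path) {
  gr <- import(path, format = "BED")
  mcols(gr) <- NULL
  gr
}

#' @rdname readTargetsBed
#' @param targets GRanges.
#' @export
writeTargetsBed <- function(targets, path) {
  export(targets, path, format = "BED")
  invisible(path)
}

#' Consensus capture targets
#'
#' Intersects the (overlap-normalized) capture designs with each other and
#' with the exon definitions, yielding the consensus regions on which all
#' downstream calling and analysis is restricted. The result's total length
#' never exceeds that of any input.
#'
#' @param designs list of GRanges, one per capture design (>= 1).
#' @param exons GRanges of exonic sequence.
#' @return GRanges, sorted and overlap-free.
#' @examples
#' d <- GenomicRanges::GRanges("1", IRanges::IRanges(101, 200))
#' e <- GenomicRanges::GRanges("1", IRanges::IRanges(151, 250))
#' consensusTargets(list(d), e)  # [151,200]
#' @export
consensusTargets <- function(designs, exons) {
  stopIfNot1(length(designs) >= 1, "need at least one capture design")
  designs <- lapply(designs, function(g) reduce(sort(g)))
  cons <- Reduce(function(a, b) GenomicRanges::intersect(a, b), designs)
  out <- GenomicRanges::intersect(cons, reduce(sort(exons)))
  mcols(out) <- NULL
  sort(out)
}

#' Is a site inside the target regions?
#'
#' @param x GRanges of site positions (1-based), or a
#'   \linkS4class{CohortDataset}.
#' @param targets GRanges of target regions.
#' @return logical vector, one per site.
#' @export
inTarget <- function(x, targets) {
  gr <- if (is(x, "CohortDataset")) rowRanges(x) else x
  overlapsAny(gr, targets, ignore.strand = TRUE)
}

#' Read a known-sites list (VCF or two-column chrom/pos table)
#'
#' @param path a \code{.vcf} file or a tab-separated chrom, pos (1-based)
#'   table without header.
#' @return character keys \code{"chrom:pos"}.
#' @export
readKnownSites <- function(path) {
  if (grepl("\\.vcf(\\.gz)?$", path)) {
    v <- readVcf(path, genome = "unknown")
    gr <- rowRanges(v)
    unique(paste(as.character(seqnames(gr)), start(gr), sep = ":"))
  } else {
    t <- read.table(path, header = FALSE, sep = "\t", stringsAsFactors = FALSE)
    unique(paste(t[[1]], t[[2]], sep = ":"))
  }
}

#' Mark sites present in a known-sites list
#'
#' @param cohort a \linkS4class{CohortDataset}.
#' @param known character keys \code{"chrom:pos"} (see
#'   \code{\link{readKnownSites}}).
#' @return the cohort with its \code{known} site column updated.
#' @export
markKnown <- function(cohort, known) {
  gr <- rowRanges(cohort)
  keys <- paste(as.character(seqnames(gr)), start(gr), sep = ":")
  mcols(rowRanges(cohort))$known <- keys %in% known
  cohort
}

# classify ref/alt allele pair
variantType <- function(ref, alt) {
  ifelse(nchar(ref) == nchar(alt) & nchar(ref) == 1L, "SNP",
         ifelse(nchar(alt) > nchar(ref), "insertion", "deletion"))
}

#' Read a VCF into a CohortDataset
#'
#' Multi-allelic records are split into one site per alternate allele; the
#' genotype assay stores the dosage of that allele (so genotype counts are
#' conserved across the split). Per-sample DP, GQ and AD are carried over
#' when present, as are the QD and AA INFO fields.
#'
#' @param path VCF file.
#' @param panel panel data.frame (see \code{\link{readPanel}}); all VCF
#'   samples must be present.
#' @param knownSites optional character keys \code{"chrom:pos"} used to set
#'   the \code{known} column.
#' @return A \linkS4class{CohortDataset}.
#' @export
readCohortVcf <- function(path, panel, knownSites = NULL) {
  v <- readVcf(path, genome = "unknown")
  samps <- rownames(colData(v))
  missing <- setdiff(samps, rownames(panel))
  stopIfNot1(length(missing) == 0,
             paste("panel error: VCF samples not in panel:",
                   paste(missing, collapse = ", ")))
  if (nrow(v) == 0L) {
    empty <- matrix(integer(0), 0, length(samps),
                    dimnames = list(NULL, samps))
    sites <- GRanges(ref = character(0), alt = character(0),
                     vtype = character(0), quality = numeric(0),
                     qd = numeric(0), ancestral = character(0),
                     known = logical(0), fclass = character(0))
    return(CohortDataset(sites = sites, genotype = empty, depth = empty,
                         panel = panel[samps, , drop = FALSE]))
  }
  altL <- alt(v)
  k <- S4Vectors::elementNROWS(altL)
  orig <- rep(seq_len(nrow(v)), k)
  altIdx <- sequence(k)
  nOut <- length(orig)

  gt <- geno(v)$GT
  spl <- strsplit(as.vector(gt), "[/|]")
  a1 <- vapply(spl, function(z) z[1], character(1))
  a2 <- vapply(spl, function(z) if (length(z) > 1) z[2] else NA_character_,
               character(1))
  a1m <- matrix(a1, nrow(v)); a2m <- matrix(a2, nrow(v))
  dosage <- function(am, idx) {
    x <- am[orig, , drop = FALSE]
    miss <- is.na(x) | x == "."
    d <- (x == as.character(idx)) * 1L
    d[miss] <- NA_integer_
    d
  }
  g <- dosage(a1m, altIdx) + dosage(a2m, altIdx)
  storage.mode(g) <- "integer"
  colnames(g) <- samps

  pull <- function(name, default) {
    m <- geno(v)[[name]]
    if (is.null(m)) matrix(default, nOut, length(samps),
                           dimnames = list(NULL, samps))
    else m[orig, , drop = FALSE]
  }
  depth <- pull("DP", NA_integer_)
  gq <- pull("GQ", NA_real_)
  adRef <- adAlt <- NULL
  if (!is.null(geno(v)$AD)) {
    adm <- geno(v)$AD
    adRef <- matrix(vapply(as.vector(adm), function(z)
      if (length(z)) as.integer(z[1]) else NA_integer_, integer(1)), nrow(v))
    adRef <- adRef[orig, , drop = FALSE]
    adAltAll <- matrix(NA_integer_, nOut, length(samps))
    admO <- adm[orig, , drop = FALSE]
    for (j in seq_along(samps)) {
      adAltAll[, j] <- vapply(seq_len(nOut), function(i) {
        z <- admO[[i, j]]
        if (length(z) > altIdx[i]) as.integer(z[altIdx[i] + 1L]) else NA_integer_
      }, integer(1))
    }
    adAlt <- adAltAll
    colnames(adRef) <- colnames(adAlt) <- samps
  }

  rr <- rowRanges(v)[orig]
  refs <- as.character(ref(v))[orig]
  alts <- as.character(unlist(altL))
  inf <- info(v)
  qdv <- if (!is.null(inf$QD)) as.numeric(inf$QD)[orig] else NA_real_
  aav <- if (!is.null(inf$AA)) as.character(inf$AA)[orig] else "N"
  aav[is.na(aav) | aav == "."] <- "N"
  fcv <- if (!is.null(inf$FC)) as.character(inf$FC)[orig] else NA_character_

  sites <- GRanges(seqnames(rr), IRanges(start(rr), width = nchar(refs)),
                   ref = refs, alt = alts, vtype = variantType(refs, alts),
                   quality = as.numeric(qual(v))[orig], qd = qdv,
                   ancestral = aav, known = FALSE, fclass = fcv)
  names(sites) <- NULL
  cohort <- CohortDataset(sites = sites, genotype = g, depth = depth,
                          panel = panel[samps, , drop = FALSE],
                          gq = gq, adRef = adRef, adAlt = adAlt)
  if (!is.null(knownSites)) cohort <- markKnown(cohort, knownSites)
  cohort
}

#' Write a CohortDataset as VCF 4.2
#'
#' Emits GT, DP, GQ and AD per sample plus QD, AA and FC INFO fields; the
#' read-write-read round trip preserves positions, alleles and genotypes
#' exactly.
#'
#' @param cohort a \linkS4class{CohortDataset}.
#' @param path output path (plain \code{.vcf}).
#' @return the path, invisibly.
#' @export
writeCohortVcf <- function(cohort, path) {
  gr <- rowRanges(cohort)
  mc <- mcols(gr)
  n <- length(gr)
  samps <- colnames(cohort)
  g <- assay(cohort, "genotype")
  gt <- matrix("./.", n, length(samps), dimnames = list(NULL, samps))
  gt[!is.na(g) & g == 0L] <- "0/0"
  gt[!is.na(g) & g == 1L] <- "0/1"
  gt[!is.na(g) & g == 2L] <- "1/1"

  depth <- assay(cohort, "depth")
  storage.mode(depth) <- "integer"
  gq <- if ("gq" %in% names(assays(cohort))) {
    x <- assay(cohort, "gq"); storage.mode(x) <- "integer"; x
  } else matrix(NA_integer_, n, length(samps))
  hasAD <- all(c("adRef", "adAlt") %in% names(assays(cohort)))
  genoList <- list(GT = gt, DP = depth, GQ = gq)
  genoList <- lapply(genoList, function(m) {
    dimnames(m) <- list(NULL, samps)
    m
  })
  if (hasAD) {
    aR <- assay(cohort, "adRef"); aA <- assay(cohort, "adAlt")
    ad <- matrix(mapply(function(r, a) as.integer(c(r, a)),
                        as.vector(aR), as.vector(aA), SIMPLIFY = FALSE),
                 n, length(samps), dimnames = list(NULL, samps))
    genoList$AD <- ad
  }

  rr <- GRanges(seqnames(gr), IRanges(start(gr), width = 1L))
  names(rr) <- paste0(as.character(seqnames(gr)), ":", start(gr), "_",
                      mc$ref, "/", mc$alt)
  hdr <- VCFHeader(samples = samps)
  meta(hdr) <- IRanges::DataFrameList(
    fileformat = S4Vectors::DataFrame(Value = "VCFv4.2",
                                      row.names = "fileformat"),
    fileDate = S4Vectors::DataFrame(Value = format(Sys.Date(), "%Y%m%d"),
                                    row.names = "fileDate"))
  info(hdr) <- S4Vectors::DataFrame(
    Number = c("1", "1", "1"), Type = c("Float", "String", "String"),
    Description = c("Variant confidence divided by depth of coverage",
                    "Ancestral allele", "Functional class"),
    row.names = c("QD", "AA", "FC"))
  geno(hdr) <- S4Vectors::DataFrame(
    Number = c("1", "1", "1", "R"),
    Type = c("String", "Integer", "Integer", "Integer"),
    Description = c("Genotype", "Read depth", "Genotype quality",
                    "Allele depths (ref, alt)"),
    row.names = c("GT", "DP", "GQ", "AD"))

  qd <- mc$qd; qd[is.na(qd)] <- NA_real_
  aa <- mc$ancestral; aa[is.na(aa)] <- "N"
  fc <- mc$fclass; fc[is.na(fc)] <- "."
  vcf <- VCF(rowRanges = rr,
             colData = S4Vectors::DataFrame(Samples = seq_along(samps),
                                            row.names = samps),
             exptData = list(header = hdr),
             fixed = S4Vectors::DataFrame(
               REF = DNAStringSet(mc$ref),
               ALT = DNAStringSetList(as.list(mc$alt)),
               QUAL = as.numeric(mc$quality),
               FILTER = rep(".", n)),
             info = S4Vectors::DataFrame(QD = qd, AA = aa, FC = fc),
             geno = S4Vectors::SimpleList(genoList))
  writeVcf(vcf, path, index = FALSE)
  invisible(path)
}
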