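#' @importFrom Biostrings subseq
NULL

#' Quality-based site filter of the joint-calling pipeline
#'
#' Keeps sites whose PHRED site quality reaches the threshold and that have
#' at least one sample with a non-reference genotype whose genotype quality
#' also reaches its threshold.
#'
#' @param cohort a \linkS4class{CohortDataset} with \code{quality} site
#'   metadata and a \code{gq} assay.
#' @param config a \linkS4class{FilterConfig}.
#' @return the kept subset of \code{cohort}.
#' @export
bcFilter <- function(cohort, config = FilterConfig()) {
  q <- mcols(rowRanges(cohort))$quality
  stopIfNot1(!all(is.na(q)), "annotation error: site quality missing")
  stopIfNot1("gq" %in% names(assays(cohort)),
             "annotation error: genotype qualities missing")
  g <- assay(cohort, "genotype")
  gq <- assay(cohort, "gq")
  support <- rowSums(!is.na(g) & g > 0L & !is.na(gq) &
                       gq >= config@bcMinGenotypeQuality) > 0L
  keep <- !is.na(q) & q >= config@bcMinQuality & support
  cohort[keep, ]
}

#' Adjacent allele-sharing homopolymer run length (HRun)
#'
#' Length of the longest homopolymer of the alternate-allele base immediately
#' adjacent to the variant position, on either side; a signature of
#' homopolymer sequencing artifacts. The variant base itself is not counted.
#'
#' @param reference named \code{DNAStringSet} (one entry per chromosome) or a
#'   single \code{DNAString}/character when \code{chrom} is omitted.
#' @param chrom chromosome name(s).
#' @param pos 1-based variant position(s).
#' @param alt alternate base(s).
#' @return integer vector of run lengths.
#' @examples
#' ref <- Biostrings::DNAStringSet(c(chr1 = "CAAAAT"))
#' hrun(ref, "chr1", 1, "A")  # 4: the AAAA run to the right
#' @export
hrun <- function(reference, chrom, pos, alt) {
  seqs <- as.character(reference)
  n <- max(length(pos), length(chrom), length(alt))
  pos <- rep_len(pos, n); chrom <- rep_len(chrom, n); alt <- rep_len(alt, n)
  vapply(seq_len(n), function(i) {
    s <- seqs[[chrom[i]]]
    if (is.na(s)) stop("bounds error: chromosome not in reference", call. = FALSE)
    L <- nchar(s)
    if (pos[i] < 1 || pos[i] > L)
      stop("bounds error: position outside reference", call. = FALSE)
    b <- alt[i]
    run <- function(from, step) {
      len <- 0L; p <- from
      while (p >= 1 && p <= L && substr(s, p, p) == b) {
        len <- len + 1L; p <- p + step
      }
      len
    }
    max(run(pos[i] - 1L, -1L), run(pos[i] + 1L, 1L))
  }, integer(1))
}

#' Allele balance averaged over heterozygous samples
#'
#' Mean, over heterozygous samples, of the fraction of reads supporting the
#' reference allele. Sites without heterozygotes return \code{NA} (the
#' statistic is undefined there and such sites pass the AB filter by
#' convention).
#'
#' @param cohort a \linkS4class{CohortDataset} with \code{adRef}/\code{adAlt}
#'   assays.
#' @return numeric vector, one value (or NA) per site.
#' @export
alleleBalance <- function(cohort) {
  stopIfNot1(all(c("adRef", "adAlt") %in% names(assays(cohort))),
             "annotation error: per-sample allele depths missing")
  g <- assay(cohort, "genotype")
  aR <- assay(cohort, "adRef"); aA <- assay(cohort, "adAlt")
  het <- !is.na(g) & g == 1L
  tot <- aR + aA
  frac <- ifelse(het & !is.na(tot) & tot > 0, aR / tot, NA_real_)
  cnt <- rowSums(het & !is.na(tot) & tot > 0)
  out <- rowSums(frac, na.rm = TRUE) / cnt
  out[cnt == 0] <- NA_real_
  out
}

#' Flag sites in dense SNP clusters
#'
#' A site is flagged when it belongs to any run of \code{n} or more called
#' variants spanning at most \code{window} bases (positions are compared per
#' chromosome; the span is the position difference of the first and last
#' variant in the run).
#'
#' @param chrom,pos chromosome and 1-based position per called variant.
#' @param n,window cluster definition (defaults 3 variants within 10 bases).
#' @return logical vector in input order.
#' @export
snpClusterFlag <- function(chrom, pos, n = 3L, window = 10L) {
  flag <- logical(length(pos))
  for (ch in unique(chrom)) {
    idx <- which(chrom == ch)
    o <- idx[order(pos[idx])]
    p <- pos[o]
    if (length(p) >= n) {
      for (i in seq_len(length(p) - n + 1L)) {
        if (p[i + n - 1L] - p[i] <= window)
          flag[o[i:(i + n - 1L)]] <- TRUE
      }
    }
  }
  flag
}

#' Covariate site filters of the per-population calling pipeline
#'
#' Keeps sites passing all four heuristics: QD (site quality / covered depth)
#' at or above its floor, adjacent allele-sharing homopolymer run no longer
#' than the maximum, mean reference allele balance over heterozygotes below
#' the cutoff (undefined AB passes), and no membership in a dense SNP
#' cluster.
#'
#' @param cohort a \linkS4class{CohortDataset} with \code{qd} metadata,
#'   allele-depth assays, and SNP sites.
#' @param reference named \code{DNAStringSet} covering the sites.
#' @param config a \linkS4class{FilterConfig}.
#' @return the kept subset of \code{cohort}.
#' @export
biFilter <- function(cohort, reference, config = FilterConfig()) {
  gr <- rowRanges(cohort)
  mc <- mcols(gr)
  stopIfNot1(!all(is.na(mc$qd)), "annotation error: QD missing")
  qdPass <- !is.na(mc$qd) & mc$qd >= config@biMinQd
  hr <- hrun(reference, as.character(seqnames(gr)), start(gr), mc$alt)
  hrunPass <- hr <= config@biMaxHrun
  ab <- alleleBalance(cohort)
  abPass <- is.na(ab) | ab < config@biMaxAb
  cluster <- snpClusterFlag(as.character(seqnames(gr)), start(gr),
                            config@biClusterN, config@biClusterWindow)
  cohort[qdPass & hrunPass & abPass & !cluster, ]
}

#' Intersect two call sets
#'
#' Sites are keyed by (chrom, pos, ref, alt); the partition into shared and
#' unique fractions is exact and disjoint.
#'
#' @param a,b \linkS4class{CohortDataset}s (or GRanges with ref/alt columns)
#'   on the same reference coordinates.
#' @return list(both, onlyA, onlyB): \code{both} is the subset of \code{a}
#'   whose key also occurs in \code{b}.
#' @export
intersectCallsets <- function(a, b) {
  ka <- siteKeys(a); kb <- siteKeys(b)
  inB <- ka %in% kb
  inA <- kb %in% ka
  list(both = a[inB, ], onlyA = a[!inB, ], onlyB = b[!inA, ])
}

#' Transition/transversion ratio of a SNP set
#'
#' Transitions are A<->G and C<->T; everything else is a transversion.
#' Classified per alternate allele (split multi-allelic records count once
#' per alternate). With zero transversions the ratio is reported as
#' \code{Inf}.
#'
#' @param ref,alt single-base allele vectors.
#' @return the ratio (numeric, possibly \code{Inf}).
#' @export
tsTv <- function(ref, alt) {
  pair <- paste0(ref, alt)
  ts <- pair %in% c("AG", "GA", "CT", "TC")
  nTs <- sum(ts); nTv <- sum(!ts)
  if (nTv == 0) Inf else nTs / nTv
}

#' Summary QC of a call set: size, fraction known, Ts/Tv
#'
#' @param cohort a \linkS4class{CohortDataset} (SNP sites are used for
#'   Ts/Tv).
#' @param knownSites optional character keys \code{"chrom:pos"}; when
#'   omitted the cohort's \code{known} column is used.
#' @return data.frame(nSites, pctKnown, tsTv).
#' @export
summarizeCallset <- function(cohort, knownSites = NULL) {
  if (!is.null(knownSites)) cohort <- markKnown(cohort, knownSites)
  mc <- mcols(rowRanges(cohort))
  n <- nrow(cohort)
  snp <- mc$vtype == "SNP"
  data.frame(nSites = n,
             pctKnown = if (n) 100 * sum(mc$known) / n else NA_real_,
             tsTv = if (any(snp)) tsTv(mc$ref[snp], mc$alt[snp]) else NA_real_)
}

#' Merge equivalent indels across call sets
#'
#' Same-type (insertion vs deletion) events within the merge window of each
#' other are clustered transitively; each cluster emits a single
#' representative at the leftmost position, carrying the alleles of the
#' member with the highest alternate allele count. Merging an already merged
#' set changes nothing.
#'
#' @param callsets list of GRanges with metadata columns \code{ref},
#'   \code{alt}, \code{vtype} ("insertion"/"deletion") and optionally
#'   \code{ac}.
#' @param window maximum distance (bp) for equivalence (default 5).
#' @return GRanges of merged representative events.
#' @export
mergeIndels <- function(callsets, window = 5L) {
  if (is(callsets, "GRanges")) callsets <- list(callsets)
  pooled <- do.call(c, lapply(callsets, function(g) {
    if (is.null(mcols(g)$ac)) mcols(g)$ac <- 1
    g[, c("ref", "alt", "vtype", "ac")]
  }))
  if (length(pooled) == 0) return(pooled)
  keyGrp <- paste(as.character(seqnames(pooled)), mcols(pooled)$vtype)
  outIdx <- integer(0)
  for (grp in unique(keyGrp)) {
    idx <- which(keyGrp == grp)
    o <- idx[order(start(pooled)[idx])]
    p <- start(pooled)[o]
    newCluster <- c(TRUE, diff(p) > window)  # transitive chain clustering
    cl <- cumsum(newCluster)
    for (c1 in unique(cl)) {
      members <- o[cl == c1]
      best <- members[which.max(mcols(pooled)$ac[members])]
      left <- members[which.min(start(pooled)[members])]
      rep1 <- pooled[best]
      GenomicRanges::ranges(rep1) <-
        IRanges(start(pooled)[left], width = width(pooled)[best])
      outIdx <- c(outIdx, best)
      pooled[best] <- rep1
    }
  }
  out <- pooled[sort(outIdx)]
  sort(out)
}

#' Site-level indel filters
#'
#' Removes sites lacking any sample with the minimum number of variant reads,
#' and 1-bp indels whose alternate allele count is 1 (singleton length-1
#' events, the most artifact-prone category).
#'
#' @param cohort a \linkS4class{CohortDataset} of indel sites with an
#'   \code{adAlt} assay.
#' @param config a \linkS4class{FilterConfig}.
#' @return the kept subset of \code{cohort}.
#' @export
indelSiteFilters <- function(cohort, config = FilterConfig()) {
  stopIfNot1("adAlt" %in% names(assays(cohort)),
             "annotation error: per-sample variant read counts missing")
  aA <- assay(cohort, "adAlt")
  readPass <- rowSums(!is.na(aA) & aA >= config@indelMinReads) > 0L
  mc <- mcols(rowRanges(cohort))
  len <- abs(nchar(mc$alt) - nchar(mc$ref))
  ac <- altAlleleCounts(assay(cohort, "genotype"))$ac
  singleton1bp <- len == 1L & ac == 1
  cohort[readPass & !singleton1bp, ]
}
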