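#' @importFrom Biostrings GENETIC_CODE reverseComplement DNAString
NULL

BASES <- c("A", "C", "G", "T")

# Map a genomic position to (codon index, position within codon 1..3) and the
# codon's three genomic positions (in transcription order) for one gene model.
codingContext <- function(pos, model) {
  cds <- model@cds
  starts <- start(cds); ends <- end(cds); w <- width(cds)
  # coding coordinate (0-based, transcription order) of each genomic position
  genomic <- unlist(lapply(seq_along(cds), function(i) {
    if (model@strand == "+") starts[i]:ends[i] else ends[i]:starts[i]
  }))
  cdsPos <- match(pos, genomic)
  if (is.na(cdsPos)) stop("annotation error: position not in CDS", call. = FALSE)
  cdsPos <- cdsPos - 1L - model@frame          # 0-based within-codon space
  if (cdsPos < 0) stop("annotation error: position before the first codon",
                       call. = FALSE)
  codonIdx <- cdsPos %/% 3L
  codonPos <- cdsPos %% 3L + 1L
  codonGenomic <- genomic[model@frame + codonIdx * 3L + 1:3]
  list(codonIdx = codonIdx, codonPos = codonPos, codonGenomic = codonGenomic)
}

# reference codon (coding-strand sense) for a context
codonBases <- function(ctx, model, reference) {
  chrom <- as.character(seqnames(model@cds))[1]
  s <- as.character(reference)[[chrom]]
  b <- vapply(ctx$codonGenomic, function(p) substr(s, p, p), character(1))
  if (model@strand == "-")
    b <- vapply(b, function(x) as.character(reverseComplement(DNAString(x))),
                character(1))
  paste(b, collapse = "")
}

complementBase <- function(b)
  c(A = "T", C = "G", G = "C", T = "A", N = "N")[[b]]

#' Codon degeneracy class of a coding position
#'
#' Counts how many of the three possible substitutions at the position leave
#' the encoded amino acid unchanged (standard genetic code, strand aware):
#' 0/1/2/3 synonymous outcomes map to non-degenerate, two-fold, three-fold
#' and four-fold. With several overlapping gene models, one class is returned
#' per transcript context (de-duplicated).
#'
#' @param pos 1-based genomic position (scalar).
#' @param models a \linkS4class{GeneModel} or list of them overlapping the
#'   position.
#' @param reference named \code{DNAStringSet}.
#' @return character vector of degeneracy classes.
#' @examples
#' ref <- Biostrings::DNAStringSet(c(chr1 = "GGA"))
#' gm <- GeneModel("t1", GenomicRanges::GRanges("chr1",
#'                 IRanges::IRanges(1, 3), strand = "+"))
#' degeneracy(3, gm, ref)  # third position of GGA (Gly): four-fold
#' @export
degeneracy <- function(pos, models, reference) {
  if (is(models, "GeneModel")) models <- list(models)
  classes <- vapply(models, function(model) {
    ctx <- codingContext(pos, model)
    codon <- codonBases(ctx, model, reference)
    refBase <- substr(codon, ctx$codonPos, ctx$codonPos)
    if (!refBase %in% BASES) {
      warning("ambiguous reference base at position ", pos, "; skipped")
      return(NA_character_)
    }
    aaRef <- GENETIC_CODE[[codon]]
    syn <- sum(vapply(setdiff(BASES, refBase), function(b) {
      alt <- codon
      substr(alt, ctx$codonPos, ctx$codonPos) <- b
      GENETIC_CODE[[alt]] == aaRef
    }, logical(1)))
    c("non-degenerate", "two-fold", "three-fold", "four-fold")[syn + 1L]
  }, character(1))
  unique(classes[!is.na(classes)])
}

#' Amino-acid effect of a coding SNP
#'
#' Translates the reference and alternate codons: same amino acid is
#' \code{"silent"}, a change to a stop codon (from a non-stop) is
#' \code{"nonsense"}, any other change (including stop-loss) is
#' \code{"missense"}.
#'
#' @param pos 1-based genomic position of the SNP.
#' @param alt alternate base (genomic strand).
#' @param model a \linkS4class{GeneModel}.
#' @param reference named \code{DNAStringSet}.
#' @return one of \code{"silent"}, \code{"missense"}, \code{"nonsense"}.
#' @export
variantEffect <- function(pos, alt, model, reference) {
  stopIfNot1(alt %in% BASES,
             "unsupported variant: only single-base substitutions")
  ctx <- codingContext(pos, model)
  codon <- codonBases(ctx, model, reference)
  altSense <- if (model@strand == "-") complementBase(alt) else alt
  altCodon <- codon
  substr(altCodon, ctx$codonPos, ctx$codonPos) <- altSense
  aaRef <- GENETIC_CODE[[codon]]
  aaAlt <- GENETIC_CODE[[altCodon]]
  if (aaRef == aaAlt) "silent"
  else if (aaAlt == "*" && aaRef != "*") "nonsense"
  else "missense"
}

.SIFT_LEVELS <- c("tolerated", "damaging-low-confidence", "damaging")
.PP2_LEVELS <- c("benign", "possibly-damaging", "probably-damaging")

#' Combine SIFT and PolyPhen-2 predictions into a three-class call
#'
#' Two rules are provided. \code{"hgmd3"}: Benign = benign + tolerated, or
#' one of these plus no prediction; Damaging = probably-damaging + damaging,
#' or one of these plus no prediction; Possibly-damaging =
#' possibly-damaging + damaging-low-confidence, either middle-severity call
#' alone, or any conflict between the programs. \code{"severest"}: the more
#' severe of the two ordinal severities wins.
#'
#' @param sift \code{"tolerated"}, \code{"damaging-low-confidence"},
#'   \code{"damaging"} or \code{"none"}.
#' @param polyphen \code{"benign"}, \code{"possibly-damaging"},
#'   \code{"probably-damaging"} or \code{"none"}.
#' @param rule \code{"hgmd3"} or \code{"severest"}.
#' @return \code{"Benign"}, \code{"Possibly-damaging"} or \code{"Damaging"}
#'   (vectorized).
#' @examples
#' combinePredictions("tolerated", "benign")                 # Benign
#' combinePredictions("damaging", "benign")                  # conflict
#' combinePredictions("damaging", "benign", rule = "severest")
#' @export
combinePredictions <- function(sift, polyphen, rule = c("hgmd3", "severest")) {
  rule <- match.arg(rule)
  n <- max(length(sift), length(polyphen))
  sift <- rep_len(sift, n); polyphen <- rep_len(polyphen, n)
  stopIfNot1(all(sift %in% c(.SIFT_LEVELS, "none")),
             "invalid SIFT category")
  stopIfNot1(all(polyphen %in% c(.PP2_LEVELS, "none")),
             "invalid PolyPhen-2 category")
  if (any(sift == "none" & polyphen == "none"))
    stop("no prediction from either program", call. = FALSE)
  sSev <- match(sift, .SIFT_LEVELS)        # NA for none
  pSev <- match(polyphen, .PP2_LEVELS)
  out <- character(n)
  if (rule == "severest") {
    sev <- pmax(sSev, pSev, na.rm = TRUE)
    out <- c("Benign", "Possibly-damaging", "Damaging")[sev]
  } else {
    for (i in seq_len(n)) {
      s <- sSev[i]; p <- pSev[i]
      out[i] <- if (is.na(s)) c("Benign", "Possibly-damaging", "Damaging")[p]
      else if (is.na(p)) c("Benign", "Possibly-damaging", "Damaging")[s]
      else if (s == p) c("Benign", "Possibly-damaging", "Damaging")[s]
      else "Possibly-damaging"             # conflict between the programs
    }
  }
  out
}
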