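test_that("quality-based filter requires site quality and a supporting non-reference genotype", {
  geno <- rbind(c(0L, 1L, 0L),   # quality 50, het with GQ 20 -> kept
                c(0L, 1L, 1L),   # quality 39 -> removed
                c(0L, 0L, 0L),   # quality 50, hom-ref only -> removed
                c(0L, 2L, 0L))   # quality 50, hom-alt but GQ 5 -> removed
  gq <- matrix(20L, 4, 3)
  gq[4, ] <- 5L
  co <- makeToyCohort(geno, quality = c(50, 39, 50, 50), gq = gq)
  kept <- bcFilter(co)
  expect_equal(start(rowRanges(kept)), 10L)
})

test_that("hrun measures the adjacent homopolymer of the alternate base", {
  ref <- DNAStringSet(c(chr1 = "CAAAAT"))
  expect_equal(hrun(ref, "chr1", 1, "A"), 4L)     # C->A before AAAA
  expect_equal(hrun(ref, "chr1", 1, "G"), 0L)     # G does not share the run
  # runs on both sides: alt G with GG to the left and GGGGG to the right
  ref2 <- DNAStringSet(c(chr1 = "GGAGGGGGT"))
  expect_equal(hrun(ref2, "chr1", 3, "G"), 5L)
  # direct-scan oracle on random sequences
  set.seed(11)
  s <- paste(sample(c("A", "C", "G", "T"), 300, replace = TRUE,
                    prob = c(0.4, 0.1, 0.1, 0.4)), collapse = "")
  refR <- DNAStringSet(c(chr1 = s))
  for (pos in sample(2:299, 40)) {
    b <- sample(c("A", "C", "G", "T"), 1)
    left <- 0L; p <- pos - 1L
    while (p >= 1 && substr(s, p, p) == b) { left <- left + 1L; p <- p - 1L }
    right <- 0L; p <- pos + 1L
    while (p <= 300 && substr(s, p, p) == b) { right <- right + 1L; p <- p + 1L }
    expect_equal(hrun(refR, "chr1", pos, b), max(left, right))
  }
  expect_error(hrun(ref, "chr1", 99, "A"), "bounds")
})

test_that("allele balance averages the reference read fraction over heterozygotes", {
  geno <- rbind(c(1L, 0L), c(1L, 1L), c(1L, 1L), c(0L, 2L))
  adRef <- rbind(c(9L, 30L), c(5L, 5L), c(8L, 6L), c(30L, 0L))
  adAlt <- rbind(c(1L, 0L), c(5L, 5L), c(2L, 4L), c(0L, 30L))
  co <- makeToyCohort(geno, depth = adRef + adAlt, adRef = adRef, adAlt = adAlt)
  ab <- alleleBalance(co)
  expect_equal(ab, c(0.9, 0.5, 0.7, NA))
})

test_that("SNP cluster rule flags runs of 3 variants spanning at most 10 bases", {
  expect_identical(snpClusterFlag(rep("1", 3), c(100L, 104L, 108L)),
                   rep(TRUE, 3))                   # span 8 <= 10
  expect_identical(snpClusterFlag(rep("1", 3), c(100L, 105L, 111L)),
                   rep(FALSE, 3))                  # span 11 > 10
  expect_identical(snpClusterFlag(rep("1", 2), c(100L, 101L)),
                   rep(FALSE, 2))                  # only two variants
  expect_identical(snpClusterFlag(c("1", "2", "1", "1"),
                                  c(100L, 104L, 104L, 108L)),
                   c(TRUE, FALSE, TRUE, TRUE))     # per-chromosome windows
})

test_that("covariate filter equals the intersection of its four single-rule survivors", {
  set.seed(23)
  n <- 60L
  pos <- sort(sample.int(3000, n)) + 50L
  refSeq <- paste(sample(c("A", "C", "G", "T"), 4000, replace = TRUE,
                         prob = c(0.35, 0.15, 0.15, 0.35)), collapse = "")
  reference <- DNAStringSet(c(`1` = refSeq))
  ref <- vapply(pos, function(p) substr(refSeq, p, p), character(1))
  alt <- vapply(ref, function(b) sample(setdiff(c("A", "C", "G", "T"), b), 1),
                character(1))
  geno <- matrix(sample(c(0L, 1L, 2L), n * 6, replace = TRUE,
                        prob = c(0.5, 0.4, 0.1)), n, 6)
  geno[rowSums(geno) == 0, 1] <- 1L
  adRef <- matrix(sample(0:20, n * 6, replace = TRUE), n, 6)
  adAlt <- matrix(sample(0:20, n * 6, replace = TRUE), n, 6)
  qd <- round(runif(n, 2, 20), 1)
  co <- makeToyCohort(geno, pos = pos, ref = ref, alt = alt, qd = qd,
                      depth = adRef + adAlt, adRef = adRef, adAlt = adAlt)
  fc <- FilterConfig()
  kept <- siteKeys(biFilter(co, reference, fc))

  qdPass <- qd >= 5
  hrPass <- hrun(reference, "1", pos, alt) <= 3
  ab <- alleleBalance(co)
  abPass <- is.na(ab) | ab < 0.75
  clPass <- !snpClusterFlag(rep("1", n), pos)
  expect_identical(kept, siteKeys(co)[qdPass & hrPass & abPass & clPass])

  # spot checks from the rule definitions
  co1 <- makeToyCohort(matrix(c(1L, 1L), 1, 2), pos = 60L, ref = "C",
                       alt = "G", qd = 4.9,
                       adRef = matrix(10L, 1, 2), adAlt = matrix(10L, 1, 2),
                       depth = matrix(20L, 1, 2))
  expect_equal(nrow(biFilter(co1, reference)), 0L)  # QD below the floor
})

test_that("call-set intersection partitions exactly and symmetrically", {
  set.seed(31)
  keyPool <- expand.grid(pos = 1:300, alt = c("G", "T"))
  mk <- function(rows) {
    makeToyCohort(matrix(1L, length(rows), 2),
                  pos = keyPool$pos[rows],
                  alt = as.character(keyPool$alt[rows]))
  }
  ra <- sample.int(600, 250); rb <- sample.int(600, 250)
  a <- mk(ra); b <- mk(rb)
  parts <- intersectCallsets(a, b)
  expect_equal(nrow(parts$both) + nrow(parts$onlyA), nrow(a))
  expect_equal(sort(siteKeys(parts$both)),
               sort(intersect(siteKeys(a), siteKeys(b))))
  expect_equal(sort(siteKeys(parts$onlyA)),
               sort(setdiff(siteKeys(a), siteKeys(b))))
  expect_equal(sort(siteKeys(parts$onlyB)),
               sort(setdiff(siteKeys(b), siteKeys(a))))
  swapped <- intersectCallsets(b, a)
  expect_equal(sort(siteKeys(swapped$both)), sort(siteKeys(parts$both)))
  expect_equal(siteKeys(swapped$onlyA), siteKeys(parts$onlyB))

  same <- intersectCallsets(a, a)
  expect_equal(nrow(same$onlyA), 0L)
  expect_equal(nrow(same$onlyB), 0L)
})

test_that("call-set summary: Ts/Tv and fraction known", {
  co <- makeToyCohort(matrix(1L, 4, 2),
                      ref = c("A", "C", "G", "A"),
                      alt = c("G", "T", "A", "T"),
                      known = c(TRUE, TRUE, FALSE, FALSE))
  s <- summarizeCallset(co)
  expect_equal(s$tsTv, 3)                      # 3 transitions, 1 transversion
  expect_equal(s$pctKnown, 50)
  expect_equal(s$nSites, 4L)
  allTs <- makeToyCohort(matrix(1L, 2, 2), ref = c("A", "C"), alt = c("G", "T"))
  expect_equal(summarizeCallset(allTs)$tsTv, Inf)
  expect_equal(summarizeCallset(allTs)$pctKnown, 0)
  expect_equal(summarizeCallset(markKnown(allTs, c("1:10", "1:20")))$pctKnown,
               100)
})

test_that("indel merging clusters same-type events transitively and is idempotent", {
  gr <- function(pos, vtype, ref, alt, ac = 1) {
    GRanges("1", IRanges(pos, width = nchar(ref)), ref = ref, alt = alt,
            vtype = vtype, ac = ac)
  }
  # deletions 4 bp apart merge
  m1 <- mergeIndels(list(gr(100L, "deletion", "AT", "A"),
                         gr(104L, "deletion", "CT", "C")))
  expect_equal(length(m1), 1L)
  expect_equal(start(m1), 100L)
  # type mismatch does not merge
  m2 <- mergeIndels(list(gr(100L, "insertion", "A", "AT"),
                         gr(103L, "deletion", "CT", "C")))
  expect_equal(length(m2), 2L)
  # transitive closure across three events each within 5 bp of a neighbour
  m3 <- mergeIndels(list(gr(100L, "deletion", "AT", "A"),
                         gr(104L, "deletion", "CT", "C", ac = 5),
                         gr(108L, "deletion", "GT", "G")))
  expect_equal(length(m3), 1L)
  expect_equal(start(m3), 100L)
  expect_equal(mcols(m3)$alt, "C")             # alleles of the highest-AC member
  expect_identical(mergeIndels(list(m3)), m3)  # idempotent

  # union-find oracle on random positions
  set.seed(13)
  pos <- sort(sample.int(500, 40))
  events <- gr(pos, "deletion", "AT", "A")
  merged <- mergeIndels(list(events))
  expectedClusters <- 1L + sum(diff(pos) > 5)
  expect_equal(length(merged), expectedClusters)
  expect_identical(mergeIndels(list(merged)), merged)
})

test_that("indel site filters: variant-read support and the singleton length-1 rule", {
  mk <- function(ref, alt, geno, adAlt) {
    makeToyCohort(geno, ref = ref, alt = alt,
                  adAlt = adAlt, adRef = matrix(10L, nrow(geno), ncol(geno)),
                  depth = adAlt + 10L)
  }
  # 1-bp deletion, AC=1 -> removed by the singleton rule
  co1 <- mk("AT", "A", matrix(c(1L, 0L), 1, 2), matrix(c(4L, 0L), 1, 2))
  expect_equal(nrow(indelSiteFilters(co1)), 0L)
  # 1-bp deletion, AC=3 with read support -> kept
  co2 <- mk("AT", "A", matrix(c(1L, 2L), 1, 2), matrix(c(4L, 6L), 1, 2))
  expect_equal(nrow(indelSiteFilters(co2)), 1L)
  # 3-bp singleton deletion with support -> kept (only length-1 singletons go)
  co3 <- mk("ATTT", "A", matrix(c(1L, 0L), 1, 2), matrix(c(2L, 0L), 1, 2))
  expect_equal(nrow(indelSiteFilters(co3)), 1L)
  # no sample reaches 2 variant reads -> removed
  co4 <- mk("ATTT", "A", matrix(c(1L, 1L), 1, 2), matrix(c(1L, 1L), 1, 2))
  expect_equal(nrow(indelSiteFilters(co4)), 0L)
})
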