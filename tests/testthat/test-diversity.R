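test_that("callable mask counts chromosomes meeting the depth floor", {
  expect_true(callableMask(matrix(12L, 1, 60)))        # 120 chromosomes
  d <- matrix(0L, 1, 60); d[1, 1:45] <- 12L
  expect_false(callableMask(d))                        # 90 < 100
  set.seed(3)
  dd <- matrix(sample(0:30, 500 * 55, replace = TRUE), 500, 55)
  oracle <- apply(dd, 1, function(r) 2 * sum(r >= 10) >= 100)
  expect_identical(callableMask(dd), oracle)
  expect_error(callableMask(1:10), "dimension")
})

test_that("site heterozygosity equals the differing-pair fraction", {
  expect_equal(siteHet(1, 2), 1)
  expect_equal(siteHet(0, 10), 0)
  expect_equal(siteHet(5, 10), 25 / 45)
  expect_error(siteHet(1, 1), "domain")
  expect_error(siteHet(5, 4), "domain")
})

test_that("per-base heterozygosity divides summed site het by callable bases", {
  # one variant at j=1 of n=2 chromosomes (one het sample) among 10 callable
  # bases -> 0.1
  co <- makeToyCohort(matrix(1L, 1, 1))
  r <- perBaseHet(co, siteClass = "silent", nBases = 10, scale = 1)
  expect_equal(r$het, 0.1)
  expect_equal(r$nSites, 1L)
  # no variants -> 0
  co0 <- makeToyCohort(matrix(c(0L, 0L), 1, 2))
  expect_equal(perBaseHet(co0, nBases = 10, scale = 1)$het, 0)
  # missing genotypes shrink the per-site chromosome count
  co2 <- makeToyCohort(matrix(c(1L, 0L, NA), 1, 3))
  r2 <- perBaseHet(co2, nBases = 1, scale = 1)
  expect_equal(r2$het, siteHet(1, 4))
  # the reporting scale defaults to 1e4
  expect_equal(perBaseHet(co, nBases = 10)$het, 1000)
  expect_error(perBaseHet(co, nBases = 0), "zero callable")
})

test_that("AFS construction polarizes by the ancestral allele and folds minor alleles", {
  geno <- rbind(c(1L, 1L, 1L, 0L, 0L),    # AC 3 of 10
                c(1L, 1L, 1L, 0L, 0L),    # AC 3, ancestral = alt -> derived 7
                c(2L, 2L, 2L, 1L, 0L))    # AC 7 -> minor 3 when folded
  co <- makeToyCohort(geno, ancestral = c("A", "G", "A"))
  afs <- buildAFS(co, polarize = TRUE)
  expect_equal(chromosomeCount(afs), 10L)
  expect_equal(unname(spectrumCounts(afs)[c("3", "7")]), c(1, 2))
  expect_equal(segregatingSites(afs), 3)

  folded <- buildAFS(co, polarize = FALSE)
  expect_equal(unname(spectrumCounts(folded)["3"]), 3)
  expect_equal(sum(spectrumCounts(folded)[as.character(6:10)]), 0)

  # unknown or mismatching ancestral bases are excluded from the unfolded AFS
  co2 <- makeToyCohort(geno, ancestral = c("N", "C", "A"))
  afs2 <- buildAFS(co2, polarize = TRUE)
  expect_equal(segregatingSites(afs2), 1)
  noAnc <- makeToyCohort(geno, ancestral = rep("N", 3))
  expect_error(buildAFS(noAnc, polarize = TRUE), "annotation error")
})

test_that("hypergeometric projection: worked example, identity, mass conservation", {
  # single site with j=2 of n=4, projected to m=2: bins (0,1,2) = (1/6,2/3,1/6)
  afs <- AFSpectrum(4, c(0, 0, 1, 0, 0))
  p <- projectAFS(afs, 2)
  expect_equal(unname(spectrumCounts(p)), c(0, 2 / 3, 0))
  expect_equal(p@lost, c(1 / 6, 1 / 6))
  # m = n is the identity
  pid <- projectAFS(afs, 4)
  expect_equal(spectrumCounts(pid), spectrumCounts(afs))
  # total projected mass (segregating + monomorphic) is conserved
  set.seed(5)
  counts <- c(0, rpois(19, 5), 0)
  big <- AFSpectrum(20, counts)
  for (m in c(3, 7, 12)) {
    pr <- projectAFS(big, m)
    expect_equal(segregatingSites(pr) + sum(pr@lost), sum(counts))
  }
  expect_error(projectAFS(afs, 5), "domain")
})

test_that("Watterson's theta and the neutral expectation are mutually consistent", {
  expect_equal(wattersonTheta(10, 5), 4.8)
  expect_equal(wattersonTheta(0, 7), 0)
  expect_equal(wattersonTheta(3, 2), 3)        # harmonic sum = 1
  expect_error(wattersonTheta(3, 1), "domain")

  ne <- neutralExpectation(6, 4)
  expect_equal(unname(spectrumCounts(ne)), c(0, 6, 3, 2, 0))
  # log-log slope is -1 by construction
  n <- 30; th <- 11
  e <- spectrumCounts(neutralExpectation(th, n))[as.character(1:(n - 1))]
  fit <- lm(log(e) ~ log(1:(n - 1)))
  expect_equal(unname(coef(fit)[2]), -1)
  # sum of expected counts inverts to the input theta
  expect_equal(wattersonTheta(sum(e), n), th)
})

test_that("fraction of sites per AF bin matches a direct count and tracks known status", {
  set.seed(9)
  af <- runif(400)
  known <- runif(400) < 0.5
  fb <- fractionInBins(af = af, known = known, breaks = c(0, 0.01, 0.1, 1))
  expect_equal(sum(fb$fraction), 1)
  expect_equal(fb$n[1], sum(af < 0.01))
  expect_equal(fb$n[2], sum(af >= 0.01 & af < 0.1))
  expect_equal(fb$fractionKnown[3], mean(known[af >= 0.1]))
  # a singleton among 1,394 chromosomes lands in the lowest bin
  fb2 <- fractionInBins(af = 1 / 1394, known = FALSE)
  expect_equal(fb2$n, c(1L, 0L, 0L))
  allKnown <- fractionInBins(af = c(0.005, 0.05, 0.5),
                             known = rep(TRUE, 3))
  expect_true(all(allKnown$fractionKnown[allKnown$n > 0] == 1))
  expect_error(fractionInBins(af = numeric(0)), "undefined")
})
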