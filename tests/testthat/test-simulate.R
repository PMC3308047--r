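test_that("simulateCohort is deterministic under the seed and internally consistent", {
  cfg <- smallConfig(seed = 101L, nSites = c(silent = 150L, missense = 100L),
                     theta = c(silent = 1e-3, missense = 4e-4),
                     fst = 0.05, selectionSkew = 0.5)
  a <- simulateCohort(cfg)
  b <- simulateCohort(cfg)
  expect_identical(assay(a, "genotype"), assay(b, "genotype"))
  expect_identical(assay(a, "depth"), assay(b, "depth"))
  expect_identical(rowRanges(a), rowRanges(b))
  expect_identical(truthInfo(a)$classBases, truthInfo(b)$classBases)

  # dimensions agree with config; every kept site is polymorphic
  expect_equal(nrow(a), sum(cfg@nSites))
  expect_equal(ncol(a), sum(cfg@populations$n))
  cnt <- ExomePopGen:::altAlleleCounts(assay(a, "genotype"))
  expect_true(all(cnt$ac > 0))
  expect_true(all(assay(a, "depth") >= 0))
  # allele-depth decomposition matches total depth
  expect_equal(assay(a, "adRef") + assay(a, "adAlt"), assay(a, "depth"),
               ignore_attr = TRUE)
  # genotypes missing exactly where depth is zero
  expect_true(all(is.na(assay(a, "genotype")[assay(a, "depth") == 0L])))
})

test_that("invalid simulation configs fail naming the offending field", {
  expect_error(smallConfig(1L, fst = 1), "fst")
  expect_error(smallConfig(1L, selectionSkew = 0), "selectionSkew")
  expect_error(smallConfig(1L, nSites = c(silent = 0L)), "nSites")
  expect_error(SimulationConfig(populations = data.frame(
    name = "A", continent = "AFR", n = 0L)), "sample counts")
  expect_error(smallConfig(1L, coverage = list(meanDepth = -1,
                                               targetSdLog = 0.5,
                                               sampleShape = 5)), "meanDepth")
})

test_that("selection skew enriches rare alleles in the selected class", {
  cfg <- SimulationConfig(
    populations = data.frame(name = "P1", continent = "AFR", n = 60L),
    nSites = c(silent = 1000L, missense = 1000L),
    theta = c(silent = 1e-3, missense = 1e-3),
    fst = 0, selectionSkew = 0.25, selectedClasses = "missense", seed = 77L)
  co <- simulateCohort(cfg)
  cnt <- ExomePopGen:::altAlleleCounts(assay(co, "genotype"))
  af <- cnt$ac / cnt$an
  fclass <- mcols(rowRanges(co))$fclass
  rare <- function(k) mean(af[fclass == k] < 0.01)
  expect_gt(rare("missense"), rare("silent"))
})

test_that("simulated depths have the configured mean, shared target effects, and a non-increasing coverage curve", {
  cfg <- smallConfig(8L, coverage = list(meanDepth = 40, targetSdLog = 0.6,
                                         sampleShape = 8))
  d <- simulateDepths(cfg, 400L)
  expect_identical(dim(d), c(400L, 60L))
  expect_lt(abs(mean(d) - 40) / 40, 0.10)
  expect_identical(d, simulateDepths(cfg, 400L))
  # zero variance at both levels: constant at the mean
  cfg0 <- smallConfig(8L, coverage = list(meanDepth = 40, targetSdLog = 0,
                                          sampleShape = Inf))
  expect_true(all(simulateDepths(cfg0, 20L) == 40L))
  # cumulative coverage (fraction of sample-site pairs >= d) is non-increasing
  cc <- vapply(0:200, function(th) mean(d >= th), numeric(1))
  expect_true(all(diff(cc) <= 0))
  # target effects are shared across samples: depth ranks of targets agree
  # between disjoint sample groups
  m1 <- rowMeans(d[, 1:30]); m2 <- rowMeans(d[, 31:60])
  expect_gt(cor(m1, m2, method = "spearman"), 0.8)
})

test_that("genotype corruption hits the requested rates and is deterministic", {
  cfg <- SimulationConfig(
    populations = data.frame(name = "P1", continent = "AFR", n = 80L),
    nSites = c(silent = 1200L), theta = c(silent = 1e-3),
    fst = 0, selectionSkew = 1, seed = 5L)
  co <- simulateCohort(cfg)

  # zero rates: diagonal table, 100% accuracy
  id <- diag(3)
  res0 <- corruptGenotypes(co, id, seed = 3L)
  expect_identical(assay(res0$cohort, "genotype"), assay(co, "genotype"))
  expect_equal(genotypeAccuracy(res0$assay)$overall, 100)

  # het -> hom-ref at 3%: realized fraction within 3 binomial SEs
  rates <- rbind(c(1, 0, 0), c(0.03, 0.97, 0), c(0, 0, 1))
  res <- corruptGenotypes(co, rates, seed = 11L)
  tab <- res$assay@genotypes
  nHet <- sum(tab[, 2])
  frac <- tab[1, 2] / nHet
  expect_gt(nHet, 5000)
  expect_lt(abs(frac - 0.03), 3 * sqrt(0.03 * 0.97 / nHet))

  # deterministic under seed
  res2 <- corruptGenotypes(co, rates, seed = 11L)
  expect_identical(assay(res$cohort, "genotype"), assay(res2$cohort, "genotype"))
  expect_error(corruptGenotypes(co, matrix(2, 3, 3)), "rates")
})
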