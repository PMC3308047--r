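test_that("site sharing probabilities match exact combinatorics", {
  conts <- c(A = "AFR", B = "AFR", C = "EUR")
  expect_equal(siteSharing(c(A = 2), conts),
               c(same = 1, cont = 0, diff = 0))
  expect_equal(siteSharing(c(A = 1, B = 1), conts),
               c(same = 0, cont = 1, diff = 0))
  expect_equal(siteSharing(c(A = 2, C = 1), conts),
               c(same = 1 / 3, cont = 0, diff = 2 / 3))
  expect_error(siteSharing(c(A = 1), conts), "[Ss]ingleton")
  # always a distribution
  s <- siteSharing(c(A = 3, B = 2, C = 4), conts)
  expect_equal(sum(s), 1, tolerance = 1e-12)
})

test_that("panmictic expectation depends only on sample sizes", {
  conts <- c(A = "AFR", B = "AFR", C = "EUR")
  expect_equal(panmicticExpectation(c(A = 2, B = 2), conts),
               c(same = 1 / 3, cont = 2 / 3, diff = 0))
  expect_equal(panmicticExpectation(c(A = 7), conts),
               c(same = 1, cont = 0, diff = 0))
  # equal sizes across k populations on one continent: p_same -> 1/k
  k <- 4
  conts4 <- setNames(rep("AFR", k), paste0("P", 1:k))
  big <- panmicticExpectation(setNames(rep(5000, k), paste0("P", 1:k)), conts4)
  expect_equal(unname(big["same"]), 1 / k, tolerance = 1e-3)
})

test_that("down-sampling to the full panel equals the unweighted mean of site sharing", {
  cfg <- smallConfig(33L, nSites = c(silent = 120L))
  co <- simulateCohort(cfg)
  # restrict to sites with complete data so the full-panel reduction is exact
  g <- assay(co, "genotype")
  co <- co[rowSums(is.na(g)) == 0, ]
  cd <- colData(co)
  conts <- setNames(cd$continent[!duplicated(cd$population)],
                    cd$population[!duplicated(cd$population)])
  m <- setNames(2L * as.integer(table(cd$population)[names(conts)]),
                names(conts))
  est <- downsampledSharing(co, DownsampleSpec(m, seed = 1L),
                            bins = c(0, 0.5), B = 100L)
  tab <- sharingTable(est)

  g <- assay(co, "genotype")
  perSite <- t(vapply(seq_len(nrow(co)), function(i) {
    cp <- vapply(names(conts), function(p)
      sum(g[i, cd$population == p]), numeric(1))
    cp <- if (sum(cp) <= sum(m) / 2) cp else m - cp
    if (sum(cp) < 2) return(c(NA, NA, NA))
    unname(siteSharing(cp[cp >= 0], conts))
  }, numeric(3)))
  manual <- colMeans(perSite, na.rm = TRUE)
  expect_equal(tab$estimate, unname(manual), tolerance = 1e-10)
  expect_equal(tab$nSites[1], sum(!is.na(perSite[, 1])))
})

test_that("single-site down-sampling weight equals the hypergeometric survival probability", {
  # one population, 2 minor alleles of 4 chromosomes, down-sampled to 2:
  # P(both minor alleles survive) = C(2,2)C(2,0)/C(4,2) = 1/6, conditional
  # sharing = 1
  spec <- DownsampleSpec(c(P1 = 2L), seed = 4L)
  cp <- c(P1 = 2); np <- c(P1 = 4)
  res <- ExomePopGen:::.siteDownsampled(cp, np, c(P1 = 2L),
                                        factor("AFR"), spec)
  expect_equal(res$w, choose(2, 2) * choose(2, 0) / choose(4, 2))
  expect_equal(unname(res$a["same"] / res$w), 1)
})

test_that("bootstrap CIs collapse on identical sites and are seed-deterministic", {
  a <- matrix(rep(c(0.2, 0.3, 0.5), each = 50), 50, 3)
  w <- rep(1, 50)
  ci <- bootstrapRatioCI(a, w, B = 200L, seed = 7L)
  expect_equal(ci[, 1], ci[, 2])
  expect_equal(ci[1, 1], 0.2)
  b <- matrix(runif(150), 50, 3)
  expect_identical(bootstrapRatioCI(b, w, B = 200L, seed = 7L),
                   bootstrapRatioCI(b, w, B = 200L, seed = 7L))
  expect_error(bootstrapRatioCI(a, w, B = 10L), "B >= 100")
  expect_error(bootstrapRatioCI(a[1, , drop = FALSE], w[1], B = 200L),
               "fewer than 2")
})

test_that("raising divergence lowers rare-variant sharing across continents", {
  fsts <- c(0, 0.15)
  diffRare <- vapply(fsts, function(f) {
    co <- simulateCohort(smallConfig(55L, fst = f,
                                     nSites = c(silent = 250L),
                                     populations = data.frame(
                                       name = c("A1", "B1"),
                                       continent = c("AFR", "EUR"),
                                       n = c(40L, 40L))))
    m <- c(A1 = 70L, B1 = 70L)
    est <- downsampledSharing(co, DownsampleSpec(m, seed = 2L),
                              bins = c(0, 0.05, 0.5), B = 100L)
    tab <- sharingTable(est)
    tab$estimate[tab$category == "diff" & tab$bin == "[0,0.05)"]
  }, numeric(1))
  expect_gt(diffRare[1], diffRare[2])
})
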