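test_that("IBS kinship scores allele sharing as specified", {
  gm <- gmFromCalls(rbind(c("A/A", "A/B"),
                          c("A/A", "A/A"),
                          c("B/B", "C/C")))
  K <- ibsKinship(gm)
  expect_equal(diag(K), rep(1, 3), ignore_attr = TRUE)
  expect_equal(K[1, 2], (1 + 0.5) / 2)   # identical + one shared allele
  expect_equal(K[2, 3], 0)               # opposite homozygotes at both loci
  expect_true(isSymmetric(K))
  # identical individuals
  gm2 <- gmFromCalls(rbind(c("1/2", "3/3"), c("1/2", "3/3")))
  expect_equal(ibsKinship(gm2)[1, 2], 1)
  # unordered pairs: "2/1" is the same genotype as "1/2"
  gm3 <- gmFromCalls(rbind(c("1/2", "1/1"), c("2/1", "1/1")))
  expect_equal(ibsKinship(gm3)[1, 2], 1)
  gmBad <- gmFromCalls(rbind(c("1/1", NA), c(NA, "2/2")))
  expect_error(ibsKinship(gmBad), "undefined")
})

test_that("a perfect predictor yields PVE ~ 100 and vanishing p", {
  set.seed(61)
  calls <- matrix(sample(c("1/1", "1/2", "2/2"), 40, TRUE), 40, 1)
  gm <- gmFromCalls(calls)
  codes <- c(`1/1` = 0, `1/2` = 1, `2/2` = 2)
  trait <- codes[calls[, 1]] + 5
  names(trait) <- individuals(gm)
  res <- glmScan(gm, trait)
  expect_equal(res$PVE, 100, tolerance = 1e-6)
  expect_lt(res$p_value, 1e-10)
})

test_that("GLM type-I error is calibrated under the null", {
  set.seed(62)
  n <- 100
  calls <- matrix(sample(c("1/1", "1/2", "2/2"), n * 60, TRUE,
                         prob = c(0.25, 0.5, 0.25)), n, 60)
  gm <- gmFromCalls(calls)
  pvals <- unlist(lapply(1:10, function(r) {
    trait <- rnorm(n)
    glmScan(gm, trait)$p_value
  }))
  frac <- mean(pvals < 0.05)
  expect_gte(frac, 0.03)
  expect_lte(frac, 0.07)
  # approximate uniformity of the null p-value distribution
  ks <- suppressWarnings(stats::ks.test(pvals, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("structure covariates attenuate confounded markers", {
  set.seed(63)
  sim <- plantedTwoPops(nPerPop = 25, nLoci = 20, pHigh = 0.85, seed = 64)
  gm <- sim$genotypes
  # phenotype driven by population membership, not by any marker
  trait <- sim$pop + rnorm(50, sd = 0.5)
  names(trait) <- individuals(gm)
  Q <- cbind(pop1 = as.numeric(sim$pop == 1), pop2 = as.numeric(sim$pop == 2))
  noQ <- glmScan(gm, trait)
  withQ <- glmScan(gm, trait, Q = Q)
  shared <- intersect(noQ$marker, withQ$marker)
  expect_gt(median(withQ$p_value[match(shared, withQ$marker)]),
            median(noQ$p_value[match(shared, noQ$marker)]))
  # partial-R2 monotonicity on this fixture: dropping the covariate
  # never lowers a marker's PVE
  expect_true(all(noQ$PVE[match(shared, noQ$marker)] >=
                  withQ$PVE[match(shared, withQ$marker)] - 1e-9))
})

test_that("MLM with identity kinship collapses to the GLM", {
  set.seed(65)
  sim <- generateStructuredGenotypes(nIndividuals = 30, nLoci = 15, K = 2,
                                     missingRate = 0.05, seed = 66)
  gm <- sim$genotypes
  trait <- rnorm(30) + rowSums(sim$Q)
  names(trait) <- individuals(gm)
  g <- glmScan(gm, trait)
  m <- mlmScan(gm, trait, kinship = diag(30))
  expect_equal(m$p_value, g$p_value, tolerance = 1e-6)
  expect_equal(m$PVE, g$PVE, tolerance = 1e-6)
})

test_that("MLM controls structured confounding better than GLM", {
  set.seed(67)
  sim <- plantedTwoPops(nPerPop = 30, nLoci = 40, pHigh = 0.85, seed = 68)
  gm <- sim$genotypes
  K <- ibsKinship(gm)
  # polygenic phenotype: covariance proportional to 2K, no causal marker
  L <- chol(2 * K + diag(1e-6, 60))
  fracs <- sapply(1:3, function(r) {
    trait <- drop(t(L) %*% rnorm(60)) + rnorm(60, sd = 0.3)
    names(trait) <- individuals(gm)
    c(glm = mean(glmScan(gm, trait)$p_value < 0.05),
      mlm = mean(mlmScan(gm, trait, kinship = K)$p_value < 0.05))
  })
  glmFrac <- mean(fracs["glm", ]); mlmFrac <- mean(fracs["mlm", ])
  expect_lt(abs(mlmFrac - 0.05), abs(glmFrac - 0.05) + 1e-9)
})

test_that("a strong planted effect is recovered and ranked first", {
  sim <- generateStructuredGenotypes(nIndividuals = 100, nLoci = 50, K = 1,
                                     alpha = 1, F = 0.3, missingRate = 0,
                                     seed = 69)
  gm <- sim$genotypes
  ph <- generatePhenotype(gm, c(m010 = 1), h2 = 0.3, seed = 70)
  # chance-monomorphic markers are skipped with a warning by design
  res <- suppressWarnings(glmScan(gm, ph$trait))
  best <- res$marker[which.min(res$p_value)]
  expect_equal(best, "m010")
  pve <- res$PVE[res$marker == "m010"]
  expect_lt(abs(pve - 30), 10)
})

test_that("trait encodings map categories to ordinal codes", {
  codes <- traitCodes()
  expect_equal(unname(encodeTrait(c("white", "green", "dark green"),
                                  codes$peel_color)), c(0, 2, 3))
  expect_equal(unname(encodeTrait(c("none", "very low"), codes$spine)),
               c(0, 1))
  expect_error(encodeTrait("purple", codes$peel_color), "unknown")
})
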