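test_that("planted SSRs are recovered exactly; sub-threshold plants are not", {
  planted <- data.frame(
    seq_id = c("chr1", "chr1", "chr1", "chr2"),
    pos = c(2001, 5001, 8001, 3001),
    motif = c("A", "AT", "AAT", "AG"),
    repeats = c(12, 7, 6, 9))
  g <- generateGenome(c(chr1 = 20000L, chr2 = 10000L), gc = 0.45,
                      planted = planted, seed = 7)
  mined <- mineSSRs(g$sequences)
  md <- data.frame(seqid = as.character(GenomicRanges::seqnames(mined)),
                   start = BiocGenerics::start(mined),
                   end = BiocGenerics::end(mined),
                   motif_class = mined$motif_class,
                   repeats = mined$repeats)
  for (r in seq_len(nrow(g$truth))) {
    hit <- md[md$seqid == g$truth$seq_id[r] &
              md$start == g$truth$start[r] &
              md$end == g$truth$end[r], , drop = FALSE]
    expect_equal(nrow(hit), 1)
    expect_equal(hit$motif_class, g$truth$motif_class[r])
    expect_equal(hit$repeats, g$truth$repeats[r])
  }

  # one repeat below threshold: never reported at the planted site
  below <- data.frame(seq_id = "chr1", pos = 2001, motif = "A", repeats = 9)
  g2 <- generateGenome(c(chr1 = 6000L), planted = below, seed = 8)
  mined2 <- findSSRs(as.character(g2$sequences[[1]]), "chr1")
  expect_false(any(mined2$start <= 2009 & mined2$end >= 2001 &
                   mined2$period == 1))
})

test_that("genome generation is byte-reproducible and validates placement", {
  spec <- data.frame(seq_id = "chr1", pos = 501, motif = "AT", repeats = 8)
  a <- generateGenome(c(chr1 = 2000L), planted = spec, seed = 12)
  b <- generateGenome(c(chr1 = 2000L), planted = spec, seed = 12)
  expect_identical(as.character(a$sequences), as.character(b$sequences))
  cc <- generateGenome(c(chr1 = 2000L), planted = spec, seed = 13)
  expect_false(identical(as.character(a$sequences),
                         as.character(cc$sequences)))
  crowded <- data.frame(seq_id = "chr1", pos = c(501, 530),
                        motif = c("A", "AT"), repeats = c(12, 8))
  expect_error(generateGenome(c(chr1 = 2000L), planted = crowded, seed = 1),
               "placement")
})

test_that("structured genotypes follow the admixture generative model", {
  # near-zero alpha: assignments are essentially hard
  sim <- generateStructuredGenotypes(nIndividuals = 200, nLoci = 10, K = 2,
                                     alpha = 0.01, seed = 31)
  expect_gt(mean(apply(sim$Q, 1, max) > 0.99), 0.95)
  # fully diverged frequencies identify the population of every genotype
  freqs <- replicate(8, rbind(c(1, 0), c(0, 1)), simplify = FALSE)
  sim2 <- generateStructuredGenotypes(nIndividuals = 20, nLoci = 8, K = 2,
                                      alpha = 0.01, freqs = freqs,
                                      missingRate = 0, seed = 32)
  pop <- apply(sim2$Q, 1, which.max)
  calls <- genotypeCalls(sim2$genotypes)
  expect_true(all(calls[pop == 1, ] == "1/1"))
  expect_true(all(calls[pop == 2, ] == "2/2"))
  # determinism
  sim3 <- generateStructuredGenotypes(nIndividuals = 20, nLoci = 8, K = 2,
                                      alpha = 0.01, freqs = freqs,
                                      missingRate = 0, seed = 32)
  expect_identical(genotypeCalls(sim2$genotypes),
                   genotypeCalls(sim3$genotypes))
})

test_that("population divergence grows with F", {
  meanDiff <- function(F) {
    mean(vapply(1:6, function(seed) {
      sim <- generateStructuredGenotypes(nIndividuals = 2, nLoci = 40,
                                         K = 2, F = F, nAlleles = 2,
                                         missingRate = 0, seed = seed)
      mean(vapply(sim$freqs, function(P) abs(P[1, 1] - P[2, 1]), 0))
    }, 0))
  }
  expect_lt(meanDiff(0.05), meanDiff(0.5))
})

test_that("phenotypes hit their target heritability", {
  sim <- generateStructuredGenotypes(nIndividuals = 500, nLoci = 10, K = 1,
                                     missingRate = 0, seed = 41)
  gm <- sim$genotypes
  # zero noise: exact linear function of the dosage codes
  ph0 <- generatePhenotype(gm, c(m003 = 2), noiseVar = 0, seed = 42)
  ac <- alleleCalls(gm, "m003")
  ref <- sort(unique(c(ac)))[1]
  dos <- (ac[, 1] == ref) + (ac[, 2] == ref)
  expect_equal(unname(ph0$trait), unname(2 * dos))

  # realized heritability concentrates around the target
  h2s <- vapply(1:20, function(s)
    generatePhenotype(gm, c(m003 = 1), h2 = 0.5, seed = s)$h2Realized,
    0)
  expect_lt(abs(mean(h2s) - 0.5), 0.05)

  # determinism
  pa <- generatePhenotype(gm, c(m003 = 1), h2 = 0.5, seed = 77)
  pb <- generatePhenotype(gm, c(m003 = 1), h2 = 0.5, seed = 77)
  expect_identical(pa$trait, pb$trait)
  expect_error(generatePhenotype(gm, c(nope = 1), h2 = 0.5), "exist")
})
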