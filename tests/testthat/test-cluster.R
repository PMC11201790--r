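test_that("band coefficients match hand counts", {
  # bands: locus1 alleles {1,2}, locus2 alleles {1,2}
  # ind1: 1/1 and 1/2 -> bands (1,0,1,1); ind2: 1/2 and 2/2 -> (1,1,0,1)
  gm <- gmFromCalls(rbind(c("1/1", "1/2"), c("1/2", "2/2")))
  bands <- alleleBands(gm)
  expect_equal(unname(bands[1, ]), c(1, 0, 1, 1))
  expect_equal(unname(bands[2, ]), c(1, 1, 0, 1))
  dSM <- similarityMatrix(gm, "simple_matching")
  expect_equal(dSM[1, 2], 1 - 2 / 4)
  dDice <- similarityMatrix(gm, "dice")
  expect_equal(dDice[1, 2], 1 - 2 * 2 / (2 * 2 + 1 + 1), tolerance = 1e-12)
  dJac <- similarityMatrix(gm, "jaccard")
  expect_equal(dJac[1, 2], 1 - 2 / 4)
  # identical individuals at distance zero
  gm2 <- gmFromCalls(rbind(c("1/2", "2/2"), c("1/2", "2/2")))
  expect_equal(similarityMatrix(gm2)[1, 2], 0)
})

test_that("all-missing individuals are dropped with a warning", {
  gm <- gmFromCalls(rbind(c("1/1", "1/2"), c(NA, NA), c("1/2", "2/2")))
  expect_warning(d <- similarityMatrix(gm), "all-missing")
  expect_equal(nrow(d), 2)
})

test_that("UPGMA reproduces forced geometries", {
  d2 <- matrix(c(0, 0.4, 0.4, 0), 2,
               dimnames = list(c("A", "B"), c("A", "B")))
  expect_equal(upgma(d2)$newick, "(A:0.2,B:0.2);")

  d3 <- matrix(c(0, 2, 4, 2, 0, 4, 4, 4, 0), 3,
               dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  tr <- upgma(d3)
  expect_equal(tr$newick, "((A:1,B:1):1,C:2);")
  expect_equal(sort(tr$height), c(1, 2))
  # ultrametric input is reproduced exactly
  expect_equal(tr$cophenetic, d3, tolerance = 1e-12)
  expect_error(upgma(matrix(c(0, NA, NA, 0), 2)), "NaN|NA")
})

test_that("UPGMA agrees with hclust average linkage on random inputs", {
  set.seed(31)
  for (i in 1:10) {
    n <- sample(4:9, 1)
    x <- matrix(rnorm(n * 3), n)
    rownames(x) <- paste0("t", seq_len(n))
    d <- as.matrix(dist(x))
    tr <- upgma(d)
    hc <- hclust(as.dist(d), method = "average")
    expect_equal(sort(tr$height * 2), sort(hc$height), tolerance = 1e-9)
    expect_equal(tr$cophenetic[rownames(d), rownames(d)],
                 as.matrix(cophenetic(hc))[rownames(d), rownames(d)],
                 tolerance = 1e-9)
  }
})

test_that("UPGMA heights never decrease and relabeling permutes cleanly", {
  set.seed(32)
  x <- matrix(rnorm(18), 6)
  rownames(x) <- paste0("t", 1:6)
  d <- as.matrix(dist(x))
  tr <- upgma(d)
  expect_true(!is.unsorted(tr$height))
  perm <- sample(6)
  dp <- d[perm, perm]
  trp <- upgma(dp)
  expect_equal(trp$cophenetic[rownames(d), rownames(d)], tr$cophenetic,
               tolerance = 1e-12)
  # Newick parses to the same topology (checked via ape)
  t1 <- ape::read.tree(text = tr$newick)
  t2 <- ape::read.tree(text = trp$newick)
  expect_equal(suppressWarnings(ape::dist.topo(t1, t2))[1], 0)
})

test_that("PCoA recovers planted configurations", {
  # collinear points: one axis carries everything
  d <- as.matrix(dist(cbind(c(1, 2, 3, 4), 0)))
  rownames(d) <- colnames(d) <- paste0("p", 1:4)
  res <- pcoa(d)
  expect_equal(length(res$percentExplained), 1)
  expect_equal(res$percentExplained[1], 100)

  # a known 2-D point set: variance shares match the coordinates'
  set.seed(41)
  pts <- cbind(rnorm(12, sd = 3), rnorm(12, sd = 1))
  pts <- scale(pts, scale = FALSE)
  pts <- pts %*% svd(pts)$v   # align to principal axes
  d2 <- as.matrix(dist(pts))
  res2 <- pcoa(d2)
  expect_equal(sum(res2$percentExplained), 100)
  share <- 100 * apply(pts, 2, function(c) sum(c^2)) /
    sum(pts^2)
  expect_equal(res2$percentExplained[1:2], share, tolerance = 1e-6)
  # distances reconstructed from all positive axes equal the input
  rec <- as.matrix(dist(res2$coordinates))
  expect_equal(unname(rec), unname(d2), tolerance = 1e-8)
  # agreement with the classical scaling reference
  cs <- cmdscale(d2, k = 2, eig = TRUE)
  expect_equal(abs(res2$coordinates[, 1:2]), abs(cs$points),
               tolerance = 1e-8, ignore_attr = TRUE)
  expect_error(pcoa(matrix(c(0, 1, 2, 0), 2, 2)), "symmetric|3")
})

test_that("two planted populations separate in tree and ordination", {
  hits <- 0
  for (seed in 1:10) {
    sim <- plantedTwoPops(nPerPop = 8, nLoci = 25, pHigh = 0.9, seed = seed)
    d <- similarityMatrix(sim$genotypes)
    tr <- upgma(d)
    # root bipartition = the two-cluster cut of the ultrametric tree
    cut2 <- stats::cutree(structure(tr$hclust, class = "hclust"), k = 2)
    treeOK <- length(unique(sim$pop[cut2 == 1])) == 1 &&
      length(unique(sim$pop[cut2 == 2])) == 1
    ax1 <- pcoa(d)$coordinates[, 1]
    pcoaOK <- length(unique(sign(ax1)[sim$pop == 1])) == 1 &&
      length(unique(sign(ax1)[sim$pop == 2])) == 1
    if (treeOK && pcoaOK) hits <- hits + 1
  }
  expect_gte(hits, 9)
})
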