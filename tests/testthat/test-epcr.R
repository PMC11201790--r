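makeTarget <- function(seed = 21, n = 400) {
  set.seed(seed)
  randomDNA(n, gc = 0.5)
}

# a pair whose perfect placement spans target[101..250] (150 bp product)
perfectPair <- function(target) {
  list(marker_id = "mk1",
       left_seq = substr(target, 101, 120),
       right_seq = revcompStr(substr(target, 231, 250)))
}

mutateAt <- function(s, pos) {
  old <- substr(s, pos, pos)
  new <- setdiff(c("A", "C", "G", "T"), old)[1]
  paste0(substr(s, 1, pos - 1), new, substr(s, pos + 1, nchar(s)))
}

test_that("a perfectly matching pair yields exactly one amplicon", {
  target <- makeTarget()
  amp <- epcr(perfectPair(target), target, "t1")
  expect_equal(nrow(amp), 1)
  expect_equal(amp$start, 101)
  expect_equal(amp$end, 250)
  expect_equal(amp$product_bp, 150)
  expect_equal(amp$left_mismatches, 0)
  expect_equal(amp$right_mismatches, 0)
  expect_equal(amp$strand, "+")
  # the pair also amplifies the reverse complement of the target
  rc <- epcr(perfectPair(target), revcompStr(target), "t1rc")
  expect_equal(nrow(rc), 1)
  expect_equal(rc$product_bp, 150)
  expect_equal(rc$strand, "-")
})

test_that("any mismatch inside the 3' anchor kills the amplicon", {
  target <- makeTarget()
  pair <- perfectPair(target)
  # left primer 3' end maps to target positions 116..120
  for (pos in c(116, 118, 120)) {
    expect_equal(nrow(epcr(pair, mutateAt(target, pos), "t1")), 0)
  }
  # right primer 3' anchor maps to target positions 231..235
  expect_equal(nrow(epcr(pair, mutateAt(target, 233), "t1")), 0)
})

test_that("5' mismatch and identity limits are enforced per primer", {
  target <- makeTarget()
  pair <- perfectPair(target)
  # six substitutions in the left primer's 5' region: rejected even with
  # the identity rule relaxed (the 5'-mismatch cap decides)
  relaxed <- matchRules(minIdentity = 0.5)
  t6 <- target
  for (pos in 101:106) t6 <- mutateAt(t6, pos)
  expect_equal(nrow(epcr(pair, t6, "t1", relaxed)), 0)
  t5 <- target
  for (pos in 101:105) t5 <- mutateAt(t5, pos)
  expect_equal(nrow(epcr(pair, t5, "t1", relaxed)), 1)
  expect_equal(epcr(pair, t5, "t1", relaxed)$left_mismatches, 5)
  # under default rules six substitutions are rejected too
  expect_equal(nrow(epcr(pair, t6, "t1")), 0)

  # identity: an 18-mer with 2 mismatches is 16/18 = 88.9% < 90%
  pair18 <- list(marker_id = "mk2",
                 left_seq = substr(target, 101, 118),
                 right_seq = revcompStr(substr(target, 231, 250)))
  t2 <- mutateAt(mutateAt(target, 101), 103)
  expect_equal(nrow(epcr(pair18, t2, "t1")), 0)
  # one mismatch (17/18 = 94.4%) passes
  expect_equal(nrow(epcr(pair18, mutateAt(target, 101), "t1")), 1)
})

test_that("loosening any rule never removes an amplicon", {
  target <- makeTarget(22)
  pair <- perfectPair(target)
  t3 <- mutateAt(mutateAt(mutateAt(target, 102), 104), 237)
  key <- function(df) paste(df$start, df$end, df$strand)
  strictSets <- list(
    matchRules(max5primeMismatches = 1),
    matchRules(minIdentity = 0.95),
    matchRules(threePrimeAnchorBp = 10),
    matchRules(maxProductBp = 120))
  loose <- epcr(pair, t3, "t1", matchRules(minIdentity = 0.8))
  for (rules in strictSets) {
    expect_true(all(key(epcr(pair, t3, "t1", rules)) %in% key(loose)))
  }
})

test_that("synteny links apply scaffold and duplicate filters", {
  src <- data.frame(marker_id = c("m1", "m2", "m3"),
                    seqid = c("chr1", "chr1", "chr2"),
                    start = c(100, 5000, 300), end = c(130, 5030, 340))
  amp <- function(mk, tid, start, mm = 0)
    data.frame(marker_id = mk, target_seq_id = tid, start = start,
               end = start + 149, strand = "+", product_bp = 150,
               left_mismatches = mm, right_mismatches = 0)
  # all hits on a scaffold: zero links
  res <- buildSyntenyLinks(rbind(amp("m1", "scaffold_12", 10),
                                 amp("m1", "scaffold_12", 900),
                                 amp("m1", "scaffold_12", 2000)), src)
  expect_equal(nrow(res$links), 0)
  # duplicates on one chromosome collapse to the best placement
  res <- buildSyntenyLinks(rbind(amp("m1", "tChr03", 500, mm = 2),
                                 amp("m1", "tChr03", 100, mm = 0),
                                 amp("m1", "tChr05", 900)), src)
  expect_equal(nrow(res$links), 2)
  expect_equal(res$links$target_start[res$links$target_chr == "tChr03"], 100)
  # chromosome-pair counting
  res <- buildSyntenyLinks(rbind(amp("m1", "tA", 10), amp("m2", "tA", 50),
                                 amp("m3", "tB", 70)), src)
  pc <- res$pairCounts
  expect_equal(pc$n_links[pc$source_chr == "chr1" & pc$target_chr == "tA"], 2)
  expect_equal(pc$n_links[pc$source_chr == "chr2" & pc$target_chr == "tB"], 1)
  expect_error(buildSyntenyLinks(amp("mX", "tA", 10), src), "consistency")
})

test_that("transfer rate decays with target divergence", {
  set.seed(33)
  source <- randomDNA(5000, gc = 0.5)
  starts <- seq(100, 4500, by = 370)[1:12]
  primers <- do.call(rbind, lapply(seq_along(starts), function(i) {
    s <- starts[i]
    data.frame(marker_id = paste0("m", i),
               left_seq = substr(source, s, s + 19),
               right_seq = revcompStr(substr(source, s + 130, s + 149)),
               stringsAsFactors = FALSE)
  }))
  mutate <- function(s, eps) {
    ch <- strsplit(s, "")[[1]]
    hit <- runif(length(ch)) < eps
    ch[hit] <- vapply(ch[hit], function(b)
      sample(setdiff(c("A", "C", "G", "T"), b), 1), "")
    paste(ch, collapse = "")
  }
  frac <- vapply(c(0, 0.04, 0.15), function(eps) {
    amp <- epcrGenome(primers, c(t1 = mutate(source, eps)))
    length(unique(amp$marker_id)) / nrow(primers)
  }, 0)
  expect_equal(frac[1], 1)
  expect_true(all(diff(frac) <= 0))
  expect_lt(frac[3], frac[1])
})
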