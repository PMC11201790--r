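# small genotype matrices built in code
gmFromCalls <- function(calls, inds = NULL, mks = NULL) {
  if (is.null(inds)) inds <- sprintf("ind%02d", seq_len(nrow(calls)))
  if (is.null(mks)) mks <- sprintf("m%02d", seq_len(ncol(calls)))
  dimnames(calls) <- list(inds, mks)
  genotypeMatrix(calls)
}

# random frequency vector over k alleles
.rfreq <- function(k) {
  x <- rgamma(k, 1)
  x / sum(x)
}

# random diploid calls from given allele frequencies (single locus)
randomLocusCalls <- function(n, p) {
  a <- replicate(n, sample.int(length(p), 2, replace = TRUE, prob = p))
  apply(a, 2, function(x) paste(sort(x), collapse = "/"))
}

# the planted two-population panel used for admixture checks:
# nPerPop individuals per population, biallelic loci with frequencies
# pHigh in population 1 and 1 - pHigh in population 2, no admixture
plantedTwoPops <- function(nPerPop = 20, nLoci = 30, pHigh = 0.9,
                           seed = 1) {
  freqs <- replicate(nLoci, rbind(c(pHigh, 1 - pHigh),
                                  c(1 - pHigh, pHigh)), simplify = FALSE)
  set.seed(seed)
  calls <- matrix(NA_character_, 2 * nPerPop, nLoci)
  popOf <- rep(1:2, each = nPerPop)
  for (i in seq_len(2 * nPerPop)) {
    for (l in seq_len(nLoci)) {
      a <- sample.int(2, 2, replace = TRUE, prob = freqs[[l]][popOf[i], ])
      calls[i, l] <- paste(sort(a), collapse = "/")
    }
  }
  list(genotypes = gmFromCalls(calls), pop = popOf)
}
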