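# Dirichlet draws, one row per observation
.rdirichlet <- function(n, shape) {
  k <- length(shape)
  x <- matrix(rgamma(n * k, shape = rep(shape, each = n)), n, k)
  x <- pmax(x, 1e-300)
  x / rowSums(x)
}

#' Generate a genome with planted SSR truth
#'
#' Background bases are sampled i.i.d. at the requested GC fraction;
#' planted perfect repeat arrays are inserted verbatim at their stated
#' positions.  A flanking base that would extend a planted array (left:
#' `s[pos-1] == s[pos+p-1]`; right: `s[end+1] == s[end+1-p]`) is replaced,
#' so planted coordinates are exactly the maximal-array coordinates.
#' Deterministic under `seed`.  Background repeats can still arise by
#' chance, so recovery comparisons should score planted loci, not assume
#' the truth table is exhaustive.
#'
#' @param lengths named integer vector of sequence lengths (bp).
#' @param gc background GC fraction.
#' @param planted data.frame with columns seq_id, pos (1-based start),
#'   motif, repeats.  Arrays must not overlap and must be separated by at
#'   least 50 bp on a sequence.
#' @param scaffoldIds subset of `names(lengths)` flagged as scaffolds in
#'   the truth table.
#' @param seed RNG seed.
#' @return list: `sequences` ([Biostrings::DNAStringSet-class]), `truth`
#'   (data.frame seq_id, start, end, motif, motif_class, period, repeats,
#'   is_scaffold).
#' @export
generateGenome <- function(lengths, gc = 0.35, planted = NULL,
                           scaffoldIds = character(), seed = 1L) {
  if (is.null(names(lengths)) || anyDuplicated(names(lengths)))
    stop("lengths must carry unique sequence names")
  set.seed(seed)
  probs <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  seqsChr <- lapply(lengths, function(L)
    sample(names(probs), L, replace = TRUE, prob = probs))

  truth <- NULL
  if (!is.null(planted) && nrow(planted) > 0) {
    planted$motif <- toupper(planted$motif)
    planted$period <- nchar(planted$motif)
    planted$end <- planted$pos + planted$period * planted$repeats - 1L
    for (id in unique(planted$seq_id)) {
      if (!id %in% names(lengths)) stop("unknown sequence: ", id)
      pl <- planted[planted$seq_id == id, , drop = FALSE]
      pl <- pl[order(pl$pos), , drop = FALSE]
      if (any(pl$pos < 2L) || any(pl$end > lengths[[id]] - 1L))
        stop("placement error: array outside ", id, " (1 bp margin needed)")
      if (nrow(pl) > 1 && any(pl$pos[-1] - pl$end[-nrow(pl)] <= 50L))
        stop("placement error: planted arrays on ", id,
             " overlap or sit closer than 50 bp")
      s <- seqsChr[[id]]
      for (r in seq_len(nrow(pl))) {
        arr <- strsplit(strrep(pl$motif[r], pl$repeats[r]), "")[[1]]
        s[pl$pos[r]:pl$end[r]] <- arr
        p <- pl$period[r]
        # break accidental periodic extension into the flanks
        if (s[pl$pos[r] - 1L] == s[pl$pos[r] + p - 1L])
          s[pl$pos[r] - 1L] <- setdiff(c("A", "C", "G", "T"),
                                       s[pl$pos[r] + p - 1L])[1]
        if (s[pl$end[r] + 1L] == s[pl$end[r] + 1L - p])
          s[pl$end[r] + 1L] <- setdiff(c("A", "C", "G", "T"),
                                       s[pl$end[r] + 1L - p])[1]
      }
      seqsChr[[id]] <- s
    }
    truth <- data.frame(
      seq_id = planted$seq_id, start = planted$pos, end = planted$end,
      motif = planted$motif,
      motif_class = canonicalMotif(planted$motif),
      period = planted$period, repeats = planted$repeats,
      is_scaffold = planted$seq_id %in% scaffoldIds,
      stringsAsFactors = FALSE)
  }
  seqs <- Biostrings::DNAStringSet(
    setNames(vapply(seqsChr, paste, "", collapse = ""), names(lengths)))
  list(sequences = seqs, truth = truth)
}

#' Generate structured diploid genotypes with known admixture
#'
#' Each individual's membership vector Q is drawn from
#' Dirichlet(alpha, ..., alpha) over K ancestral populations; each of the
#' two allele copies at each locus picks an origin population from Q and
#' then an allele from that population's frequency vector.  Population
#' allele frequencies either are supplied directly or drift from shared
#' ancestral frequencies under a divergence parameter `F` (frequencies ~
#' Dirichlet(ancestral * (1-F)/F), the Dirichlet analogue of the
#' Balding-Nichols model; larger F = more divergence).  Missing calls are
#' masked i.i.d.  Deterministic under `seed`.
#'
#' @param nIndividuals,nLoci panel dimensions.
#' @param K number of ancestral populations.
#' @param alpha admixture Dirichlet parameter (small = crisp assignment).
#' @param F divergence parameter in (0, 1), used when `freqs` is NULL.
#' @param nAlleles alleles per locus (scalar or per-locus vector).
#' @param freqs optional list (length nLoci) of K x alleles frequency
#'   matrices.
#' @param missingRate i.i.d. probability that a call is masked.
#' @param seed RNG seed.
#' @return list: `genotypes` ([GenotypeMatrix-class] with integer allele
#'   labels), `Q` (true membership matrix), `freqs` (per-locus K x J
#'   matrices).
#' @export
generateStructuredGenotypes <- function(nIndividuals = 35L, nLoci = 42L,
                                        K = 2L, alpha = 0.2, F = 0.3,
                                        nAlleles = 4L, freqs = NULL,
                                        missingRate = 0.02, seed = 1L) {
  if (missingRate < 0 || missingRate >= 1)
    stop("missingRate must be in [0, 1)")
  set.seed(seed)
  nAlleles <- rep_len(nAlleles, nLoci)
  if (is.null(freqs)) {
    if (F <= 0 || F >= 1) stop("F must be in (0, 1)")
    freqs <- lapply(seq_len(nLoci), function(l) {
      anc <- drop(.rdirichlet(1, rep(1, nAlleles[l])))
      P <- t(vapply(seq_len(K), function(k)
        drop(.rdirichlet(1, anc * (1 - F) / F)), numeric(nAlleles[l])))
      P
    })
  } else {
    if (length(freqs) != nLoci) stop("freqs must have one matrix per locus")
    freqs <- lapply(freqs, function(P) {
      P <- as.matrix(P)
      if (nrow(P) != K) stop("each frequency matrix needs K rows")
      if (any(abs(rowSums(P) - 1) > 1e-8))
        stop("frequencies must sum to 1 per population")
      P
    })
    nAlleles <- vapply(freqs, ncol, 0L)
  }
  Q <- .rdirichlet(nIndividuals, rep(alpha, K))
  rownames(Q) <- sprintf("ind%02d", seq_len(nIndividuals))
  colnames(Q) <- paste0("pop", seq_len(K))

  calls <- matrix(NA_character_, nIndividuals, nLoci,
                  dimnames = list(rownames(Q),
                                  sprintf("m%03d", seq_len(nLoci))))
  for (i in seq_len(nIndividuals)) {
    for (l in seq_len(nLoci)) {
      z <- sample.int(K, 2, replace = TRUE, prob = Q[i, ])
      a <- vapply(z, function(k)
        sample.int(nAlleles[l], 1, prob = freqs[[l]][k, ]), 0L)
      calls[i, l] <- paste(sort(a), collapse = "/")
    }
  }
  if (missingRate > 0) {
    mask <- matrix(runif(length(calls)) < missingRate, nIndividuals, nLoci)
    calls[mask] <- NA
  }
  if (any(colSums(!is.na(calls)) == 0))
    stop("a locus came out entirely missing; lower missingRate or reseed")
  list(genotypes = genotypeMatrix(calls), Q = Q, freqs = freqs)
}

#' Generate a phenotype with known marker effects
#'
#' `phenotype = sum(effect * dosage) + N(0, sigma_e^2)` where dosage is the
#' count of the locus's reference allele (first sorted allele label).  The
#' noise variance is either given directly or scaled so the genetic
#' variance share hits a target heritability.  Deterministic under `seed`.
#'
#' @param x a [GenotypeMatrix-class]; causal markers must be fully typed.
#' @param effects named numeric vector of effects (names = causal markers).
#' @param h2 target heritability in (0, 1); ignored when `noiseVar` given.
#' @param noiseVar noise variance (0 gives an exact linear phenotype).
#' @param seed RNG seed.
#' @return list: `trait` (named numeric), `truth` (data.frame marker,
#'   effect, realized_pve), `h2Realized`.
#' @export
generatePhenotype <- function(x, effects, h2 = 0.5, noiseVar = NULL,
                              seed = 1L) {
  stopifnot(is(x, "GenotypeMatrix"))
  causal <- names(effects)
  if (is.null(causal) || !all(causal %in% markers(x)))
    stop("causal markers must exist in the genotype matrix")
  set.seed(seed)
  dos <- sapply(causal, function(mk) {
    ac <- alleleCalls(x, mk)
    if (anyNA(ac)) stop("causal marker ", mk, " has missing calls")
    ref <- sort(unique(c(ac)))[1]
    (ac[, 1] == ref) + (ac[, 2] == ref)
  })
  g <- drop(dos %*% effects)
  if (is.null(noiseVar)) {
    if (h2 <= 0 || h2 >= 1) stop("h2 must be in (0, 1)")
    if (var(g) == 0)
      stop("spec error: zero genetic variance with nonzero target heritability")
    noiseVar <- var(g) * (1 - h2) / h2
  }
  y <- g + rnorm(length(g), 0, sqrt(noiseVar))
  names(y) <- individuals(x)
  truth <- data.frame(
    marker = causal, effect = unname(effects),
    realized_pve = 100 * apply(dos, 2, var) * effects^2 / var(y),
    stringsAsFactors = FALSE)
  list(trait = y, truth = truth, h2Realized = var(g) / var(y))
}
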