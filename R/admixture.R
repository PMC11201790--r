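#' MCMC configuration for admixture inference
#'
#' Desk-scale defaults run 1,000 burn-in and 10,000 main iterations; the
#' full-scale setting used for real germplasm panels (10,000 burn-in,
#' 100,000 iterations, 10 replicates, K = 1-10) is reachable by argument.
#'
#' @param burnIn discarded iterations.
#' @param mainIterations recorded iterations.
#' @param replicates independent runs per K (for [structureScan()]).
#' @param kRange integer vector of K values to scan.
#' @param alpha Dirichlet hyperparameter on admixture proportions
#'   (initial value when `inferAlpha` is on).
#' @param lambda Dirichlet hyperparameter on allele frequencies.
#' @param inferAlpha sample alpha by random-walk Metropolis under a flat
#'   prior on (0, `alphaMax`), as the standard admixture samplers do; set
#'   `FALSE` to keep alpha fixed.
#' @param alphaPropSd proposal standard deviation for the alpha update.
#' @param alphaMax upper prior bound for alpha.
#' @param seed base RNG seed.
#' @return list of class `"MCMCConfig"`.
#' @export
mcmcConfig <- function(burnIn = 1000L, mainIterations = 10000L,
                       replicates = 10L, kRange = 1:10,
                       alpha = 1.0, lambda = 1.0, inferAlpha = TRUE,
                       alphaPropSd = 0.025, alphaMax = 10, seed = 1L) {
  if (burnIn < 0 || mainIterations < 1 || replicates < 1 || any(kRange < 1))
    stop("invalid MCMC configuration")
  structure(list(burnIn = as.integer(burnIn),
                 mainIterations = as.integer(mainIterations),
                 replicates = as.integer(replicates),
                 kRange = as.integer(kRange),
                 alpha = alpha, lambda = lambda,
                 inferAlpha = isTRUE(inferAlpha),
                 alphaPropSd = alphaPropSd, alphaMax = alphaMax,
                 seed = as.integer(seed)),
            class = "MCMCConfig")
}

# integer-encode a GenotypeMatrix for the sampler: per-locus allele codes
# 1..J, 0 = missing copy.  Internal.
.encodeAlleles <- function(x) {
  n <- nIndividuals(x); m <- nMarkers(x)
  a1 <- matrix(0L, n, m); a2 <- matrix(0L, n, m)
  nAlleles <- integer(m)
  alleleLabels <- vector("list", m)
  for (l in seq_len(m)) {
    ac <- alleleCalls(x, l)
    labs <- sort(unique(c(ac[, 1], ac[, 2])))
    labs <- labs[!is.na(labs)]
    if (length(labs) == 0) stop("locus ", markers(x)[l], " entirely missing")
    a1[, l] <- ifelse(is.na(ac[, 1]), 0L, match(ac[, 1], labs))
    a2[, l] <- ifelse(is.na(ac[, 2]), 0L, match(ac[, 2], labs))
    nAlleles[l] <- length(labs)
    alleleLabels[[l]] <- labs
  }
  list(a1 = a1, a2 = a2, nAlleles = nAlleles, labels = alleleLabels)
}

#' Fit the admixture model by Gibbs sampling
#'
#' STRUCTURE-style admixture model with independent allele frequencies:
#' each individual has membership proportions Q ~ Dirichlet(alpha), each
#' population has per-locus allele frequencies P ~ Dirichlet(lambda), and
#' every allele copy originates from a population drawn from Q.  The Gibbs
#' sweep alternates origins Z | P,Q; P | Z; Q | Z.  The log probability of
#' the data is estimated from the post-burn-in likelihood trace as
#' `mean(lnL) - var(lnL)/2`.  Identical seed and configuration give an
#' identical result.
#'
#' @param x a [GenotypeMatrix-class]; no locus may be entirely missing.
#' @param K number of ancestral populations (>= 1).
#' @param config an [mcmcConfig()]; `replicates`/`kRange` are ignored here.
#' @param seed RNG seed overriding `config$seed` when given.
#' @return An [AdmixtureResult-class].
#' @export
fitAdmixture <- function(x, K, config = mcmcConfig(), seed = NULL) {
  stopifnot(is(x, "GenotypeMatrix"), K >= 1)
  enc <- .encodeAlleles(x)
  nDistinct <- length(unique(apply(genotypeCalls(x), 1, paste, collapse = "|")))
  if (K > nDistinct)
    warning("K exceeds the number of distinct multilocus genotypes")
  set.seed(if (is.null(seed)) config$seed else seed)
  fit <- gibbs_admixture_cpp(enc$a1, enc$a2, as.integer(K),
                             config$burnIn, config$mainIterations,
                             config$alpha, config$lambda, enc$nAlleles,
                             config$inferAlpha, config$alphaPropSd,
                             config$alphaMax)
  Q <- fit$Q
  rownames(Q) <- individuals(x)
  colnames(Q) <- paste0("pop", seq_len(K))
  P <- fit$P
  names(P) <- markers(x)
  for (l in seq_along(P)) {
    rownames(P[[l]]) <- paste0("pop", seq_len(K))
    colnames(P[[l]]) <- enc$labels[[l]]
  }
  lnL <- fit$lnL
  v <- if (length(lnL) > 1) var(lnL) else 0
  new("AdmixtureResult", K = as.integer(K), Q = Q, P = P,
      lnPD = mean(lnL) - v / 2, lnLMean = mean(lnL), lnLVar = v,
      alphaHat = fit$alphaHat)
}

#' Replicated admixture runs over a range of K
#'
#' Runs [fitAdmixture()] for every K in `config$kRange` with
#' `config$replicates` independent seeds (derived deterministically from
#' `config$seed`), and assembles the Evanno table.
#'
#' @param x a [GenotypeMatrix-class].
#' @param config an [mcmcConfig()].
#' @return list with `lnPD` (matrix K x replicate), `evanno` (the
#'   [evannoDeltaK()] table), `bestK`, and `fits` (list of lists of
#'   [AdmixtureResult-class], indexed `fits[[as.character(K)]][[rep]]`).
#' @export
structureScan <- function(x, config = mcmcConfig()) {
  ks <- config$kRange
  lnPD <- matrix(NA_real_, length(ks), config$replicates,
                 dimnames = list(as.character(ks), NULL))
  fits <- setNames(vector("list", length(ks)), as.character(ks))
  counter <- 0L
  for (ki in seq_along(ks)) {
    fits[[ki]] <- vector("list", config$replicates)
    for (r in seq_len(config$replicates)) {
      counter <- counter + 1L
      runSeed <- (config$seed + 7919L * counter) %% .Machine$integer.max
      fit <- fitAdmixture(x, ks[ki], config, seed = runSeed)
      fits[[ki]][[r]] <- fit
      lnPD[ki, r] <- lnProbData(fit)
    }
  }
  ev <- evannoDeltaK(lnPD)
  list(lnPD = lnPD, evanno = ev, bestK = attr(ev, "bestK"), fits = fits)
}

#' Evanno delta-K table from replicate lnP(D) values
#'
#' Computes, per K: mean and sd of L(K) over replicates, the first
#' difference `L'(K) = L(K) - L(K-1)`, the mean absolute second difference
#' `|L''(K)| = mean over replicates of |L_r(K+1) - 2 L_r(K) + L_r(K-1)|`,
#' and `deltaK = |L''(K)| / sd(L(K))`.  `bestK` is the interior K
#' maximizing deltaK.
#'
#' @param lnPD numeric matrix of lnP(D) values, rows = consecutive K
#'   (rownames = K), columns = replicates; at least 3 consecutive K and 2
#'   replicates.
#' @return data.frame (K, meanL, sdL, L1, absL2, deltaK) with attribute
#'   `bestK`.  deltaK is NA at the boundary K and wherever sd = 0; a flat
#'   profile (all deltaK equal) raises a warning.
#' @examples
#' L <- sapply(c(-10, 0, 10), function(s) c(-1000, -800, -790, -788) + s)
#' evannoDeltaK(t(L))
#' @export
evannoDeltaK <- function(lnPD) {
  lnPD <- as.matrix(lnPD)
  nK <- nrow(lnPD)
  if (nK < 3) stop("need at least 3 consecutive K values")
  if (ncol(lnPD) < 2) stop("need at least 2 replicates per K for sd")
  ks <- if (!is.null(rownames(lnPD))) as.integer(rownames(lnPD)) else seq_len(nK)
  if (any(diff(ks) != 1L)) stop("K values must be consecutive")
  meanL <- rowMeans(lnPD)
  sdL <- apply(lnPD, 1, sd)
  L1 <- c(NA, diff(meanL))
  absL2 <- rep(NA_real_, nK)
  for (i in 2:(nK - 1)) {
    absL2[i] <- mean(abs(lnPD[i + 1, ] - 2 * lnPD[i, ] + lnPD[i - 1, ]))
  }
  deltaK <- ifelse(sdL > 0, absL2 / sdL, NA_real_)
  out <- data.frame(K = ks, meanL = meanL, sdL = sdL, L1 = L1,
                    absL2 = absL2, deltaK = deltaK, row.names = NULL)
  interior <- which(!is.na(deltaK))
  if (length(interior) == 0) {
    bestK <- NA_integer_
  } else {
    bestK <- ks[interior[which.max(deltaK[interior])]]
    finite <- deltaK[interior]
    if (length(finite) > 1 && max(finite) - min(finite) < 1e-12)
      warning("flat deltaK profile; bestK is not well supported")
  }
  attr(out, "bestK") <- bestK
  out
}
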