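#' Identity-by-state kinship matrix
#'
#' Pairwise allele-sharing score averaged over jointly typed loci: 1 for an
#' identical genotype, 0.5 when the two genotypes share exactly one allele
#' copy, 0 otherwise (multiset intersection of the two allele pairs,
#' halved).  Diagonal is 1.
#'
#' @param x a [GenotypeMatrix-class].
#' @return n x n symmetric numeric matrix with individual dimnames.
#' @export
ibsKinship <- function(x) {
  n <- nIndividuals(x); m <- nMarkers(x)
  A1 <- matrix(NA_character_, n, m); A2 <- A1
  for (l in seq_len(m)) {
    ac <- alleleCalls(x, l)
    A1[, l] <- ac[, 1]; A2[, l] <- ac[, 2]
  }
  K <- diag(1, n)
  dimnames(K) <- list(individuals(x), individuals(x))
  for (i in seq_len(n - 1)) {
    for (j in seq(i + 1, n)) {
      ok <- !is.na(A1[i, ]) & !is.na(A1[j, ])
      if (!any(ok))
        stop("undefined entry: individuals '", individuals(x)[i], "' and '",
             individuals(x)[j], "' share no typed locus")
      m1 <- (A1[i, ok] == A1[j, ok]) + (A2[i, ok] == A2[j, ok])
      m2 <- (A1[i, ok] == A2[j, ok]) + (A2[i, ok] == A1[j, ok])
      K[i, j] <- K[j, i] <- mean(pmax(m1, m2)) / 2
    }
  }
  K
}

# genotype-class indicator design for one marker (first class as baseline),
# or allele dosage for biallelic loci.  Calls normalized so "2/1" == "1/2".
.markerDesign <- function(calls, coding = "genotype") {
  parts <- strsplit(calls, "/", fixed = TRUE)
  norm <- vapply(parts, function(p) paste(sort(p), collapse = "/"), "")
  norm[is.na(calls)] <- NA
  if (coding == "dosage") {
    alleles <- sort(unique(unlist(parts[!is.na(calls)])))
    if (length(alleles) > 2)
      stop("dosage coding requires a biallelic locus")
    ref <- alleles[1]
    d <- vapply(parts, function(p) sum(p == ref), 0)
    d[is.na(calls)] <- NA
    return(matrix(d, ncol = 1, dimnames = list(NULL, "dosage")))
  }
  f <- factor(norm)
  if (nlevels(f) < 2) return(NULL)
  mm <- matrix(0, length(norm), nlevels(f) - 1,
               dimnames = list(NULL, levels(f)[-1]))
  for (j in seq_len(ncol(mm))) mm[, j] <- as.numeric(norm == levels(f)[j + 1])
  mm[is.na(norm), ] <- NA
  mm
}

.olsRss <- function(y, X) {
  fit <- qr(X)
  res <- qr.resid(fit, y)
  list(rss = sum(res^2), rank = fit$rank)
}

# shared scan machinery: whiten = NULL for OLS (GLM), else a function
# taking the row subset and returning the whitening matrix W such that
# the model is fit to (W y, W X).
.assocScan <- function(x, trait, Q, model, kinship = NULL,
                       coding = "genotype") {
  stopifnot(is(x, "GenotypeMatrix"))
  ids <- individuals(x)
  if (!is.null(names(trait))) {
    if (!all(ids %in% names(trait)))
      stop("trait must cover every genotyped individual")
    trait <- trait[ids]
  } else if (length(trait) != length(ids)) {
    stop("unnamed trait must have one value per individual, in order")
  }
  if (sd(trait, na.rm = TRUE) == 0) stop("trait is constant")
  X0 <- matrix(1, length(ids), 1, dimnames = list(ids, "intercept"))
  if (!is.null(Q)) {
    Q <- as.matrix(Q)
    if (nrow(Q) != length(ids)) stop("Q must have one row per individual")
    if (ncol(Q) > 1) X0 <- cbind(X0, Q[, -1, drop = FALSE])
  }

  eigenFull <- NULL
  if (model == "MLM") {
    G <- 2 * kinship
    eigenFull <- .bentEigen(G)
  }

  out <- list(); skipped <- character()
  for (mk in markers(x)) {
    calls <- genotypeCalls(x)[, mk]
    M <- tryCatch(.markerDesign(calls, coding), error = function(e) NULL)
    if (is.null(M)) { skipped <- c(skipped, mk); next }
    keep <- !is.na(trait) & !is.na(calls)
    if (sum(keep) <= ncol(X0) + ncol(M)) { skipped <- c(skipped, mk); next }
    y <- trait[keep]
    Xr <- X0[keep, , drop = FALSE]
    Xf <- cbind(Xr, M[keep, , drop = FALSE])

    if (model == "MLM") {
      ev <- if (all(keep)) eigenFull else .bentEigen(2 * kinship[keep, keep])
      lam <- .remlLambda(y, Xf, ev)
      w <- 1 / sqrt(lam * ev$values + 1)
      Ut <- t(ev$vectors)
      y <- w * (Ut %*% y)
      Xr <- w * (Ut %*% Xr)
      Xf <- w * (Ut %*% Xf)
    }

    fr <- .olsRss(y, Xr)
    ff <- .olsRss(y, Xf)
    df1 <- ff$rank - fr$rank
    df2 <- length(y) - ff$rank
    if (df1 < 1 || df2 < 1) { skipped <- c(skipped, mk); next }
    Fstat <- ((fr$rss - ff$rss) / df1) / (ff$rss / df2)
    pval <- pf(Fstat, df1, df2, lower.tail = FALSE)
    tss <- .olsRss(y, matrix(1, length(y), 1))$rss
    pve <- 100 * (fr$rss - ff$rss) / tss
    out[[mk]] <- data.frame(marker = mk, model = model,
                            p_value = pval, PVE = pve,
                            F_stat = Fstat, df1 = df1, df2 = df2,
                            n = length(y), stringsAsFactors = FALSE)
  }
  if (length(skipped))
    warning("skipped rank-deficient/constant markers: ",
            paste(head(skipped, 5), collapse = ", "),
            if (length(skipped) > 5) " ..." else "")
  res <- do.call(rbind, out)
  if (is.null(res))
    res <- data.frame(marker = character(), model = character(),
                      p_value = numeric(), PVE = numeric(),
                      F_stat = numeric(), df1 = integer(), df2 = integer(),
                      n = integer(), stringsAsFactors = FALSE)
  rownames(res) <- NULL
  res
}

# eigendecomposition of 2K with standard bending: eigenvalues within
# numerical noise of zero are clipped to zero; genuinely negative spectra
# are rejected.
.bentEigen <- function(G) {
  G <- (G + t(G)) / 2
  ev <- eigen(G, symmetric = TRUE)
  tolNeg <- 1e-6 * max(abs(ev$values))
  if (min(ev$values) < -tolNeg)
    stop("validation error: kinship matrix is not PSD after bending")
  ev$values <- pmax(ev$values, 0)
  ev
}

# profile REML estimate of lambda = sigma_g^2 / sigma_e^2 on the kinship
# eigen-spectrum
.remlLambda <- function(y, X, ev) {
  Ut <- t(ev$vectors)
  ys <- drop(Ut %*% y)
  Xs <- Ut %*% X
  n <- length(ys); p <- qr(X)$rank
  negll <- function(loglam) {
    lam <- exp(loglam)
    v <- lam * ev$values + 1
    w <- 1 / sqrt(v)
    fit <- qr(w * Xs)
    res <- qr.resid(fit, w * ys)
    rss <- sum(res^2)
    XtX <- crossprod(w * Xs)
    ldXtX <- determinant(XtX, logarithm = TRUE)$modulus
    0.5 * ((n - p) * log(rss / (n - p)) + sum(log(v)) + as.numeric(ldXtX))
  }
  opt <- optimize(negll, c(-12, 12))
  exp(opt$minimum)
}

#' GLM marker-trait association scan
#'
#' Per marker: ordinary least squares of the trait on genotype-class
#' indicators plus an intercept and (optionally) K-1 population-membership
#' covariates; the marker term is tested by a partial F-test and
#' `PVE = 100 (RSS_reduced - RSS_full) / TSS`.
#'
#' @param x a [GenotypeMatrix-class].
#' @param trait numeric vector named by (or ordered as) the individuals.
#' @param Q optional individuals x K membership matrix (from
#'   [fitAdmixture()]); the first column is dropped to avoid collinearity
#'   with the intercept.
#' @param coding `"genotype"` (class indicators; default) or `"dosage"`
#'   (reference-allele count; biallelic loci only).
#' @return data.frame: marker, model, p_value, PVE (percent), F_stat, df1,
#'   df2, n.  Rank-deficient or constant markers are skipped with a
#'   warning.
#' @export
glmScan <- function(x, trait, Q = NULL, coding = "genotype") {
  .assocScan(x, trait, Q, "GLM", coding = coding)
}

#' MLM marker-trait association scan
#'
#' Adds a polygenic random effect with covariance `sigma_g^2 * 2K` to the
#' GLM.  The variance ratio is estimated per marker by profile REML through
#' a one-dimensional search on the kinship eigen-spectrum (the
#' eigendecomposition is computed once and reused across markers); the
#' marker is then tested by a partial F-test on the generalized
#' least-squares fit, with PVE from the GLS sums of squares.  With
#' `kinship = diag(n)` the scan reduces exactly to [glmScan()].
#'
#' @inheritParams glmScan
#' @param kinship n x n kinship matrix, e.g. from [ibsKinship()]; must be
#'   positive semi-definite after bending.
#' @return as [glmScan()], with model = "MLM".
#' @export
mlmScan <- function(x, trait, Q = NULL, kinship, coding = "genotype") {
  stopifnot(is.matrix(kinship), nrow(kinship) == nIndividuals(x))
  .assocScan(x, trait, Q, "MLM", kinship = kinship, coding = coding)
}

#' Ordinal trait encodings for fruit phenotypes
#'
#' The default numeric codes used for the fruit traits: peel color
#' white = 0, light green = 1, green = 2, dark green = 3; spine none = 0,
#' very low = 1.  Both GLM and MLM treat traits numerically, so ordinal
#' categories are coded as consecutive integers.
#'
#' @return named list of named numeric vectors.
#' @export
traitCodes <- function() {
  list(peel_color = c(white = 0, `light green` = 1, green = 2,
                      `dark green` = 3),
       spine = c(none = 0, `very low` = 1))
}

#' Encode categorical trait values numerically
#'
#' @param values character vector of category labels.
#' @param scheme named numeric vector mapping labels to codes (one entry
#'   of [traitCodes()], or custom).
#' @return numeric vector, preserving names of `values`.
#' @export
encodeTrait <- function(values, scheme) {
  out <- unname(scheme[as.character(values)])
  if (anyNA(out) && !anyNA(values))
    stop("unknown trait categories: ",
         paste(setdiff(unique(values), names(scheme)), collapse = ", "))
  names(out) <- names(values)
  out
}
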