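#' Allele presence/absence band matrix
#'
#' Binarizes co-dominant genotypes the way gel-band scoring does: one
#' column per (locus, allele) combination, 1 when the individual carries
#' the allele, 0 when typed but lacking it, NA for missing calls.
#'
#' @param x a [GenotypeMatrix-class].
#' @return numeric matrix individuals x bands, with band names
#'   `"marker.allele"`.
#' @export
alleleBands <- function(x) {
  cols <- lapply(markers(x), function(m) {
    ac <- alleleCalls(x, m)
    alleles <- sort(unique(c(ac[, 1], ac[, 2])))
    alleles <- alleles[!is.na(alleles)]
    band <- matrix(NA_real_, nrow(ac), length(alleles),
                   dimnames = list(rownames(ac), paste(m, alleles, sep = ".")))
    typed <- !is.na(ac[, 1])
    for (j in seq_along(alleles)) {
      band[typed, j] <- (ac[typed, 1] == alleles[j]) +
        (ac[typed, 2] == alleles[j]) > 0
    }
    band
  })
  do.call(cbind, cols)
}

#' Pairwise genetic distance from banded genotypes
#'
#' Scores every pair of individuals over the bands typed in both, with
#' similarity coefficients: `simple_matching` = matches/total,
#' `dice` = 2a/(2a+b+c), `jaccard` = a/(a+b+c) (a = shared presences,
#' b/c = presences unique to either individual).  Returned as distance
#' `1 - similarity`.
#'
#' @param x a [GenotypeMatrix-class].
#' @param method one of `"simple_matching"`, `"dice"`, `"jaccard"`.
#' @return symmetric distance matrix with zero diagonal and individual
#'   dimnames; `attr(, "method")` records the coefficient.  Individuals
#'   with all-missing data are dropped with a warning.
#' @export
similarityMatrix <- function(x, method = c("simple_matching", "dice",
                                           "jaccard")) {
  method <- match.arg(method)
  bands <- alleleBands(x)
  allMissing <- rowSums(!is.na(bands)) == 0
  if (any(allMissing)) {
    warning("dropping individuals with all-missing data: ",
            paste(rownames(bands)[allMissing], collapse = ", "))
    bands <- bands[!allMissing, , drop = FALSE]
  }
  n <- nrow(bands)
  if (n < 2) stop("need at least 2 individuals with data")
  d <- matrix(0, n, n, dimnames = list(rownames(bands), rownames(bands)))
  for (i in seq_len(n - 1)) {
    for (j in seq(i + 1, n)) {
      bi <- bands[i, ]; bj <- bands[j, ]
      ok <- !is.na(bi) & !is.na(bj)
      a <- sum(bi[ok] == 1 & bj[ok] == 1)
      b <- sum(bi[ok] == 1 & bj[ok] == 0)
      cc <- sum(bi[ok] == 0 & bj[ok] == 1)
      dd <- sum(bi[ok] == 0 & bj[ok] == 0)
      s <- switch(method,
                  simple_matching = (a + dd) / (a + b + cc + dd),
                  dice = 2 * a / (2 * a + b + cc),
                  jaccard = a / (a + b + cc))
      d[i, j] <- d[j, i] <- 1 - s
    }
  }
  attr(d, "method") <- method
  d
}

#' UPGMA clustering
#'
#' Unweighted pair-group method with arithmetic mean: iteratively merges
#' the closest pair of clusters at height d/2; the distance between merged
#' clusters is the size-weighted arithmetic average (equivalently the mean
#' over all leaf pairs).  Ties are broken by the smallest (row, column)
#' index pair in the original label order, so output is deterministic.
#'
#' @param d symmetric distance matrix (or `dist`) with labels.
#' @return object of class `"upgma"`: list with `merge`/`height`/`labels`
#'   (hclust convention, heights on the d/2 node-height scale), `newick`
#'   (rooted ultrametric Newick string, branch lengths = height
#'   differences rounded to 6 dp) and `cophenetic` (implied distance
#'   matrix, on the original d scale).
#' @examples
#' d <- matrix(c(0, 2, 4, 2, 0, 4, 4, 4, 0), 3,
#'             dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
#' upgma(d)$newick  # "((A:1,B:1):1,C:2);"
#' @export
upgma <- function(d) {
  if (inherits(d, "dist")) d <- as.matrix(d)
  if (!isSymmetric(unname(d))) stop("validation error: d must be symmetric")
  if (anyNA(d)) stop("validation error: NaN/NA distances")
  n <- nrow(d)
  if (n < 2) stop("need at least 2 taxa")
  labels <- rownames(d)
  if (is.null(labels)) labels <- paste0("t", seq_len(n))

  # active clusters: negative = leaf index, positive = merge row
  id <- -seq_len(n)          # hclust-style ids
  minIdx <- seq_len(n)       # smallest original member, for tie-breaks
  size <- rep(1L, n)
  D <- d
  merge <- matrix(0L, n - 1, 2)
  height <- numeric(n - 1)
  nodeHeight <- c(rep(0, n))          # per active cluster
  newickStr <- labels

  for (step in seq_len(n - 1)) {
    m <- length(id)
    best <- NULL
    for (i in seq_len(m - 1)) {
      for (j in seq(i + 1, m)) {
        # order the candidate by original-label indices for tie-breaking
        a <- min(minIdx[i], minIdx[j]); b <- max(minIdx[i], minIdx[j])
        cand <- c(D[i, j], a, b)
        if (is.null(best) ||
            cand[1] < best[1] - 1e-12 ||
            (abs(cand[1] - best[1]) <= 1e-12 &&
             (cand[2] < best[2] ||
              (cand[2] == best[2] && cand[3] < best[3])))) {
          best <- cand; bi <- i; bj <- j
        }
      }
    }
    h <- D[bi, bj] / 2
    merge[step, ] <- sort(c(id[bi], id[bj]))
    height[step] <- h

    # child with the smaller original label index prints first
    first <- if (minIdx[bi] <= minIdx[bj]) bi else bj
    second <- if (first == bi) bj else bi
    newClade <- sprintf(
      "(%s:%s,%s:%s)",
      newickStr[first],
      format(round(h - nodeHeight[first], 6), scientific = FALSE),
      newickStr[second],
      format(round(h - nodeHeight[second], 6), scientific = FALSE))

    newD <- (size[bi] * D[bi, ] + size[bj] * D[bj, ]) / (size[bi] + size[bj])
    keep <- setdiff(seq_len(m), c(bi, bj))
    D <- rbind(cbind(D[keep, keep, drop = FALSE], newD[keep]),
               c(newD[keep], 0))
    id <- c(id[keep], step)
    minIdx <- c(minIdx[keep], min(minIdx[bi], minIdx[bj]))
    size <- c(size[keep], size[bi] + size[bj])
    nodeHeight <- c(nodeHeight[keep], h)
    newickStr <- c(newickStr[keep], newClade)
  }

  hc <- list(merge = merge, height = 2 * height, labels = labels,
             method = "average")
  coph <- .cophenetic(merge, 2 * height, labels)
  structure(list(merge = merge, height = height, labels = labels,
                 newick = paste0(newickStr, ";"),
                 cophenetic = coph, hclust = hc),
            class = "upgma")
}

# cophenetic distances implied by a merge/height table (d scale)
.cophenetic <- function(merge, height, labels) {
  n <- length(labels)
  members <- vector("list", n - 1)
  coph <- matrix(0, n, n, dimnames = list(labels, labels))
  for (s in seq_len(n - 1)) {
    grab <- function(k) if (k < 0) -k else members[[k]]
    a <- grab(merge[s, 1]); b <- grab(merge[s, 2])
    coph[a, b] <- height[s]
    coph[b, a] <- height[s]
    members[[s]] <- c(a, b)
  }
  coph
}

#' @export
print.upgma <- function(x, ...) {
  cat(sprintf("UPGMA tree on %d taxa\n", length(x$labels)))
  cat(" ", x$newick, "\n")
  invisible(x)
}

#' Principal coordinates analysis
#'
#' Gower double-centering of `-d^2/2` followed by a symmetric
#' eigendecomposition.  Coordinates are eigenvectors scaled by the square
#' root of their (positive) eigenvalues; negative eigenvalues are excluded
#' both from the coordinates and from the percent-explained denominator.
#'
#' @param d symmetric distance matrix (or `dist`).
#' @param tol eigenvalues below `tol * max(|eigenvalue|)` are treated as
#'   null and dropped.
#' @return list of class `"PCoAResult"`: `coordinates` (individuals x
#'   axes, axes ordered by eigenvalue), `eigenvalues` (all of them) and
#'   `percentExplained` (over positive eigenvalues, summing to 100).
#' @export
pcoa <- function(d, tol = 1e-9) {
  if (inherits(d, "dist")) d <- as.matrix(d)
  if (!isSymmetric(unname(d))) stop("validation error: d must be symmetric")
  n <- nrow(d)
  if (n < 3) stop("need at least 3 individuals")
  A <- -0.5 * d^2
  J <- diag(n) - matrix(1 / n, n, n)
  B <- J %*% A %*% J
  B <- (B + t(B)) / 2
  e <- eigen(B, symmetric = TRUE)
  thresh <- tol * max(abs(e$values))
  pos <- e$values > thresh
  coords <- e$vectors[, pos, drop = FALSE] %*%
    diag(sqrt(e$values[pos]), sum(pos))
  rownames(coords) <- rownames(d)
  colnames(coords) <- paste0("Axis", seq_len(ncol(coords)))
  structure(list(coordinates = coords,
                 eigenvalues = e$values,
                 percentExplained = 100 * e$values[pos] / sum(e$values[pos])),
            class = "PCoAResult")
}

#' @export
print.PCoAResult <- function(x, ...) {
  k <- min(3, length(x$percentExplained))
  cat(sprintf("PCoA: %d individuals, %d positive axes\n",
              nrow(x$coordinates), ncol(x$coordinates)))
  cat("  percent explained:",
      paste(sprintf("%.2f%%", x$percentExplained[seq_len(k)]),
            collapse = ", "),
      if (length(x$percentExplained) > k) "..." else "", "\n")
  invisible(x)
}
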