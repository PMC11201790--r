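#' GenotypeMatrix: co-dominant diploid genotype calls
#'
#' Stores an individuals x loci matrix of unordered diploid allele pairs
#' ("a/b" strings, `NA` for missing) with individual and marker identifiers
#' as dimnames.  Allele labels are arbitrary per-locus strings; fragment
#' sizes ("120/124") and integer codes ("1/3") are both valid.
#'
#' @slot calls character matrix, rows = individuals, columns = markers;
#'   each non-missing cell is `"a/b"`.
#'
#' @seealso [genotypeMatrix()] for construction, [readGenotypeTable()] for
#'   the TSV reader, [alleleCalls()] for parsed access.
#' @export
setClass("GenotypeMatrix", representation(calls = "matrix"))

setValidity("GenotypeMatrix", function(object) {
  x <- object@calls
  if (!is.character(x)) return("calls must be a character matrix")
  if (is.null(rownames(x)) || is.null(colnames(x)))
    return("calls must carry individual rownames and marker colnames")
  if (anyDuplicated(rownames(x))) return("duplicate individual IDs")
  if (anyDuplicated(colnames(x))) return("duplicate marker IDs")
  bad <- !is.na(x) & !grepl("^[^/[:space:]]+/[^/[:space:]]+$", x)
  if (any(bad)) {
    i <- which(bad, arr.ind = TRUE)[1, ]
    return(sprintf("malformed genotype cell at individual '%s', marker '%s'",
                   rownames(x)[i[1]], colnames(x)[i[2]]))
  }
  TRUE
})

#' Construct a GenotypeMatrix
#'
#' @param calls character matrix of `"a/b"` calls (`NA` = missing) with
#'   individual rownames and marker colnames.
#' @return A [GenotypeMatrix-class] object.
#' @examples
#' calls <- matrix(c("1/1", "1/2", "2/2", NA), 2, 2,
#'                 dimnames = list(c("ind1", "ind2"), c("m1", "m2")))
#' genotypeMatrix(calls)
#' @export
genotypeMatrix <- function(calls) {
  obj <- new("GenotypeMatrix", calls = calls)
  validObject(obj)
  obj
}

#' @describeIn genotypeMatrix individual identifiers
#' @param x a `GenotypeMatrix`.
#' @export
individuals <- function(x) rownames(x@calls)

#' @describeIn genotypeMatrix marker identifiers
#' @export
markers <- function(x) colnames(x@calls)

#' @describeIn genotypeMatrix the raw call matrix
#' @export
genotypeCalls <- function(x) x@calls

#' @describeIn genotypeMatrix number of individuals
#' @export
nIndividuals <- function(x) nrow(x@calls)

#' @describeIn genotypeMatrix number of markers
#' @export
nMarkers <- function(x) ncol(x@calls)

setMethod("show", "GenotypeMatrix", function(object) {
  x <- object@calls
  cat(sprintf("GenotypeMatrix: %d individuals x %d markers (%.1f%% missing)\n",
              nrow(x), ncol(x), 100 * mean(is.na(x))))
  cat("individuals:", paste(head(rownames(x), 4), collapse = ", "),
      if (nrow(x) > 4) "..." else "", "\n")
  cat("markers:", paste(head(colnames(x), 4), collapse = ", "),
      if (ncol(x) > 4) "..." else "", "\n")
})

#' Parsed allele calls at one locus
#'
#' @param x a [GenotypeMatrix-class].
#' @param marker marker ID or column index.
#' @return A 2-column character matrix (one row per individual) of allele
#'   labels; both entries `NA` for missing calls.
#' @export
alleleCalls <- function(x, marker) {
  calls <- x@calls[, marker]
  out <- matrix(NA_character_, length(calls), 2,
                dimnames = list(rownames(x@calls), c("a1", "a2")))
  ok <- !is.na(calls)
  if (any(ok)) {
    parts <- strsplit(calls[ok], "/", fixed = TRUE)
    out[ok, 1] <- vapply(parts, `[`, "", 1L)
    out[ok, 2] <- vapply(parts, `[`, "", 2L)
  }
  out
}

#' AdmixtureResult: posterior summaries of one admixture-model fit
#'
#' @slot K integer, number of ancestral populations.
#' @slot Q numeric matrix, individuals x K posterior-mean membership
#'   proportions; rows sum to 1.
#' @slot P list (one entry per locus) of K x alleles posterior-mean allele
#'   frequency matrices; rows sum to 1.
#' @slot lnPD numeric, estimated log probability of the data
#'   (`mean(lnL) - var(lnL)/2` over the post-burn-in trace).
#' @slot lnLMean,lnLVar numeric, trace summaries.
#' @slot alphaHat numeric, posterior-mean admixture hyperparameter (the
#'   fixed value when alpha inference is off).
#' @seealso [fitAdmixture()]
#' @export
setClass("AdmixtureResult",
         representation(K = "integer", Q = "matrix", P = "list",
                        lnPD = "numeric", lnLMean = "numeric",
                        lnLVar = "numeric", alphaHat = "numeric"))

setValidity("AdmixtureResult", function(object) {
  if (ncol(object@Q) != object@K) return("Q must have K columns")
  if (any(abs(rowSums(object@Q) - 1) > 1e-6)) return("Q rows must sum to 1")
  if (!is.finite(object@lnPD)) return("lnPD must be finite")
  TRUE
})

setMethod("show", "AdmixtureResult", function(object) {
  cat(sprintf("AdmixtureResult: K = %d, %d individuals, %d loci\n",
              object@K, nrow(object@Q), length(object@P)))
  cat(sprintf("  lnP(D) = %.2f  (mean lnL %.2f, var %.2f, alpha-hat %.3f)\n",
              object@lnPD, object@lnLMean, object@lnLVar, object@alphaHat))
})

#' @describeIn AdmixtureResult-class posterior-mean membership matrix
#' @param x an `AdmixtureResult`.
#' @export
membershipQ <- function(x) x@Q

#' @describeIn AdmixtureResult-class per-locus allele-frequency estimates
#' @export
alleleFreqP <- function(x) x@P

#' @describeIn AdmixtureResult-class estimated log probability of data
#' @export
lnProbData <- function(x) x@lnPD
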