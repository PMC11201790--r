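#' Per-locus genetic diversity statistics
#'
#' Computes, from the non-missing diploid calls at one locus (two allele
#' observations per typed individual):
#' observed allele number `Na`; effective allele number `Ne = 1 / sum(p^2)`;
#' observed heterozygosity `Ho` (fraction of typed individuals with two
#' different alleles); Nei's gene diversity `H = 1 - sum(p^2)`; unbiased
#' expected heterozygosity `He = 2n/(2n-1) * H`; Shannon's information
#' index `I = -sum(p log p)`; and Botstein's polymorphism information
#' content `PIC = 1 - sum(p^2) - sum_{i<j} 2 p_i^2 p_j^2`.
#'
#' @param calls character vector of `"a/b"` genotype strings (`NA` =
#'   missing), or a 2-column allele matrix from [alleleCalls()].
#' @return one-row data.frame: Na, Ne, Ho, He, I, H, PIC, n_typed.
#' @examples
#' locusSummary(c("1/1", "1/2", "2/2", "1/2"))
#' @export
locusSummary <- function(calls) {
  if (is.matrix(calls)) {
    a1 <- calls[, 1]; a2 <- calls[, 2]
  } else {
    parts <- strsplit(as.character(calls), "/", fixed = TRUE)
    a1 <- vapply(parts, function(x) x[1], "")
    a2 <- vapply(parts, function(x) if (length(x) > 1) x[2] else NA_character_, "")
  }
  ok <- !is.na(a1) & !is.na(a2)
  n <- sum(ok)
  if (n < 2) stop("insufficient data: need at least 2 typed individuals")
  a1 <- a1[ok]; a2 <- a2[ok]
  p <- as.numeric(table(c(a1, a2))) / (2 * n)

  sp2 <- sum(p^2)
  H <- 1 - sp2
  data.frame(
    Na = length(p),
    Ne = 1 / sp2,
    Ho = mean(a1 != a2),
    He = (2 * n / (2 * n - 1)) * H,
    I = -sum(p * log(p)),
    H = H,
    PIC = 1 - sp2 - (sp2^2 - sum(p^4)),
    n_typed = n)
}

#' Polymorphism classes from PIC
#'
#' Boundaries applied to unrounded PIC: high `PIC >= 0.5`, moderate
#' `0.25 < PIC < 0.5`, low `PIC <= 0.25`.
#'
#' @param pic numeric vector of PIC values.
#' @return factor with levels low, moderate, high.
#' @export
classifyPolymorphism <- function(pic) {
  cls <- ifelse(pic >= 0.5, "high", ifelse(pic > 0.25, "moderate", "low"))
  factor(cls, levels = c("low", "moderate", "high"))
}

#' Diversity summary table over all loci
#'
#' One [locusSummary()] row per marker plus a means row (arithmetic mean of
#' each statistic over loci) and polymorphism class counts.
#'
#' @param x a [GenotypeMatrix-class], or a precomputed per-locus statistics
#'   data.frame carrying at least marker and PIC columns (e.g. a published
#'   per-marker table), in which case the classification and means are
#'   computed from the given values.
#' @return list of class `"DiversityTable"`: `perLocus` (data.frame with a
#'   marker column), `means` (named numeric vector over loci) and
#'   `classCounts` (table over low/moderate/high).
#' @export
summaryTable <- function(x) {
  if (is(x, "GenotypeMatrix")) {
    rows <- lapply(markers(x), function(m) {
      cbind(data.frame(marker = m, stringsAsFactors = FALSE),
            locusSummary(alleleCalls(x, m)))
    })
    perLocus <- do.call(rbind, rows)
  } else {
    perLocus <- as.data.frame(x)
    if (!all(c("marker", "PIC") %in% names(perLocus)))
      stop("precomputed table needs 'marker' and 'PIC' columns")
  }
  num <- vapply(perLocus, is.numeric, NA)
  means <- colMeans(perLocus[, num, drop = FALSE])
  structure(list(perLocus = perLocus,
                 means = means,
                 classCounts = table(classifyPolymorphism(perLocus$PIC))),
            class = "DiversityTable")
}

#' @export
print.DiversityTable <- function(x, ...) {
  cat(sprintf("Diversity summary for %d loci\n", nrow(x$perLocus)))
  cat("means: ", paste(sprintf("%s=%.3f", names(x$means), x$means),
                       collapse = "  "), "\n")
  cat("polymorphism classes:",
      paste(sprintf("%s=%d", names(x$classCounts), x$classCounts),
            collapse = "  "), "\n")
  invisible(x)
}

#' Published per-marker diversity statistics bundled as a worked example
#'
#' Per-locus Na, Ne, Ho, He, I, H and PIC for 42 polymorphic SSR markers
#' scored in 35 chayote accessions; used to exercise the table and
#' classification code on real published numbers.
#'
#' @return data.frame with columns marker, Na, Ne, Ho, He, I, H, PIC.
#' @export
chayoteDiversityTable <- function() {
  read.delim(system.file("extdata", "chayote_ssr_diversity.tsv",
                         package = "SSRtools"),
             stringsAsFactors = FALSE)
}
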