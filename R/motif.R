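#' @keywords internal
.revcompChr <- function(x) {
  vapply(x, function(s) {
    paste(rev(strsplit(chartr("ACGTacgt", "TGCAtgca", s), "")[[1]]),
          collapse = "")
  }, "", USE.NAMES = FALSE)
}

#' Test whether a motif is primitive
#'
#' A motif is primitive when it is not itself a whole-number repetition of a
#' shorter unit ("AT" is primitive, "ATAT" is not).
#'
#' @param motif DNA string.
#' @return logical.
#' @export
isPrimitiveMotif <- function(motif) {
  p <- nchar(motif)
  if (p == 1L) return(TRUE)
  for (d in seq_len(p - 1L)) {
    if (p %% d == 0L &&
        strrep(substr(motif, 1L, d), p %/% d) == motif) return(FALSE)
  }
  TRUE
}

#' Canonical motif class
#'
#' Folds a repeat motif over phase and strand: the class representative is
#' the lexicographically smallest string among all cyclic rotations of the
#' motif and all cyclic rotations of its reverse complement.  Poly-T runs
#' therefore fall in class "A", and GA/TC/CT repeats all in class "AG".
#'
#' @param motif primitive DNA motif (1-6 bp, ACGT only, case-insensitive).
#' @return The canonical class string.  Idempotent:
#'   `canonicalMotif(canonicalMotif(x)) == canonicalMotif(x)`.
#' @examples
#' canonicalMotif("T")    # "A"
#' canonicalMotif("TC")   # "AG"
#' canonicalMotif("ATT")  # "AAT"
#' @export
canonicalMotif <- function(motif) {
  vapply(toupper(motif), function(m) {
    if (!grepl("^[ACGT]+$", m))
      stop("invalid alphabet: motif must contain only A, C, G, T")
    if (!isPrimitiveMotif(m))
      stop("invalid motif: '", m, "' is not primitive")
    p <- nchar(m)
    rot <- function(s) {
      if (p == 1L) return(s)
      d <- strrep(s, 2L)
      vapply(seq_len(p), function(i) substr(d, i, i + p - 1L), "")
    }
    min(c(rot(m), rot(.revcompChr(m))))
  }, "", USE.NAMES = FALSE)
}
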