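#' Primer design constraints
#'
#' Defaults follow the usual SSR-validation setting: PCR product 100-250 bp,
#' primer length 18-24 bp, Tm 50-60 C, GC 40-60%, and at most a 3 C Tm
#' difference within a pair.
#'
#' @param productBp,primerLen,tmCelsius,gcPercent inclusive `c(min, max)`
#'   ranges.
#' @param maxTmDiff maximum |left Tm - right Tm| in degrees C.
#' @return list of class `"PrimerConstraints"`.
#' @export
primerConstraints <- function(productBp = c(100, 250),
                              primerLen = c(18, 24),
                              tmCelsius = c(50, 60),
                              gcPercent = c(40, 60),
                              maxTmDiff = 3) {
  stopifnot(length(productBp) == 2, length(primerLen) == 2,
            length(tmCelsius) == 2, length(gcPercent) == 2)
  if (productBp[1] > productBp[2] || primerLen[1] > primerLen[2] ||
      tmCelsius[1] > tmCelsius[2] || gcPercent[1] > gcPercent[2])
    stop("all constraint ranges must be non-empty")
  if (productBp[1] <= 2 * primerLen[1])
    stop("minimum product must exceed twice the minimum primer length")
  structure(list(productBp = productBp, primerLen = primerLen,
                 tmCelsius = tmCelsius, gcPercent = gcPercent,
                 maxTmDiff = maxTmDiff), class = "PrimerConstraints")
}

#' Oligonucleotide melting temperature
#'
#' The Wallace rule `2(A+T) + 4(G+C)` for oligos shorter than 14 nt and the
#' GC formula `64.9 + 41 (GC - 16.4) / length` from 14 nt on.  Deliberately
#' simple (no nearest-neighbour thermodynamics); the design functions take
#' the Tm function as data so a different rule can be slotted in.
#'
#' @param seq DNA string(s), ACGT only, length >= 8.
#' @return Tm in degrees C.
#' @examples
#' meltingTemperature(strrep("AG", 6))   # 36
#' @export
meltingTemperature <- function(seq) {
  seq <- toupper(seq)
  if (any(!grepl("^[ACGT]+$", seq)))
    stop("invalid alphabet: primer sequences must be ACGT only")
  len <- nchar(seq)
  if (any(len < 8)) stop("primer too short: need at least 8 nt")
  gc <- len - nchar(gsub("[GC]", "", seq))
  ifelse(len < 14, 2 * (len - gc) + 4 * gc, 64.9 + 41 * (gc - 16.4) / len)
}

#' GC content in percent
#' @param seq DNA string(s).
#' @return percent G+C.
#' @export
gcContent <- function(seq) {
  seq <- toupper(seq)
  100 * (nchar(seq) - nchar(gsub("[GC]", "", seq))) / nchar(seq)
}

# enumerate candidate single primers in [lo, hi] of the template (+ strand
# footprints), as a data.frame of start/len with Tm and GC precomputed from
# cumulative counts.  Internal.
.primerWindows <- function(cumGC, lo, hi, constraints) {
  lens <- seq(constraints$primerLen[1], constraints$primerLen[2])
  grid <- expand.grid(start = seq(lo, hi), len = lens)
  grid <- grid[grid$start + grid$len - 1 <= hi, , drop = FALSE]
  if (nrow(grid) == 0) return(grid)
  gc <- cumGC[grid$start + grid$len] - cumGC[grid$start]
  grid$gcPct <- 100 * gc / grid$len
  grid$tm <- ifelse(grid$len < 14,
                    2 * (grid$len - gc) + 4 * gc,
                    64.9 + 41 * (gc - 16.4) / grid$len)
  ok <- grid$gcPct >= constraints$gcPercent[1] &
    grid$gcPct <= constraints$gcPercent[2] &
    grid$tm >= constraints$tmCelsius[1] &
    grid$tm <= constraints$tmCelsius[2]
  grid[ok, , drop = FALSE]
}

#' Design primer pairs flanking an SSR locus
#'
#' Enumerates every (left, right) primer placement in the flanks whose
#' product fully contains the SSR array and satisfies all constraints, then
#' ranks candidates by Tm balance (|left Tm - right Tm|), product-size
#' centrality (|product - midpoint of the allowed range|), and finally
#' left/right start for a deterministic order.
#'
#' @param locus one SSR locus: a single-row data.frame (or list) with
#'   `start` and `end` (1-based inclusive on `template`), plus optionally
#'   `seqid`/`motif` carried into the output marker ID.
#' @param template the source DNA sequence containing the locus and flanks.
#' @param constraints a [primerConstraints()] object.
#' @param maxCandidates maximum number of pairs returned.
#' @return data.frame with columns left_seq, right_seq, left_start,
#'   right_start (1-based leftmost template coordinate of each primer's
#'   footprint), left_len, right_len, product_bp, left_tm, right_tm,
#'   left_gc, right_gc.  `right_seq` is the reverse complement of the
#'   template segment.  Zero rows when no placement satisfies the
#'   constraints.
#' @export
designPrimers <- function(locus, template, constraints = primerConstraints(),
                          maxCandidates = 3L) {
  if (is(template, "XString")) template <- as.character(template)
  template <- toupper(template)
  n <- nchar(template)
  start <- as.integer(locus$start); end <- as.integer(locus$end)
  if (is.na(start) || is.na(end) || start < 1 || end > n || start > end)
    stop("coordinate error: locus does not lie within the template")
  if (maxCandidates < 1) stop("maxCandidates must be >= 1")

  chars <- strsplit(template, "")[[1]]
  cumGC <- c(0, cumsum(chars %in% c("G", "C")))

  prodMax <- constraints$productBp[2]
  # left primers end strictly before the array, right primers start after it
  leftLo <- max(1L, end - prodMax + 1L)
  leftHi <- start - 1L
  rightLo <- end + 1L
  rightHi <- min(n, start + prodMax - 1L)
  if (leftHi - leftLo + 1 < constraints$primerLen[1] ||
      rightHi - rightLo + 1 < constraints$primerLen[1])
    return(.emptyPairs())

  left <- .primerWindows(cumGC, leftLo, leftHi, constraints)
  right <- .primerWindows(cumGC, rightLo, rightHi, constraints)
  if (nrow(left) == 0 || nrow(right) == 0) return(.emptyPairs())

  combo <- expand.grid(i = seq_len(nrow(left)), j = seq_len(nrow(right)))
  product <- right$start[combo$j] + right$len[combo$j] - left$start[combo$i]
  tmDiff <- abs(left$tm[combo$i] - right$tm[combo$j])
  ok <- product >= constraints$productBp[1] &
    product <= constraints$productBp[2] &
    tmDiff <= constraints$maxTmDiff
  if (!any(ok)) return(.emptyPairs())
  combo <- combo[ok, , drop = FALSE]
  product <- product[ok]; tmDiff <- tmDiff[ok]

  mid <- mean(constraints$productBp)
  ord <- order(tmDiff, abs(product - mid),
               left$start[combo$i], right$start[combo$j])
  take <- head(ord, maxCandidates)
  li <- combo$i[take]; rj <- combo$j[take]

  leftSeq <- substring(template, left$start[li],
                       left$start[li] + left$len[li] - 1)
  rightTemplate <- substring(template, right$start[rj],
                             right$start[rj] + right$len[rj] - 1)
  data.frame(
    left_seq = leftSeq,
    right_seq = .revcompChr(rightTemplate),
    left_start = left$start[li],
    right_start = right$start[rj],
    left_len = left$len[li], right_len = right$len[rj],
    product_bp = product[take],
    left_tm = left$tm[li], right_tm = right$tm[rj],
    left_gc = left$gcPct[li], right_gc = right$gcPct[rj],
    stringsAsFactors = FALSE)
}

.emptyPairs <- function() {
  data.frame(left_seq = character(), right_seq = character(),
             left_start = integer(), right_start = integer(),
             left_len = integer(), right_len = integer(),
             product_bp = integer(), left_tm = numeric(),
             right_tm = numeric(), left_gc = numeric(),
             right_gc = numeric(), stringsAsFactors = FALSE)
}
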