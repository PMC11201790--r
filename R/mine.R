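#' Minimum repeat-count thresholds for SSR mining
#'
#' Defaults follow the common genome-wide SSR survey setting: ten repeats
#' for mononucleotides, six for dinucleotides and five for tri- through
#' hexanucleotides.
#'
#' @param mono,di,tri,tetra,penta,hexa integer minimum repeat counts
#'   (all must be >= 2).
#' @return Named integer vector with elements "1".."6".
#' @export
miningThresholds <- function(mono = 10L, di = 6L, tri = 5L, tetra = 5L,
                             penta = 5L, hexa = 5L) {
  thr <- as.integer(c(mono, di, tri, tetra, penta, hexa))
  if (anyNA(thr) || any(thr < 2L))
    stop("all minimum repeat counts must be integers >= 2")
  names(thr) <- as.character(1:6)
  thr
}

#' Detect perfect SSRs in a single sequence
#'
#' Finds every maximal perfect tandem array with primitive period 1-6 whose
#' complete-repeat count meets the period's threshold.  Arrays are reported
#' once, under their primitive period (a poly-A run is one mononucleotide
#' locus, never a dinucleotide "AA" locus); partial trailing repeats are
#' trimmed, so `length == period * repeats`.  Arrays never extend across
#' non-ACGT characters; lowercase (soft-masked) bases are treated as their
#' uppercase equivalents.
#'
#' @param sequence DNA string (character scalar or
#'   [Biostrings::DNAString-class]); may contain N and lowercase.
#' @param seqId sequence identifier recorded in the output.
#' @param thresholds named integer vector from [miningThresholds()].
#' @return data.frame with columns seqid, start, end (1-based inclusive),
#'   motif (as found on the forward strand), motif_class (canonical),
#'   period, repeats, length; sorted by start, then period.
#' @examples
#' findSSRs(paste0("GGG", strrep("A", 10), "GGG"), "chr1")
#' @export
findSSRs <- function(sequence, seqId = "seq1",
                     thresholds = miningThresholds()) {
  if (is(sequence, "XString")) sequence <- as.character(sequence)
  if (!is.character(sequence) || length(sequence) != 1L || nchar(sequence) == 0L)
    stop("empty input: sequence must be a non-empty DNA string")
  if (!is.character(seqId) || length(seqId) != 1L)
    stop("seqId must be a single string")
  if (!identical(sort(names(thresholds)), as.character(1:6)))
    stop("thresholds must be named '1'..'6'; see miningThresholds()")
  s <- toupper(sequence)
  n <- nchar(s)
  raw <- charToRaw(s)
  valid <- raw == charToRaw("A") | raw == charToRaw("C") |
    raw == charToRaw("G") | raw == charToRaw("T")

  out <- vector("list", 6L)
  for (p in 1:6) {
    thr <- thresholds[[as.character(p)]]
    if (n < p * thr) next
    idx <- seq_len(n - p)
    eq <- raw[idx] == raw[idx + p] & valid[idx] & valid[idx + p]
    r <- rle(eq)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    keep <- r$values & (r$lengths + p) %/% p >= thr
    if (!any(keep)) next
    a <- starts[keep]
    reps <- (r$lengths[keep] + p) %/% p
    motif <- substring(s, a, a + p - 1L)
    prim <- vapply(motif, isPrimitiveMotif, NA, USE.NAMES = FALSE)
    if (!any(prim)) next
    a <- a[prim]; reps <- reps[prim]; motif <- motif[prim]
    out[[p]] <- data.frame(
      seqid = seqId, start = a, end = a + p * reps - 1L,
      motif = motif, motif_class = canonicalMotif(motif),
      period = p, repeats = reps, length = p * reps,
      stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out[!vapply(out, is.null, NA)])
  if (is.null(res))
    res <- data.frame(seqid = character(), start = integer(),
                      end = integer(), motif = character(),
                      motif_class = character(), period = integer(),
                      repeats = integer(), length = integer(),
                      stringsAsFactors = FALSE)
  res <- res[order(res$start, res$period), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Mine SSRs from a multi-record genome
#'
#' Applies [findSSRs()] to every record of a genome and returns the loci as
#' a [GenomicRanges::GRanges-class] with motif annotation.
#'
#' @param seqs named character vector or
#'   [Biostrings::DNAStringSet-class] of chromosome/scaffold sequences.
#' @param thresholds see [miningThresholds()].
#' @return `GRanges` (1-based inclusive) with metadata columns motif,
#'   motif_class, period, repeats; `seqlengths` set from the input.
#' @export
mineSSRs <- function(seqs, thresholds = miningThresholds()) {
  if (is(seqs, "DNAStringSet")) seqs <- as.character(seqs)
  if (is.null(names(seqs)) || anyDuplicated(names(seqs)))
    stop("sequences must carry unique names")
  tabs <- lapply(names(seqs), function(id)
    findSSRs(seqs[[id]], id, thresholds))
  tab <- do.call(rbind, tabs)
  gr <- GenomicRanges::GRanges(
    seqnames = tab$seqid,
    ranges = IRanges::IRanges(start = tab$start, end = tab$end),
    motif = tab$motif, motif_class = tab$motif_class,
    period = tab$period, repeats = tab$repeats,
    seqlengths = setNames(nchar(seqs), names(seqs)))
  gr
}

#' Total genome size used as the abundance/density denominator
#'
#' @param seqs named character vector or DNAStringSet.
#' @param excludeN drop non-ACGT characters from the total when `TRUE`
#'   (default counts them, i.e. the full assembly span is the denominator).
#' @return total length in bp.
#' @export
genomeSize <- function(seqs, excludeN = FALSE) {
  if (is(seqs, "DNAStringSet")) seqs <- as.character(seqs)
  if (!excludeN) return(sum(nchar(seqs)))
  sum(vapply(seqs, function(s)
    sum(strsplit(toupper(s), "")[[1]] %in% c("A", "C", "G", "T")),
    0L, USE.NAMES = FALSE))
}

#' Percentage share of each period class
#'
#' @param counts named numeric vector of locus counts (names = period).
#' @return percentages summing to 100.
#' @export
periodProportions <- function(counts) {
  if (sum(counts) == 0) stop("degenerate input: zero loci")
  100 * counts / sum(counts)
}

#' Genome-wide SSR summary statistics
#'
#' @param loci `GRanges` from [mineSSRs()] or data.frame from [findSSRs()].
#' @param seqLengths named vector of sequence lengths in bp; every locus
#'   seqid must appear.  Typically `genomeSize()` components or
#'   `seqlengths(gr)`.
#' @return An object of class `"MiningSummary"`: a list with
#'   countsByPeriod, totalCount, totalLengthBp, meanLengthBp,
#'   relativeAbundance (loci/Mb), relativeDensity (bp/Mb),
#'   perSequenceCounts, motifClassFrequencies (data.frame period, class,
#'   count, proportion within period) and lengthCountCorrelation (Pearson r
#'   between per-sequence SSR count and sequence length; `NA` with fewer
#'   than 3 sequences).
#' @export
summarizeSSRs <- function(loci, seqLengths) {
  if (is(loci, "GRanges")) {
    tab <- data.frame(seqid = as.character(GenomicRanges::seqnames(loci)),
                      length = GenomicRanges::width(loci),
                      period = loci$period,
                      motif_class = loci$motif_class,
                      stringsAsFactors = FALSE)
  } else {
    tab <- loci
  }
  if (is.null(names(seqLengths)))
    stop("seqLengths must be a named vector")
  if (!all(tab$seqid %in% names(seqLengths)))
    stop("every locus seqid must appear in seqLengths")
  genomeMb <- sum(as.numeric(seqLengths)) / 1e6
  if (genomeMb <= 0) stop("degenerate input: zero total genome length")

  countsByPeriod <- setNames(
    vapply(1:6, function(p) sum(tab$period == p), 0), as.character(1:6))
  totalCount <- nrow(tab)
  totalLengthBp <- sum(tab$length)

  perSeq <- setNames(numeric(length(seqLengths)), names(seqLengths))
  tc <- table(tab$seqid)
  perSeq[names(tc)] <- as.numeric(tc)

  mc <- if (totalCount > 0) {
    agg <- as.data.frame(table(period = tab$period, class = tab$motif_class),
                         stringsAsFactors = FALSE)
    agg <- agg[agg$Freq > 0, , drop = FALSE]
    agg$period <- as.integer(agg$period)
    names(agg)[3] <- "count"
    agg$proportion <- agg$count /
      ave(agg$count, agg$period, FUN = sum)
    agg[order(agg$period, -agg$count), , drop = FALSE]
  } else {
    data.frame(period = integer(), class = character(), count = integer(),
               proportion = numeric())
  }
  rownames(mc) <- NULL

  r <- if (length(seqLengths) >= 3)
    cor(perSeq, as.numeric(seqLengths)) else NA_real_

  structure(list(
    countsByPeriod = countsByPeriod,
    totalCount = totalCount,
    totalLengthBp = totalLengthBp,
    meanLengthBp = if (totalCount > 0) totalLengthBp / totalCount else NA_real_,
    relativeAbundance = totalCount / genomeMb,
    relativeDensity = totalLengthBp / genomeMb,
    perSequenceCounts = perSeq,
    motifClassFrequencies = mc,
    lengthCountCorrelation = r), class = "MiningSummary")
}

#' @export
print.MiningSummary <- function(x, ...) {
  cat("SSR mining summary\n")
  cat(sprintf("  total loci: %d  (total %.0f bp, mean %.1f bp)\n",
              x$totalCount, x$totalLengthBp, x$meanLengthBp))
  cat(sprintf("  relative abundance: %.2f loci/Mb, density: %.2f bp/Mb\n",
              x$relativeAbundance, x$relativeDensity))
  pct <- periodProportions(x$countsByPeriod)
  cat("  by period:", paste(sprintf("%s:%d (%.2f%%)",
                                    names(pct), x$countsByPeriod, pct),
                            collapse = "  "), "\n")
  if (!is.na(x$lengthCountCorrelation))
    cat(sprintf("  count-vs-length Pearson r = %.3f\n",
                x$lengthCountCorrelation))
  invisible(x)
}
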