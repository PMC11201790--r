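#' Cross-species primer matching rules
#'
#' Operationalizes the usual in-silico transferability screen: up to five
#' mismatches in the 5' part of a primer, none inside a fixed-length 3'
#' anchor, at least 90% overall identity per primer, and a cap on the
#' amplicon size.
#'
#' @param max5primeMismatches maximum mismatches outside the 3' anchor.
#' @param threePrimeAnchorBp anchor length at the 3' end with zero
#'   mismatches allowed.
#' @param minIdentity minimum per-primer identity fraction (0, 1].
#' @param maxProductBp maximum amplicon length in bp.
#' @return list of class `"MatchRules"`.
#' @export
matchRules <- function(max5primeMismatches = 5L, threePrimeAnchorBp = 5L,
                       minIdentity = 0.90, maxProductBp = 2000L) {
  if (threePrimeAnchorBp < 1) stop("anchor must be >= 1 bp")
  if (minIdentity <= 0 || minIdentity > 1)
    stop("minIdentity must be in (0, 1]")
  structure(list(max5primeMismatches = as.integer(max5primeMismatches),
                 threePrimeAnchorBp = as.integer(threePrimeAnchorBp),
                 minIdentity = minIdentity,
                 maxProductBp = as.integer(maxProductBp)),
            class = "MatchRules")
}

# Ungapped placements of one primer on the + strand of `target`.
# With revcomp = TRUE the reverse complement of the primer is the pattern,
# so the primer's 3' anchor maps to the *first* pattern positions.
.primerHits <- function(primer, target, rules, revcomp = FALSE) {
  primer <- toupper(primer)
  len <- nchar(primer)
  pattern <- if (revcomp) .revcompChr(primer) else primer
  maxTotal <- floor(len * (1 - rules$minIdentity))
  allow <- min(rules$max5primeMismatches, maxTotal)
  hits <- Biostrings::matchPattern(pattern, Biostrings::DNAString(target),
                                   max.mismatch = allow, with.indels = FALSE)
  if (length(hits) == 0)
    return(data.frame(start = integer(), end = integer(),
                      mismatches = integer()))
  patRaw <- charToRaw(pattern)
  anchorIdx <- if (revcomp) seq_len(rules$threePrimeAnchorBp)
               else seq(len - rules$threePrimeAnchorBp + 1L, len)
  st <- BiocGenerics::start(hits)
  keep <- logical(length(st))
  mm <- integer(length(st))
  for (h in seq_along(st)) {
    hitRaw <- charToRaw(substr(target, st[h], st[h] + len - 1L))
    bad <- patRaw != hitRaw
    mm[h] <- sum(bad)
    keep[h] <- !any(bad[anchorIdx])
  }
  data.frame(start = st[keep], end = st[keep] + len - 1L,
             mismatches = mm[keep])
}

#' Electronic PCR of one primer pair against a target sequence
#'
#' Finds every convergent placement of the pair on either strand where each
#' primer aligns ungapped with at most `max5primeMismatches` outside its 3'
#' anchor, zero mismatches inside the anchor, per-primer identity at least
#' `minIdentity`, and product length at most `maxProductBp`.
#'
#' @param pair single-row data.frame (or list) with `left_seq` and
#'   `right_seq` (both written 5'->3'), optionally `marker_id`.
#' @param target target DNA string.
#' @param targetId identifier recorded in the output.
#' @param rules a [matchRules()] object.
#' @return data.frame of amplicons: marker_id, target_seq_id, start, end
#'   (1-based inclusive), strand of the left primer, product_bp,
#'   left_mismatches, right_mismatches.  Zero rows when nothing amplifies.
#' @export
epcr <- function(pair, target, targetId = "target",
                 rules = matchRules()) {
  if (is(target, "XString")) target <- as.character(target)
  target <- toupper(target)
  if (nchar(target) == 0) stop("target must be non-empty")
  marker <- if (!is.null(pair$marker_id)) as.character(pair$marker_id)
            else "marker1"

  amp <- function(fwdHits, rcHits, fwdMmIsLeft, strand) {
    if (nrow(fwdHits) == 0 || nrow(rcHits) == 0) return(NULL)
    combo <- expand.grid(f = seq_len(nrow(fwdHits)), r = seq_len(nrow(rcHits)))
    s1 <- fwdHits$start[combo$f]; e2 <- rcHits$end[combo$r]
    s2 <- rcHits$start[combo$r]; e1 <- fwdHits$end[combo$f]
    product <- e2 - s1 + 1L
    ok <- s2 >= s1 & e2 >= e1 & product <= rules$maxProductBp
    if (!any(ok)) return(NULL)
    combo <- combo[ok, , drop = FALSE]; product <- product[ok]
    data.frame(
      marker_id = marker, target_seq_id = targetId,
      start = fwdHits$start[combo$f], end = rcHits$end[combo$r],
      strand = strand, product_bp = product,
      left_mismatches = if (fwdMmIsLeft) fwdHits$mismatches[combo$f]
                        else rcHits$mismatches[combo$r],
      right_mismatches = if (fwdMmIsLeft) rcHits$mismatches[combo$r]
                         else fwdHits$mismatches[combo$f],
      stringsAsFactors = FALSE)
  }

  leftF <- .primerHits(pair$left_seq, target, rules, revcomp = FALSE)
  rightR <- .primerHits(pair$right_seq, target, rules, revcomp = TRUE)
  rightF <- .primerHits(pair$right_seq, target, rules, revcomp = FALSE)
  leftR <- .primerHits(pair$left_seq, target, rules, revcomp = TRUE)

  out <- rbind(amp(leftF, rightR, TRUE, "+"),
               amp(rightF, leftR, FALSE, "-"))
  if (is.null(out))
    out <- data.frame(marker_id = character(), target_seq_id = character(),
                      start = integer(), end = integer(),
                      strand = character(), product_bp = integer(),
                      left_mismatches = integer(),
                      right_mismatches = integer(),
                      stringsAsFactors = FALSE)
  out[order(out$start, out$end), , drop = FALSE]
}

#' Run e-PCR for a primer table against a multi-record genome
#'
#' @param primers data.frame with marker_id, left_seq, right_seq rows.
#' @param targets named character vector or DNAStringSet.
#' @param rules a [matchRules()] object.
#' @return row-bound amplicon data.frame (see [epcr()]).
#' @export
epcrGenome <- function(primers, targets, rules = matchRules()) {
  if (is(targets, "DNAStringSet")) targets <- as.character(targets)
  res <- list()
  for (i in seq_len(nrow(primers))) {
    for (id in names(targets)) {
      res[[length(res) + 1L]] <-
        epcr(primers[i, , drop = FALSE], targets[[id]], id, rules)
    }
  }
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Synteny links from cross-species amplicons
#'
#' Applies the published post-filters: amplicons on scaffold-like target
#' sequences are dropped, markers whose source locus sits on a scaffold are
#' dropped, and multiple amplicons of one marker on one target chromosome
#' are collapsed to the best placement (fewest total mismatches, then
#' smallest start), so each marker contributes at most one link per target
#' chromosome.
#'
#' @param amplicons data.frame from [epcr()]/[epcrGenome()].
#' @param sourceLoci data.frame with one row per marker: marker_id, seqid,
#'   start, end of the source SSR locus.
#' @param scaffoldPattern regular expression flagging scaffold IDs
#'   (matched case-insensitively against both endpoints).
#' @return list with `links` (source_chr, source_start, source_end,
#'   target_chr, target_start, target_end, marker_id; sorted) and
#'   `pairCounts` (source_chr, target_chr, n_links).
#' @export
buildSyntenyLinks <- function(amplicons, sourceLoci,
                              scaffoldPattern = "scaffold") {
  unknown <- setdiff(amplicons$marker_id, sourceLoci$marker_id)
  if (length(unknown))
    stop("consistency error: amplicon markers without a source locus: ",
         paste(head(unknown, 5), collapse = ", "))
  src <- sourceLoci[match(amplicons$marker_id, sourceLoci$marker_id), ,
                    drop = FALSE]
  keep <- !grepl(scaffoldPattern, amplicons$target_seq_id,
                 ignore.case = TRUE) &
          !grepl(scaffoldPattern, src$seqid, ignore.case = TRUE)
  amplicons <- amplicons[keep, , drop = FALSE]
  src <- src[keep, , drop = FALSE]
  empty <- data.frame(source_chr = character(), source_start = integer(),
                      source_end = integer(), target_chr = character(),
                      target_start = integer(), target_end = integer(),
                      marker_id = character(), stringsAsFactors = FALSE)
  if (nrow(amplicons) == 0)
    return(list(links = empty,
                pairCounts = data.frame(source_chr = character(),
                                        target_chr = character(),
                                        n_links = integer())))
  totalMm <- amplicons$left_mismatches + amplicons$right_mismatches
  key <- paste(amplicons$marker_id, amplicons$target_seq_id, sep = "\r")
  ord <- order(key, totalMm, amplicons$start)
  best <- ord[!duplicated(key[ord])]

  links <- data.frame(
    source_chr = src$seqid[best],
    source_start = src$start[best],
    source_end = src$end[best],
    target_chr = amplicons$target_seq_id[best],
    target_start = amplicons$start[best],
    target_end = amplicons$end[best],
    marker_id = amplicons$marker_id[best],
    stringsAsFactors = FALSE)
  links <- links[order(links$source_chr, links$source_start,
                       links$target_chr), , drop = FALSE]
  rownames(links) <- NULL

  counts <- as.data.frame(table(source_chr = links$source_chr,
                                target_chr = links$target_chr),
                          stringsAsFactors = FALSE)
  counts <- counts[counts$Freq > 0, , drop = FALSE]
  names(counts)[3] <- "n_links"
  counts <- counts[order(counts$source_chr, counts$target_chr), ,
                   drop = FALSE]
  rownames(counts) <- NULL
  list(links = links, pairCounts = counts)
}
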