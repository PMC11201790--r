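# Independent quadratic scanner for perfect tandem repeats: tests every
# (start, period, extension) triple directly on the character vector.
# Reports each maximal array once, from its left-maximal start, trimmed to
# complete repeats, classified by primitive motif.
bruteForceSSRs <- function(sequence, thresholds = miningThresholds()) {
  s <- toupper(sequence)
  n <- nchar(s)
  ch <- strsplit(s, "")[[1]]
  ok <- ch %in% c("A", "C", "G", "T")
  rows <- list()
  for (p in 1:6) {
    thr <- thresholds[[as.character(p)]]
    if (n < p * thr) next
    for (start in seq_len(n - p * thr + 1L)) {
      motif <- ch[start:(start + p - 1L)]
      if (!all(ok[start:(start + p - 1L)])) next
      # left-maximality: the base before `start` must not extend the period
      if (start > 1L && ok[start - 1L] &&
          ch[start - 1L] == ch[start + p - 1L]) next
      motifStr <- paste(motif, collapse = "")
      if (!isPrimitiveMotif(motifStr)) next
      k <- 1L
      while (start + (k + 1L) * p - 1L <= n &&
             all(ch[(start + k * p):(start + (k + 1L) * p - 1L)] == motif)) {
        k <- k + 1L
      }
      if (k >= thr) {
        rows[[length(rows) + 1L]] <-
          data.frame(start = start, end = start + p * k - 1L,
                     motif = motifStr, period = p, repeats = k,
                     stringsAsFactors = FALSE)
      }
    }
  }
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(start = integer(), end = integer(),
                      motif = character(), period = integer(),
                      repeats = integer(), stringsAsFactors = FALSE)
  out[order(out$start, out$period), , drop = FALSE]
}

randomDNA <- function(n, gc = 0.4) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

# drop rownames/classes so locus tables from different scanners compare
lociKey <- function(df) {
  df <- df[order(df$start, df$period), c("start", "end", "motif",
                                         "period", "repeats")]
  rownames(df) <- NULL
  df
}

revcompStr <- function(s) {
  paste(rev(strsplit(chartr("ACGT", "TGCA", toupper(s)), "")[[1]]),
        collapse = "")
}
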