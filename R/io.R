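#' Read a co-dominant genotype TSV
#'
#' Expected layout: a header row `individual<TAB>marker1<TAB>...`, one row
#' per individual, cells `"a/b"` allele pairs with `"./."` for missing.
#' Ragged rows, duplicate IDs and malformed cells raise errors naming the
#' offending line and column.
#'
#' @param path file path.
#' @return A [GenotypeMatrix-class].
#' @export
readGenotypeTable <- function(path) {
  lines <- readLines(path)
  if (length(lines) < 2) stop("parse error: need a header and >= 1 row")
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf != nf[1]))
    stop("parse error: ragged row at line ",
         which(nf != nf[1])[1])
  hdr <- fields[[1]][-1]
  if (anyDuplicated(hdr)) stop("parse error: duplicate marker IDs in header")
  ids <- vapply(fields[-1], `[`, "", 1L)
  if (anyDuplicated(ids))
    stop("parse error: duplicate individual ID at line ",
         which(duplicated(ids))[1] + 1L)
  calls <- t(vapply(fields[-1], function(f) f[-1], character(length(hdr))))
  if (length(hdr) == 1L) calls <- matrix(calls, ncol = 1L)
  dimnames(calls) <- list(ids, hdr)
  missing <- calls == "./." | calls == "" | calls == "NA"
  bad <- !missing & !grepl("^[^/[:space:]]+/[^/[:space:]]+$", calls)
  if (any(bad)) {
    w <- which(bad, arr.ind = TRUE)[1, ]
    stop(sprintf("parse error: malformed cell '%s' at line %d, column %d",
                 calls[w[1], w[2]], w[1] + 1L, w[2] + 1L))
  }
  calls[missing] <- NA
  genotypeMatrix(calls)
}

#' Write a genotype TSV (inverse of [readGenotypeTable()])
#' @param x a [GenotypeMatrix-class].
#' @param path file path.
#' @export
writeGenotypeTable <- function(x, path) {
  calls <- genotypeCalls(x)
  calls[is.na(calls)] <- "./."
  df <- data.frame(individual = rownames(calls), calls,
                   check.names = FALSE, stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

# loci input for the writers: GRanges from mineSSRs() or data.frame from
# findSSRs(); normalize to the data.frame form
.lociFrame <- function(loci) {
  if (is(loci, "GRanges")) {
    data.frame(seqid = as.character(GenomicRanges::seqnames(loci)),
               start = BiocGenerics::start(loci),
               end = BiocGenerics::end(loci),
               motif = loci$motif, motif_class = loci$motif_class,
               period = loci$period, repeats = loci$repeats,
               stringsAsFactors = FALSE)
  } else loci
}

#' Write SSR loci as GFF3
#'
#' One `microsatellite` feature per locus, 1-based inclusive coordinates,
#' with `motif`, `motif_class` and `repeats` attributes; stable ordering
#' for byte-identical reruns.
#'
#' @param loci `GRanges` from [mineSSRs()] or data.frame from [findSSRs()].
#' @param path file path.
#' @export
writeLociGFF3 <- function(loci, path) {
  tab <- .lociFrame(loci)
  con <- file(path, "w"); on.exit(close(con))
  writeLines("##gff-version 3", con)
  if (nrow(tab)) {
    tab <- tab[order(tab$seqid, tab$start, tab$period), , drop = FALSE]
    writeLines(sprintf(
      "%s\tSSRtools\tmicrosatellite\t%d\t%d\t.\t+\t.\tID=ssr%d;motif=%s;motif_class=%s;repeats=%d",
      tab$seqid, tab$start, tab$end, seq_len(nrow(tab)),
      tab$motif, tab$motif_class, tab$repeats), con)
  }
  invisible(path)
}

#' Write SSR loci as BED (0-based half-open)
#' @inheritParams writeLociGFF3
#' @export
writeLociBED <- function(loci, path) {
  tab <- .lociFrame(loci)
  tab <- tab[order(tab$seqid, tab$start, tab$period), , drop = FALSE]
  bed <- data.frame(tab$seqid, tab$start - 1L, tab$end,
                    paste0(tab$motif_class, "x", tab$repeats))
  write.table(bed, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Write a Newick file
#' @param tree an [upgma()] result (or any list with a `newick` string).
#' @param path file path.
#' @export
writeNewick <- function(tree, path) {
  writeLines(tree$newick, path)
  invisible(path)
}

#' Write a Circos-compatible synteny link file
#'
#' Columns: source_chr source_start source_end target_chr target_start
#' target_end marker_id (tab-separated, no header, sorted rows).
#'
#' @param links data.frame from [buildSyntenyLinks()]`$links`.
#' @param path file path.
#' @export
writeLinks <- function(links, path) {
  write.table(links[, c("source_chr", "source_start", "source_end",
                        "target_chr", "target_start", "target_end",
                        "marker_id")],
              path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Write / read a primer table TSV
#' @param primers data.frame from [designPrimers()] (plus a marker_id
#'   column when designing for many loci).
#' @param path file path.
#' @export
writePrimerTable <- function(primers, path) {
  write.table(primers, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname writePrimerTable
#' @export
readPrimerTable <- function(path) {
  read.delim(path, stringsAsFactors = FALSE)
}

#' Read a trait table TSV (individual ID column + one column per trait)
#' @param path file path.
#' @return data.frame with an `individual` column.
#' @export
readTraitTable <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  if (!"individual" %in% names(df))
    stop("trait table needs an 'individual' column")
  df
}

#' Default pipeline configuration
#'
#' Every stage's tunable parameters in one nested list, suitable for YAML
#' round-tripping with [writePipelineConfig()] / [readPipelineConfig()].
#'
#' @return nested named list.
#' @export
defaultPipelineConfig <- function() {
  list(
    seed = 1,
    mining = list(min_mono = 10, min_di = 6, min_tri = 5, min_tetra = 5,
                  min_penta = 5, min_hexa = 5, exclude_n = FALSE),
    primers = list(product_bp = c(100, 250), primer_len = c(18, 24),
                   tm_celsius = c(50, 60), gc_percent = c(40, 60),
                   max_tm_diff = 3, max_candidates = 3),
    transfer = list(max_5prime_mismatches = 5, three_prime_anchor_bp = 5,
                    min_identity = 0.9, max_product_bp = 2000,
                    scaffold_pattern = "scaffold"),
    clustering = list(method = "simple_matching"),
    structure = list(burn_in = 1000, main_iterations = 10000,
                     replicates = 10, k_min = 1, k_max = 10,
                     alpha = 1, lambda = 1),
    association = list(model = "both", coding = "genotype"))
}

#' @rdname defaultPipelineConfig
#' @param config a configuration list (defaults from
#'   [defaultPipelineConfig()] with any overrides).
#' @param path file path.
#' @export
writePipelineConfig <- function(config, path) {
  yaml::write_yaml(config, path)
  invisible(path)
}

#' @rdname defaultPipelineConfig
#' @export
readPipelineConfig <- function(path) {
  cfg <- yaml::read_yaml(path)
  ref <- defaultPipelineConfig()
  checkKeys <- function(got, want, where) {
    extra <- setdiff(names(got), names(want))
    if (length(extra))
      stop("unknown configuration key", if (length(extra) > 1) "s" else "",
           " at ", where, ": ", paste(extra, collapse = ", "))
    for (nm in names(got)) {
      if (is.list(want[[nm]]) && !is.null(names(want[[nm]])))
        checkKeys(got[[nm]], want[[nm]], paste0(where, "$", nm))
    }
  }
  checkKeys(cfg, ref, "config")
  utils::modifyList(ref, cfg)
}
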