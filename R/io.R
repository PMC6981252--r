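# Readers and writers for the pipeline's plain-text interchange formats.
# Matrices travel as TSV with probe_id in the first column; interval tracks
# as BED (0-based half-open) through rtracklayer; sets as one id per line.

#' Write / read a probe x sample matrix as TSV
#'
#' First column \code{probe_id}, remaining columns sample ids.
#' @param x numeric matrix with rownames.
#' @param path file path.
#' @export
write_matrix_tsv <- function(x, path) {
  df <- data.frame(probe_id = rownames(x), as.data.frame(x),
                   check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_matrix_tsv
#' @export
read_matrix_tsv <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  m
}

#' Write / read an interval track as BED
#'
#' Intervals are held internally as data.frames in BED convention (0-based
#' half-open \code{start}/\code{end}); the optional \code{state} column
#' becomes the BED name field (chromHMM mnemonics).
#' @param df data.frame with \code{chrom}, \code{start}, \code{end} and
#'   optionally \code{state}.
#' @param path file path.
#' @export
write_bed <- function(df, path) {
  gr <- GenomicRanges::GRanges(
    seqnames = df$chrom,
    ranges = IRanges::IRanges(start = df$start + 1L, end = df$end))
  if (!is.null(df$state)) gr$name <- df$state
  rtracklayer::export(gr, path, format = "BED")
  invisible(path)
}

#' @rdname write_bed
#' @export
read_bed <- function(path) {
  gr <- rtracklayer::import(path, format = "BED")
  out <- data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
                    start = GenomicRanges::start(gr) - 1L,
                    end = GenomicRanges::end(gr))
  nm <- gr$name
  if (!is.null(nm)) out$state <- nm
  out
}

#' Export DMRs as BED6
#'
#' 0-based half-open intervals spanning the member CpG positions; the score
#' is \code{-10 log10(min adjusted p)} capped at 1000; strand ".".
#' @param dmrs a \code{dmr_set}.
#' @param path file path.
#' @export
write_dmr_bed <- function(dmrs, path) {
  if (nrow(dmrs) == 0L) {
    writeLines(character(0), path)
    return(invisible(path))
  }
  gr <- GenomicRanges::GRanges(
    seqnames = dmrs$chrom,
    ranges = IRanges::IRanges(start = dmrs$start, end = dmrs$end),
    name = sprintf("DMR%d", seq_len(nrow(dmrs))),
    score = pmin(1000, round(-10 * log10(pmax(dmrs$min_p_adj, 1e-300)))))
  rtracklayer::export(gr, path, format = "BED")
  invisible(path)
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write / read a truth set as JSON
#' @param truth a \code{truth_set}.
#' @param path file path.
#' @export
write_truth_json <- function(truth, path) {
  x <- unclass(truth)
  x$planted_direction <- as.list(x$planted_direction)
  x$planted_effect <- as.list(x$planted_effect)
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_truth_json
#' @export
read_truth_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  x$planted_direction <- unlist(x$planted_direction)
  x$planted_effect <- unlist(x$planted_effect)
  if (!is.null(x$planted_dmr_regions)) {
    x$planted_dmr_regions <- as.data.frame(x$planted_dmr_regions)
  }
  structure(x, class = "truth_set")
}
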