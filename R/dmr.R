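#' Merge significant CpGs into differentially methylated regions
#'
#' Per chromosome, sorts the significant probes by position and greedily
#' extends a run while the gap between consecutive significant CpGs is at
#' most \code{max_gap} bp; maximal runs with at least \code{min_cpgs}
#' members become DMRs. "Separation" is the distance between consecutive
#' significant CpG positions, not the region span. Hypo- and
#' hyper-methylated CpGs may share a region; the mean beta change reports
#' the net direction.
#'
#' @param dmls a \code{dml_calls} data.frame (or any data.frame with
#'   \code{probe_id}, \code{significant}, \code{delta_beta}, \code{p_adj}).
#' @param manifest probe manifest with \code{probe_id}, \code{chrom},
#'   \code{pos} (1-based).
#' @param max_gap maximum separation between consecutive member CpGs, bp.
#' @param min_cpgs minimum number of member CpGs per region (default 2,
#'   i.e. ">1 differentially methylated CpG").
#' @return data.frame of class \code{dmr_set}, sorted by (chrom, start):
#'   \code{chrom}, \code{start}, \code{end} (positions of the first/last
#'   member CpG, 1-based inclusive), \code{n_probes}, \code{mean_delta_beta},
#'   \code{min_p_adj}, \code{probes} (comma-separated ids in position order).
#' @export
call_dmrs <- function(dmls, manifest, max_gap = 1000L, min_cpgs = 2L) {
  sig <- dmls[dmls$significant, , drop = FALSE]
  empty <- data.frame(chrom = character(0), start = integer(0),
                      end = integer(0), n_probes = integer(0),
                      mean_delta_beta = numeric(0), min_p_adj = numeric(0),
                      probes = character(0))
  class(empty) <- c("dmr_set", "data.frame")
  if (nrow(sig) == 0L) return(empty)
  mi <- match(sig$probe_id, manifest$probe_id)
  if (anyNA(mi)) {
    stop("probe(s) absent from manifest: ",
         paste(utils::head(sig$probe_id[is.na(mi)], 5L), collapse = ", "),
         call. = FALSE)
  }
  sig$chrom <- manifest$chrom[mi]
  sig$pos <- manifest$pos[mi]
  out <- list()
  for (chr in sort(unique(sig$chrom))) {
    s <- sig[sig$chrom == chr, , drop = FALSE]
    s <- s[order(s$pos), , drop = FALSE]
    run_break <- c(TRUE, diff(s$pos) > max_gap)
    run_id <- cumsum(run_break)
    for (r in split(seq_len(nrow(s)), run_id)) {
      if (length(r) < min_cpgs) next
      out[[length(out) + 1L]] <- data.frame(
        chrom = chr, start = s$pos[r[1]], end = s$pos[r[length(r)]],
        n_probes = length(r), mean_delta_beta = mean(s$delta_beta[r]),
        min_p_adj = min(s$p_adj[r]),
        probes = paste(s$probe_id[r], collapse = ","))
    }
  }
  if (!length(out)) return(empty)
  res <- do.call(rbind, out)
  res <- res[order(res$chrom, res$start), , drop = FALSE]
  rownames(res) <- NULL
  class(res) <- c("dmr_set", "data.frame")
  res
}

#' @export
print.dmr_set <- function(x, ...) {
  cat(sprintf("DMRs: %d region(s)", nrow(x)))
  if (nrow(x)) {
    cat(sprintf(", %d-%d CpGs each, median span %d bp",
                min(x$n_probes), max(x$n_probes),
                as.integer(stats::median(x$end - x$start))))
  }
  cat("\n")
  if (nrow(x)) {
    print.data.frame(utils::head(
      x[, c("chrom", "start", "end", "n_probes", "mean_delta_beta",
            "min_p_adj")], 10L), row.names = FALSE)
    if (nrow(x) > 10L) cat("  ...", nrow(x) - 10L, "more\n")
  }
  invisible(x)
}
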