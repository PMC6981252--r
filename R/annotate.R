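#' CpG island relation: Island / Shore / Shelf / Open sea
#'
#' Classifies 1-based probe positions against a set of non-overlapping CpG
#' island intervals on the same chromosome. A probe inside an island is
#' "Island"; within 2 kb of the nearest island edge, "Shore"; within 2-4 kb,
#' "Shelf"; otherwise "OpenSea". Islands are given in BED convention
#' (0-based, half-open), so an island \code{[start, end)} covers 1-based
#' positions \code{start+1 .. end}.
#'
#' @param pos integer vector of 1-based positions.
#' @param islands data.frame with columns \code{start}, \code{end} (0-based
#'   half-open), sorted and non-overlapping; rows on one chromosome.
#' @param shore_bp,shelf_bp distance cutoffs in bp (defaults 2000 and 4000).
#' @return data.frame with columns \code{relation} (factor with levels
#'   Island, Shore, Shelf, OpenSea) and \code{distance} (bp to the nearest
#'   island edge; 0 inside an island, Inf when no islands exist).
#' @export
classify_island_relation <- function(pos, islands, shore_bp = 2000L,
                                     shelf_bp = 4000L) {
  lv <- c("Island", "Shore", "Shelf", "OpenSea")
  if (is.null(islands) || nrow(islands) == 0L) {
    return(data.frame(relation = factor(rep("OpenSea", length(pos)), levels = lv),
                      distance = rep(Inf, length(pos))))
  }
  s <- as.numeric(islands$start)
  e <- as.numeric(islands$end)
  if (is.unsorted(s, strictly = FALSE) || any(s[-1] < e[-length(e)])) {
    stop("validation error: islands must be sorted and non-overlapping",
         call. = FALSE)
  }
  if (any(e <= s)) stop("validation error: empty island interval", call. = FALSE)
  p0 <- as.numeric(pos) - 1           # 0-based coordinate of the base
  # index of the island starting at or before p0
  idx <- findInterval(p0, s)
  inside <- idx >= 1L & p0 < e[pmax(idx, 1L)]
  # distance to the island ending before p0 (gap in bp between base and edge)
  d_left <- ifelse(idx >= 1L, p0 - e[pmax(idx, 1L)] + 1, Inf)
  d_right <- ifelse(idx < length(s), s[pmin(idx + 1L, length(s))] - p0, Inf)
  dist <- pmin(pmax(d_left, 0), pmax(d_right, 0))
  dist[inside] <- 0
  relation <- ifelse(inside, "Island",
              ifelse(dist <= shore_bp, "Shore",
              ifelse(dist <= shelf_bp, "Shelf", "OpenSea")))
  data.frame(relation = factor(relation, levels = lv), distance = dist)
}

#' Detect CpG islands in a nucleotide sequence
#'
#' Slides a fixed window over the sequence and scores each window by the
#' observed/expected CpG ratio, O/E = (#CG dinucleotides x window length) /
#' (#C x #G), taken as 0 when #C or #G is 0. Qualifying windows
#' (O/E > \code{oe_min}) are unioned into maximal runs; runs longer than
#' \code{min_len} bp are reported as islands in BED convention (0-based,
#' half-open). No GC-content criterion is applied.
#'
#' @param seq single character string over A, C, G, T, N.
#' @param min_len minimum island length in bp (strict >).
#' @param oe_min minimum observed/expected CpG ratio (strict >).
#' @param window window length in bp.
#' @param step window step in bp.
#' @return data.frame with columns \code{start}, \code{end} (0-based
#'   half-open) and \code{oe} (mean window O/E over the merged run).
#' @export
detect_islands <- function(seq, min_len = 200L, oe_min = 0.60,
                           window = 200L, step = 1L) {
  empty <- data.frame(start = integer(0), end = integer(0), oe = numeric(0))
  n <- nchar(seq)
  if (n < window) return(empty)
  ch <- strsplit(toupper(seq), "", fixed = TRUE)[[1]]
  isC <- ch == "C"
  isG <- ch == "G"
  isCG <- c(isC[-n] & isG[-1], FALSE)
  cumC <- cumsum(isC); cumG <- cumsum(isG); cumCG <- cumsum(isCG)
  starts <- seq.int(1L, n - window + 1L, by = step)
  ends <- starts + window - 1L
  nC <- cumC[ends] - ifelse(starts > 1L, cumC[starts - 1L], 0)
  nG <- cumG[ends] - ifelse(starts > 1L, cumG[starts - 1L], 0)
  # dinucleotides fully inside the window start at positions start..end-1
  nCG <- cumCG[ends - 1L] - ifelse(starts > 1L, cumCG[starts - 1L], 0)
  oe <- ifelse(nC * nG > 0, nCG * window / (nC * nG), 0)
  ok <- oe > oe_min
  if (!any(ok)) return(empty)
  # union of qualifying windows, merged while overlapping or adjacent
  ws <- starts[ok] - 1L   # 0-based
  we <- ends[ok]          # half-open end
  keep_oe <- oe[ok]
  run_start <- ws[1]; run_end <- we[1]; acc <- keep_oe[1]; cnt <- 1L
  out <- list()
  if (length(ws) > 1L) {
    for (i in 2:length(ws)) {
      if (ws[i] <= run_end) {
        run_end <- max(run_end, we[i]); acc <- acc + keep_oe[i]; cnt <- cnt + 1L
      } else {
        out[[length(out) + 1L]] <- c(run_start, run_end, acc / cnt)
        run_start <- ws[i]; run_end <- we[i]; acc <- keep_oe[i]; cnt <- 1L
      }
    }
  }
  out[[length(out) + 1L]] <- c(run_start, run_end, acc / cnt)
  m <- do.call(rbind, out)
  res <- data.frame(start = as.integer(m[, 1]), end = as.integer(m[, 2]),
                    oe = m[, 3])
  res[res$end - res$start > min_len, , drop = FALSE]
}

#' The 15-state chromHMM mnemonics and their five-category collapse
#'
#' Roadmap 15-state mnemonics are collapsed into five functional categories:
#' TSS (TssA, TssBiv), FlankingTSS (TssAFlnk, BivFlnk), Transcribed (Tx,
#' TxFlnk, TxWk), Enhancer (Enh, EnhG, EnhBiv) and Repressed (ZNF/Rpts, Het,
#' ReprPC, ReprPCWk, Quies).
#'
#' @return named character vector mapping mnemonic to category.
#' @export
chromhmm_collapse_map <- function() {
  c(TssA = "TSS", TssBiv = "TSS",
    TssAFlnk = "FlankingTSS", BivFlnk = "FlankingTSS",
    Tx = "Transcribed", TxFlnk = "Transcribed", TxWk = "Transcribed",
    Enh = "Enhancer", EnhG = "Enhancer", EnhBiv = "Enhancer",
    `ZNF/Rpts` = "Repressed", Het = "Repressed", ReprPC = "Repressed",
    ReprPCWk = "Repressed", Quies = "Repressed")
}

chromatin_categories <- function() {
  c("TSS", "FlankingTSS", "Transcribed", "Enhancer", "Repressed")
}

#' Map probe positions to chromatin states
#'
#' Looks up each 1-based position in a chromHMM segmentation given in BED
#' convention (0-based half-open): a segment \code{[start, end)} covers
#' 1-based positions \code{start+1 .. end}. Segments must tile the
#' chromosome without overlap; positions outside all segments are returned
#' as state \code{NA} / category "Unassigned" and are meant to be excluded
#' from enrichment denominators.
#'
#' @param pos integer vector of 1-based positions (one chromosome).
#' @param segments data.frame with columns \code{start}, \code{end}
#'   (0-based half-open) and \code{state} (15-state mnemonic), sorted.
#' @return data.frame with columns \code{state} and \code{category}.
#' @export
map_chromatin_state <- function(pos, segments) {
  if (nrow(segments) == 0L) {
    return(data.frame(state = rep(NA_character_, length(pos)),
                      category = rep("Unassigned", length(pos))))
  }
  s <- as.numeric(segments$start); e <- as.numeric(segments$end)
  o <- order(s)
  s <- s[o]; e <- e[o]; st <- as.character(segments$state)[o]
  if (any(s[-1] < e[-length(e)])) {
    stop("validation error: chromatin segments overlap", call. = FALSE)
  }
  bad <- setdiff(unique(st), names(chromhmm_collapse_map()))
  if (length(bad)) {
    stop("validation error: unknown chromHMM mnemonic(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  p0 <- as.numeric(pos) - 1
  idx <- findInterval(p0, s)
  hit <- idx >= 1L & p0 < e[pmax(idx, 1L)]
  state <- ifelse(hit, st[pmax(idx, 1L)], NA_character_)
  map <- chromhmm_collapse_map()
  category <- ifelse(is.na(state), "Unassigned", unname(map[state]))
  data.frame(state = state, category = category)
}

#' Assign a gene-feature class to probe positions
#'
#' Assigns each probe one of TSS200, TSS1500, 5'UTR, Body, 3'UTR or
#' Intergenic against a table of gene models, using the 450K manifest
#' feature taxonomy. TSS windows are strand-aware (upstream of the
#' transcription start). When a probe overlaps several genes' features the
#' precedence TSS200 > TSS1500 > 5'UTR > Body > 3'UTR applies. Strand is
#' otherwise ignored.
#'
#' @param pos integer vector of 1-based positions (one chromosome).
#' @param genes data.frame with columns \code{gene}, \code{start},
#'   \code{end} (1-based inclusive), \code{strand} ("+" or "-"),
#'   \code{utr5_end}, \code{utr3_start} (1-based positions delimiting the
#'   5'UTR [start..utr5_end] and 3'UTR [utr3_start..end] on the + strand,
#'   mirrored on the - strand).
#' @return data.frame with columns \code{feature} (factor) and \code{gene}
#'   (first gene assigned, NA for Intergenic).
#' @export
assign_gene_feature <- function(pos, genes) {
  lv <- c("TSS200", "TSS1500", "5'UTR", "Body", "3'UTR", "Intergenic")
  n <- length(pos)
  rank <- rep(7L, n)                   # lower is higher precedence
  gene_hit <- rep(NA_character_, n)
  if (!is.null(genes) && nrow(genes) > 0L) {
    for (i in seq_len(nrow(genes))) {
      g <- genes[i, ]
      plus <- identical(as.character(g$strand), "+")
      tss <- if (plus) g$start else g$end
      in200 <- if (plus) pos >= tss - 200L & pos < tss
               else      pos > tss & pos <= tss + 200L
      in1500 <- if (plus) pos >= tss - 1500L & pos < tss - 200L
                else      pos > tss + 200L & pos <= tss + 1500L
      if (plus) {
        u5 <- pos >= g$start & pos <= g$utr5_end
        u3 <- pos >= g$utr3_start & pos <= g$end
        body <- pos > g$utr5_end & pos < g$utr3_start
      } else {
        u5 <- pos >= g$utr3_start & pos <= g$end
        u3 <- pos >= g$start & pos <= g$utr5_end
        body <- pos > g$utr5_end & pos < g$utr3_start
      }
      feat_rank <- rep(7L, n)
      feat_rank[u3] <- 5L
      feat_rank[body] <- 4L
      feat_rank[u5] <- 3L
      feat_rank[in1500] <- 2L
      feat_rank[in200] <- 1L
      better <- feat_rank < rank
      rank[better] <- feat_rank[better]
      gene_hit[better] <- as.character(g$gene)
    }
  }
  feature <- lv[ifelse(rank == 7L, 6L, rank)]
  data.frame(feature = factor(feature, levels = lv), gene = gene_hit)
}

#' Annotate a probe manifest with island relation, gene feature and
#' chromatin state
#'
#' Convenience wrapper applying [classify_island_relation()],
#' [assign_gene_feature()] and [map_chromatin_state()] chromosome by
#' chromosome.
#'
#' @param manifest probe manifest data.frame (columns \code{probe_id},
#'   \code{chrom}, \code{pos}).
#' @param islands data.frame of island intervals with a \code{chrom} column.
#' @param segments data.frame of chromHMM segments with a \code{chrom} column.
#' @param genes data.frame of gene models with a \code{chrom} column.
#' @return data.frame keyed by \code{probe_id} with columns
#'   \code{island_relation}, \code{island_distance}, \code{feature},
#'   \code{gene}, \code{state}, \code{category}.
#' @export
annotate_probes <- function(manifest, islands, segments, genes) {
  out <- vector("list", 0L)
  for (chr in unique(manifest$chrom)) {
    m <- manifest[manifest$chrom == chr, , drop = FALSE]
    isl <- classify_island_relation(m$pos,
      islands[islands$chrom == chr, , drop = FALSE])
    gf <- assign_gene_feature(m$pos,
      genes[genes$chrom == chr, , drop = FALSE])
    cs <- map_chromatin_state(m$pos,
      segments[segments$chrom == chr, , drop = FALSE])
    out[[chr]] <- data.frame(probe_id = m$probe_id, chrom = chr, pos = m$pos,
                             island_relation = isl$relation,
                             island_distance = isl$distance,
                             feature = gf$feature, gene = gf$gene,
                             state = cs$state, category = cs$category)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res[match(manifest$probe_id, res$probe_id), , drop = FALSE]
}
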