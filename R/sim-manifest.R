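#' Generate a synthetic probe manifest with island, chromatin-state and
#' gene-model annotation tracks
#'
#' Emulates the structure of an Infinium 450K manifest plus the interval
#' annotation a Roadmap-style segmentation provides: probes at strictly
#' increasing positions on two autosomes, a small sex-chromosome contingent
#' and a SNP-flagged contingent for QC-filter testing, CpG-island intervals,
#' a 15-state chromHMM tiling, and non-overlapping gene models covering the
#' probe space. Deterministic for a fixed \code{config$seed}.
#'
#' @param config a [sim_config()] object.
#' @return list with elements \code{manifest} (data.frame: probe_id, chrom,
#'   pos, strand, gene, feature_class, sex_chrom_flag, snp_flag),
#'   \code{islands}, \code{chrom_states} and \code{genes} (data.frames;
#'   interval tracks in BED convention, 0-based half-open, except
#'   \code{genes} which is 1-based inclusive).
#' @export
simulate_manifest <- function(config) {
  validate_sim_config(config)
  set.seed(config$seed)
  n <- config$n_probes
  n_sex <- as.integer(round(n * config$sex_fraction))
  n_auto <- n - n_sex
  chroms <- c(rep("chr1", ceiling(n_auto / 2)),
              rep("chr2", n_auto - ceiling(n_auto / 2)),
              rep("chrX", n_sex))

  manifest <- do.call(rbind, lapply(unique(chroms), function(chr) {
    k <- sum(chroms == chr)
    # bimodal gap structure: half the gaps short enough to seed DMR runs
    short <- stats::runif(k) < 0.5
    gaps <- ifelse(short, round(stats::runif(k, 100, 900)),
                   round(stats::runif(k, 1100, 5000)))
    pos <- 10000L + cumsum(as.integer(gaps))
    data.frame(chrom = chr, pos = pos,
               strand = sample(c("+", "-"), k, replace = TRUE))
  }))
  manifest$probe_id <- sprintf("cg%08d", seq_len(nrow(manifest)))
  manifest$sex_chrom_flag <- as.integer(manifest$chrom == "chrX")
  snp_flag <- integer(nrow(manifest))
  n_snp <- as.integer(round(n * config$snp_fraction))
  auto_idx <- which(manifest$sex_chrom_flag == 0L)
  if (n_snp > 0L && length(auto_idx) > 0L) {
    k <- min(n_snp, length(auto_idx))
    snp_flag[auto_idx[sample.int(length(auto_idx), k)]] <- 1L
  }
  manifest$snp_flag <- snp_flag

  chrom_len <- tapply(manifest$pos, manifest$chrom, max) + 10000L

  islands <- do.call(rbind, lapply(names(chrom_len), function(chr) {
    len <- chrom_len[[chr]]
    starts <- integer(0); ends <- integer(0)
    p <- 5000L
    while (p < len - 2000L) {
      w <- as.integer(round(stats::runif(1, 300, 1500)))
      starts <- c(starts, p); ends <- c(ends, p + w)
      p <- p + w + as.integer(round(stats::runif(1, 8000, 30000)))
    }
    if (!length(starts)) return(NULL)
    data.frame(chrom = chr, start = starts, end = ends)
  }))

  states <- names(chromhmm_collapse_map())
  # Quies-heavy state frequencies, enhancers and promoters sparser
  state_w <- c(TssA = 2, TssBiv = 1, TssAFlnk = 2, BivFlnk = 1, Tx = 4,
               TxFlnk = 1, TxWk = 6, Enh = 4, EnhG = 1, EnhBiv = 1,
               `ZNF/Rpts` = 1, Het = 2, ReprPC = 2, ReprPCWk = 3, Quies = 12)
  chrom_states <- do.call(rbind, lapply(names(chrom_len), function(chr) {
    len <- as.numeric(chrom_len[[chr]])
    n_seg <- ceiling(len / 2000) + 10L
    seg_len <- 200L * (1L + stats::rgeom(n_seg, 1 / 10))
    ends <- cumsum(as.numeric(seg_len))
    keep <- which(ends - seg_len < len)
    seg_len <- seg_len[keep]; ends <- ends[keep]
    data.frame(chrom = chr, start = ends - seg_len, end = ends,
               state = sample(states, length(ends), replace = TRUE,
                              prob = state_w[states]))
  }))

  genes <- do.call(rbind, lapply(names(chrom_len), function(chr) {
    len <- chrom_len[[chr]]
    share <- len / sum(as.numeric(chrom_len))
    k <- max(1L, as.integer(round(config$n_genes * share)))
    starts <- integer(0); ends <- integer(0)
    p <- as.integer(round(stats::runif(1, 2000, 20000)))
    for (i in seq_len(k)) {
      glen <- as.integer(round(stats::runif(1, 5000, 25000)))
      if (p + glen > len) break
      starts <- c(starts, p); ends <- c(ends, p + glen)
      p <- p + glen + as.integer(round(stats::runif(1, 3000, 30000)))
    }
    if (!length(starts)) return(NULL)
    u5 <- starts + pmax(200L, as.integer(round((ends - starts) * 0.1)))
    u3 <- ends - pmax(200L, as.integer(round((ends - starts) * 0.15)))
    data.frame(gene = paste0("G_", chr, "_", seq_along(starts)),
               chrom = chr, start = starts, end = ends,
               strand = sample(c("+", "-"), length(starts), replace = TRUE),
               utr5_end = u5, utr3_start = u3)
  }))
  rownames(genes) <- NULL

  ann <- annotate_probes(manifest[, c("probe_id", "chrom", "pos")],
                         islands, chrom_states, genes)
  manifest$gene <- ann$gene
  manifest$feature_class <- as.character(ann$feature)
  manifest <- manifest[, c("probe_id", "chrom", "pos", "strand", "gene",
                           "feature_class", "sex_chrom_flag", "snp_flag")]
  rownames(manifest) <- NULL
  list(manifest = manifest, islands = islands, chrom_states = chrom_states,
       genes = genes)
}
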