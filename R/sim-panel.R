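#' Simulate a multi-tissue methylation panel with planted tissue-specific
#' probes and planted convergence at DMLs
#'
#' Produces per-tissue mean-beta vectors for \code{config$n_tissues}
#' non-reference tissues plus a cartilage-like reference, and a small
#' reference beta matrix (three replicate columns). Three probe strata:
#' \itemize{
#'   \item planted tissue-specific probes: reference strongly
#'     hypomethylated (beta around 0.25), every other tissue strongly
#'     methylated (beta around 0.9);
#'   \item planted DML probes (from \code{truth}): the reference sits at
#'     the followup (Day14) methylation level while other tissues sit at
#'     the baseline level, planting the convergence seen when a
#'     differentiating tissue approaches its mature counterpart;
#'   \item all other probes: one shared per-probe mean across every tissue
#'     including the reference, plus tissue noise.
#' }
#'
#' @param sim result of [simulate_manifest()].
#' @param config a [sim_config()] object.
#' @param truth the \code{truth_set} from [simulate_paired_betas()].
#' @param baseline_m optional named per-probe baseline M values; defaults
#'   to a fresh bimodal draw.
#' @return list: \code{panel} (probe x tissue mean-beta matrix, reference
#'   column first), \code{reference} (column name), \code{reference_betas}
#'   (probe x 3 replicate beta matrix) and \code{truth} (input truth with
#'   \code{planted_tissue_specific} filled in).
#' @export
simulate_tissue_panel <- function(sim, config, truth, baseline_m = NULL) {
  validate_sim_config(config)
  set.seed(config$seed + 2L)
  manifest <- sim$manifest
  probes <- manifest$probe_id
  n <- length(probes)
  nt <- config$n_tissues

  clean <- manifest$sex_chrom_flag == 0L & manifest$snp_flag == 0L
  pool <- setdiff(probes[clean], truth$planted_dml_probes)
  n_ts <- min(config$n_tissue_specific, length(pool))
  ts_probes <- pool[sample.int(length(pool), n_ts)]

  if (is.null(baseline_m)) {
    mix <- sample(1:3, n, replace = TRUE, prob = c(0.35, 0.45, 0.20))
    baseline_m <- ifelse(mix == 1, stats::rnorm(n, -2.5, 0.8),
                  ifelse(mix == 2, stats::rnorm(n, 2.5, 0.8),
                         stats::rnorm(n, 0, 1)))
    names(baseline_m) <- probes
  }
  mu <- baseline_m[probes]

  ref_m <- mu
  other_m <- matrix(mu, n, nt, dimnames = list(probes, NULL))
  # planted tissue-specific stratum: margins wide enough that the
  # reference-low / others-high construction holds for essentially every
  # planted probe after tissue noise
  ts_i <- match(ts_probes, probes)
  ref_m[ts_i] <- stats::rnorm(n_ts, -2, 0.4)
  other_m[ts_i, ] <- stats::rnorm(n_ts * nt, 3.8, 0.4)
  # planted convergence at DMLs: reference at followup level, others at
  # baseline level
  dml_i <- match(intersect(truth$planted_dml_probes, probes), probes)
  if (length(dml_i)) {
    eff <- truth$planted_effect[probes[dml_i]]
    ref_m[dml_i] <- mu[dml_i] + eff
  }

  noise <- function(k) stats::rnorm(k, 0, config$tissue_sd)
  panel_m <- cbind(ref_m + noise(n),
                   other_m + matrix(noise(n * nt), n, nt))
  colnames(panel_m) <- c("cartilage", sprintf("tissue%02d", seq_len(nt)))
  panel <- m_to_beta(panel_m)
  rownames(panel) <- probes

  ref_betas <- m_to_beta(matrix(ref_m, n, 3L) +
                           matrix(noise(n * 3L), n, 3L))
  dimnames(ref_betas) <- list(probes, paste0("cartilage_rep", 1:3))

  truth$planted_tissue_specific <- ts_probes
  list(panel = panel, reference = "cartilage", reference_betas = ref_betas,
       truth = truth)
}

#' Simulate a gene expression table coupled to planted DMLs
#'
#' Genes whose span (including the 1500 bp TSS window) contains at least
#' one planted DML probe draw their log2 fold-change from a distribution
#' shifted up by \code{coupling} (default \code{config$expression_coupling});
#' all other genes draw from a null centred at zero. With coupling 0 the
#' two distributions coincide. An adjusted p-value column is generated from
#' the fold-changes so the table has the shape of a differential-expression
#' result.
#'
#' @param sim result of [simulate_manifest()].
#' @param config a [sim_config()] object.
#' @param truth the \code{truth_set} from [simulate_paired_betas()].
#' @param coupling mean log2FC shift for DML-overlapping genes; defaults to
#'   \code{config$expression_coupling}.
#' @return list: \code{expression} (data.frame gene, log2fc, p_adj),
#'   \code{gene_probes} (named list of probe ids per gene),
#'   \code{gene_has_dml} (named logical).
#' @export
simulate_expression <- function(sim, config, truth, coupling = NULL) {
  validate_sim_config(config)
  set.seed(config$seed + 3L)
  if (is.null(coupling)) coupling <- config$expression_coupling
  genes <- sim$genes
  manifest <- sim$manifest
  gene_probes <- lapply(seq_len(nrow(genes)), function(i) {
    g <- genes[i, ]
    tss_lo <- if (g$strand == "+") g$start - 1500L else g$start
    tss_hi <- if (g$strand == "+") g$end else g$end + 1500L
    manifest$probe_id[manifest$chrom == g$chrom &
                        manifest$pos >= tss_lo & manifest$pos <= tss_hi]
  })
  names(gene_probes) <- genes$gene
  has_dml <- vapply(gene_probes,
                    function(pr) any(pr %in% truth$planted_dml_probes),
                    logical(1))
  k <- nrow(genes)
  log2fc <- stats::rnorm(k, 0, 0.8)
  log2fc[has_dml] <- stats::rnorm(sum(has_dml), coupling, 0.9)
  p_adj <- adjust_bh(2 * stats::pnorm(-abs(log2fc) / 0.5))
  list(expression = data.frame(gene = genes$gene, log2fc = log2fc,
                               p_adj = p_adj),
       gene_probes = gene_probes, gene_has_dml = has_dml)
}

#' Simulate a disease DML set with a configured overlap
#'
#' Draws \code{config$disease_overlap} probes from the planted DMLs and the
#' remainder from clean non-planted probes, emulating a disease-tissue DML
#' call set that partially overlaps the differentiation DMLs.
#'
#' @param sim result of [simulate_manifest()].
#' @param config a [sim_config()] object.
#' @param truth the \code{truth_set} from [simulate_paired_betas()].
#' @return list: \code{disease_probes} (character), \code{truth} (with
#'   \code{planted_overlap_probes} filled in).
#' @export
simulate_disease_dmls <- function(sim, config, truth) {
  validate_sim_config(config)
  set.seed(config$seed + 4L)
  manifest <- sim$manifest
  clean <- manifest$sex_chrom_flag == 0L & manifest$snp_flag == 0L
  planted <- intersect(truth$planted_dml_probes, manifest$probe_id[clean])
  n_ov <- min(config$disease_overlap, length(planted))
  ov <- planted[sample.int(length(planted), n_ov)]
  pool <- setdiff(manifest$probe_id[clean], truth$planted_dml_probes)
  n_rest <- min(config$disease_size - n_ov, length(pool))
  rest <- pool[sample.int(length(pool), n_rest)]
  truth$planted_overlap_probes <- ov
  list(disease_probes = c(ov, rest), truth = truth)
}
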