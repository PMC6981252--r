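#' Simulation configuration for synthetic 450K-style experiments
#'
#' Builds and validates the parameter set for the synthetic-data generator.
#' Defaults describe a paired Day0/Day14 chondrogenesis-like experiment:
#' mostly hypomethylating planted DMLs (95%, mirroring the strong
#' hypomethylation bias seen during MSC chondrogenesis), logit-normal noise
#' on the M scale, donor baseline effects shared between timepoints, a
#' multi-tissue panel with a hidden cartilage-hypomethylated probe subset,
#' and a disease-like DML set partially overlapping the planted loci.
#'
#' @param n_probes total number of probes on the synthetic array.
#' @param n_donors number of paired donors (>= 2; the paired test needs at
#'   least two complete pairs).
#' @param fraction_planted_dml fraction of QC-clean probes carrying a planted
#'   methylation change.
#' @param hypo_fraction fraction of planted DMLs that lose methylation
#'   (negative effect on M); the assignment is deterministic in count.
#' @param effect_size_mean,effect_size_sd mean and sd of the absolute planted
#'   effect on the M scale. The default mean of 2 gives a typical beta change
#'   around 0.3 at mid-range baselines.
#' @param residual_sd residual noise sd per sample on the M scale.
#' @param donor_effect_sd sd of the per-donor baseline shift on the M scale,
#'   shared between Day0 and Day14 (removed by pairing).
#' @param sex_fraction,snp_fraction fractions of probes placed on a sex
#'   chromosome or flagged as SNP-contaminated, for QC-filter testing.
#' @param dmr_count number of planted DMR regions (runs of 2-6 planted
#'   probes with consecutive gaps below \code{dmr_gap}).
#' @param dmr_gap maximum within-run gap, bp, used when planting DMRs.
#' @param n_tissues number of non-reference tissues in the synthetic panel.
#' @param n_tissue_specific number of planted tissue-specific
#'   (reference-hypomethylated) probes.
#' @param tissue_sd per-tissue noise sd on the M scale for panel means.
#' @param n_genes number of synthetic gene models.
#' @param expression_coupling mean log2 fold-change boost for genes
#'   overlapping planted DMLs (0 decouples expression from methylation).
#' @param disease_size,disease_overlap size of the synthetic disease DML set
#'   and the number of its probes shared with the planted DMLs.
#' @param unpaired_extra if TRUE, add one extra Day0-only donor sample
#'   (dropped, with a warning, by the paired fitter).
#' @param seed integer seed; all generator functions are deterministic given
#'   the config.
#'
#' @return an object of class \code{sim_config} (a validated list).
#' @export
sim_config <- function(n_probes = 10000L,
                       n_donors = 4L,
                       fraction_planted_dml = 0.05,
                       hypo_fraction = 0.95,
                       effect_size_mean = 2,
                       effect_size_sd = 0.4,
                       residual_sd = 0.5,
                       donor_effect_sd = 0.5,
                       sex_fraction = 0.02,
                       snp_fraction = 0.02,
                       dmr_count = 25L,
                       dmr_gap = 1000L,
                       n_tissues = 12L,
                       n_tissue_specific = 200L,
                       tissue_sd = 0.3,
                       n_genes = 400L,
                       expression_coupling = 1.5,
                       disease_size = 500L,
                       disease_overlap = 50L,
                       unpaired_extra = FALSE,
                       seed = 1L) {
  cfg <- list(
    n_probes = as.integer(n_probes),
    n_donors = as.integer(n_donors),
    fraction_planted_dml = fraction_planted_dml,
    hypo_fraction = hypo_fraction,
    effect_size_mean = effect_size_mean,
    effect_size_sd = effect_size_sd,
    residual_sd = residual_sd,
    donor_effect_sd = donor_effect_sd,
    sex_fraction = sex_fraction,
    snp_fraction = snp_fraction,
    dmr_count = as.integer(dmr_count),
    dmr_gap = as.integer(dmr_gap),
    n_tissues = as.integer(n_tissues),
    n_tissue_specific = as.integer(n_tissue_specific),
    tissue_sd = tissue_sd,
    n_genes = as.integer(n_genes),
    expression_coupling = expression_coupling,
    disease_size = as.integer(disease_size),
    disease_overlap = as.integer(disease_overlap),
    unpaired_extra = isTRUE(unpaired_extra),
    seed = as.integer(seed)
  )
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
  cfg
}

validate_sim_config <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  if (cfg$n_probes <= 0L) {
    stop("configuration error: n_probes must be positive", call. = FALSE)
  }
  if (cfg$n_donors < 2L) {
    stop("configuration error: n_donors must be >= 2 (paired test needs >= 2 pairs)",
         call. = FALSE)
  }
  fracs <- c(fraction_planted_dml = cfg$fraction_planted_dml,
             hypo_fraction = cfg$hypo_fraction,
             sex_fraction = cfg$sex_fraction,
             snp_fraction = cfg$snp_fraction)
  bad <- fracs < 0 | fracs > 1
  if (any(bad)) {
    stop("configuration error: fractions must lie in [0,1]: ",
         paste(names(fracs)[bad], collapse = ", "), call. = FALSE)
  }
  sds <- c(effect_size_sd = cfg$effect_size_sd,
           residual_sd = cfg$residual_sd,
           donor_effect_sd = cfg$donor_effect_sd,
           tissue_sd = cfg$tissue_sd)
  if (any(sds <= 0)) {
    stop("configuration error: standard deviations must be > 0", call. = FALSE)
  }
  if (cfg$disease_overlap > cfg$disease_size) {
    stop("configuration error: disease_overlap cannot exceed disease_size",
         call. = FALSE)
  }
  invisible(cfg)
}

#' @export
print.sim_config <- function(x, ...) {
  cat("Synthetic methylation experiment configuration\n")
  cat(sprintf("  probes: %d (%.0f%% sex-chrom, %.0f%% SNP-flagged)\n",
              x$n_probes, 100 * x$sex_fraction, 100 * x$snp_fraction))
  cat(sprintf("  donors: %d paired%s\n", x$n_donors,
              if (x$unpaired_extra) " (+1 unpaired Day0 extra)" else ""))
  cat(sprintf("  planted DMLs: %.1f%% of clean probes, %.0f%% hypomethylated, |effect| ~ N(%.2g, %.2g) on M\n",
              100 * x$fraction_planted_dml, 100 * x$hypo_fraction,
              x$effect_size_mean, x$effect_size_sd))
  cat(sprintf("  noise: residual sd %.2g, donor sd %.2g (M scale)\n",
              x$residual_sd, x$donor_effect_sd))
  cat(sprintf("  planted DMRs: %d (gap <= %d bp); tissues: %d (+reference), %d tissue-specific probes\n",
              x$dmr_count, x$dmr_gap, x$n_tissues, x$n_tissue_specific))
  cat(sprintf("  seed: %d\n", x$seed))
  invisible(x)
}
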