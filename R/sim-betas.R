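#' Simulate paired Day0/Day14 beta matrices with planted DMLs and DMRs
#'
#' Generates per-probe M values \code{M0 = mu + u_j + e} and
#' \code{M14 = mu + u_j + delta + e} for each donor j, where the donor
#' baseline \code{u_j} is shared between timepoints (removed by pairing),
#' \code{e} is Gaussian residual noise on the M scale, and \code{delta} is
#' nonzero only at planted DMLs. Betas are obtained by the logistic map
#' \code{beta = 2^M / (1 + 2^M)} and therefore always lie in (0, 1).
#' A configured number of planted DMR regions is created by planting runs
#' of 2-6 probes whose consecutive gaps are at most \code{config$dmr_gap}.
#' The hypomethylated share of planted DMLs equals
#' \code{config$hypo_fraction} exactly (deterministic count).
#'
#' Planted probes are drawn only from QC-clean probes (autosomal,
#' non-SNP-flagged, detection-pass) so recovery can be scored after
#' filtering. A small fraction of clean non-planted probes is given one
#' failing detection p-value to exercise the QC filter.
#'
#' @param sim result of [simulate_manifest()].
#' @param config a [sim_config()] object.
#' @return list with elements \code{beta_day0}, \code{beta_day14} (probe x
#'   donor matrices), \code{detection_day0}, \code{detection_day14}
#'   (detection p-value matrices), \code{samples} (sample sheet data.frame:
#'   sample_id, donor, group), \code{truth} (a \code{truth_set}) and
#'   \code{baseline_m} (the per-probe baseline M values, reused by the
#'   tissue-panel generator to plant convergence).
#' @export
simulate_paired_betas <- function(sim, config) {
  validate_sim_config(config)
  manifest <- sim$manifest
  set.seed(config$seed + 1L)
  n <- nrow(manifest)
  nd <- config$n_donors
  probes <- manifest$probe_id

  # detection p-values: everything passes except a 0.5% planted-failure set
  make_det <- function() matrix(stats::runif(n * nd, 0, 0.01), n, nd)
  det0 <- make_det(); det14 <- make_det()

  clean <- manifest$sex_chrom_flag == 0L & manifest$snp_flag == 0L
  clean_idx <- which(clean)
  n_fail <- min(length(clean_idx), max(0L, round(0.005 * n)))
  fail_idx <- clean_idx[sample.int(length(clean_idx), n_fail)]
  if (length(fail_idx)) {
    det0[cbind(fail_idx, sample.int(nd, length(fail_idx), replace = TRUE))] <-
      stats::runif(length(fail_idx), 0.06, 0.5)
  }
  clean[fail_idx] <- FALSE

  # ---- choose planted probes: DMR runs first, then isolated DMLs ----
  # fraction is of the whole array; planted probes are drawn from the
  # QC-clean subset so recovery can be scored after filtering
  n_planted <- min(round(config$fraction_planted_dml * n), sum(clean))
  dmr_members <- integer(0)
  dmr_regions <- NULL
  if (n_planted > 0L && config$dmr_count > 0L) {
    picked <- list()
    for (chr in unique(manifest$chrom)) {
      idx <- which(manifest$chrom == chr & clean)
      if (length(idx) < 2L) next
      gaps <- diff(manifest$pos[idx])
      ok <- gaps <= config$dmr_gap
      # starts of maximal runs of consecutive small gaps
      r <- rle(ok)
      pos0 <- cumsum(c(1L, r$lengths))
      for (j in which(r$values)) {
        run_len <- r$lengths[j] + 1L          # probes in the run
        picked[[length(picked) + 1L]] <- idx[pos0[j]:(pos0[j] + run_len - 1L)]
      }
    }
    if (length(picked) < config$dmr_count) {
      stop("cannot plant ", config$dmr_count, " DMR regions: only ",
           length(picked), " eligible probe runs in the manifest", call. = FALSE)
    }
    picked <- picked[sample.int(length(picked), config$dmr_count)]
    picked <- lapply(picked, function(run) {
      size <- min(length(run), sample(2:6, 1L))
      run[seq_len(size)]
    })
    dmr_members <- unlist(picked)
    dmr_regions <- do.call(rbind, lapply(picked, function(run) {
      data.frame(chrom = manifest$chrom[run[1]],
                 start = min(manifest$pos[run]),
                 end = max(manifest$pos[run]),
                 n_probes = length(run))
    }))
  }
  if (length(dmr_members) > n_planted) {
    stop("fraction_planted_dml too small for the requested dmr_count",
         call. = FALSE)
  }
  rest_pool <- setdiff(which(clean), dmr_members)
  isolated <- rest_pool[sample.int(length(rest_pool),
                                   n_planted - length(dmr_members))]
  planted <- c(dmr_members, isolated)

  # ---- directions: exact hypomethylated count; DMR members all hypo ----
  n_hypo <- round(config$hypo_fraction * n_planted)
  direction <- rep(1L, n_planted)
  if (n_hypo >= length(dmr_members)) {
    extra <- sample(seq_along(isolated), n_hypo - length(dmr_members))
    direction[c(seq_along(dmr_members), length(dmr_members) + extra)] <- -1L
  } else {
    direction[sample(seq_along(planted), n_hypo)] <- -1L
  }

  # ---- baselines and effects on the M scale ----
  mix <- sample(1:3, n, replace = TRUE, prob = c(0.35, 0.45, 0.20))
  mu <- ifelse(mix == 1, stats::rnorm(n, -2.5, 0.8),
        ifelse(mix == 2, stats::rnorm(n, 2.5, 0.8), stats::rnorm(n, 0, 1)))
  # planted probes get mid-range baselines with headroom in the planted
  # direction so the beta change is visible
  mu[planted] <- ifelse(direction < 0,
                        stats::runif(n_planted, 0.5, 2.5),
                        stats::runif(n_planted, -2.5, -0.5))
  delta <- numeric(n)
  delta[planted] <- direction *
    abs(stats::rnorm(n_planted, config$effect_size_mean, config$effect_size_sd))

  donor_u <- stats::rnorm(nd, 0, config$donor_effect_sd)
  eps <- function() matrix(stats::rnorm(n * nd, 0, config$residual_sd), n, nd)
  M0 <- mu + matrix(donor_u, n, nd, byrow = TRUE) + eps()
  M14 <- mu + delta + matrix(donor_u, n, nd, byrow = TRUE) + eps()

  beta0 <- m_to_beta(M0)
  beta14 <- m_to_beta(M14)
  donors <- sprintf("donor%02d", seq_len(nd))
  dimnames(beta0) <- dimnames(det0) <- list(probes, paste0(donors, "_Day0"))
  dimnames(beta14) <- dimnames(det14) <- list(probes, paste0(donors, "_Day14"))

  samples <- data.frame(
    sample_id = c(colnames(beta0), colnames(beta14)),
    donor = rep(donors, 2L),
    group = rep(c("Day0", "Day14"), each = nd))

  if (config$unpaired_extra) {
    extra_u <- stats::rnorm(1, 0, config$donor_effect_sd)
    Mx <- mu + extra_u + stats::rnorm(n, 0, config$residual_sd)
    beta0 <- cbind(beta0, extra_Day0 = m_to_beta(Mx))
    det0 <- cbind(det0, extra_Day0 = stats::runif(n, 0, 0.01))
    colnames(beta0)[ncol(beta0)] <- "donor_extra_Day0"
    colnames(det0)[ncol(det0)] <- "donor_extra_Day0"
    samples <- rbind(samples, data.frame(sample_id = "donor_extra_Day0",
                                         donor = "donor_extra", group = "Day0"))
  }

  truth <- structure(list(
    planted_dml_probes = probes[planted],
    planted_direction = stats::setNames(ifelse(direction < 0, "hypo", "hyper"),
                                        probes[planted]),
    planted_effect = stats::setNames(delta[planted], probes[planted]),
    planted_dmr_regions = dmr_regions,
    planted_tissue_specific = character(0),
    planted_overlap_probes = character(0),
    seed = config$seed
  ), class = "truth_set")

  list(beta_day0 = beta0, beta_day14 = beta14,
       detection_day0 = det0, detection_day14 = det14,
       samples = samples, truth = truth,
       baseline_m = stats::setNames(mu, probes))
}

#' @export
print.truth_set <- function(x, ...) {
  n_hypo <- sum(x$planted_direction == "hypo")
  cat("Planted truth set\n")
  cat(sprintf("  planted DMLs: %d (%d hypo, %d hyper)\n",
              length(x$planted_dml_probes), n_hypo,
              length(x$planted_dml_probes) - n_hypo))
  cat(sprintf("  planted DMR regions: %d\n",
              if (is.null(x$planted_dmr_regions)) 0L
              else nrow(x$planted_dmr_regions)))
  cat(sprintf("  tissue-specific probes: %d; disease-overlap probes: %d\n",
              length(x$planted_tissue_specific),
              length(x$planted_overlap_probes)))
  invisible(x)
}
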