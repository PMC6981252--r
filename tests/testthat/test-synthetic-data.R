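test_that("manifest generation is deterministic, sorted and flag-consistent", {
  cfg <- sim_config(n_probes = 1000L, seed = 1L)
  a <- simulate_manifest(cfg)
  b <- simulate_manifest(cfg)
  expect_identical(a, b)

  man <- a$manifest
  expect_setequal(unique(man$chrom[man$sex_chrom_flag == 0L]),
                  c("chr1", "chr2"))
  for (chr in unique(man$chrom)) {
    pos <- man$pos[man$chrom == chr]
    expect_true(all(diff(pos) > 0))
  }
  expect_true(all(man$snp_flag[man$sex_chrom_flag == 1L] == 0L))
  # interval tracks tile without overlap per chromosome
  for (chr in unique(a$chrom_states$chrom)) {
    seg <- a$chrom_states[a$chrom_states$chrom == chr, ]
    expect_true(all(seg$start[-1] >= seg$end[-nrow(seg)]))
  }
})

test_that("zero sex fraction leaves the sex-chromosome filter with nothing to do", {
  cfg <- sim_config(n_probes = 400L, sex_fraction = 0, snp_fraction = 0,
                    dmr_count = 2L, seed = 3L)
  sim <- simulate_manifest(cfg)
  expect_true(all(sim$manifest$sex_chrom_flag == 0L))
  paired <- simulate_paired_betas(sim, cfg)
  kept <- filter_probes(paired$beta_day0,
                        cbind(paired$detection_day0, paired$detection_day14),
                        sim$manifest, quiet = TRUE)
  removed <- attr(kept, "removed")
  expect_identical(unname(removed["sex_chromosome"]), 0L)
  expect_identical(unname(removed["snp"]), 0L)
})

test_that("non-positive probe counts are a configuration error", {
  expect_error(sim_config(n_probes = 0L), "n_probes")
  expect_error(sim_config(n_donors = 1L), "donor")
  expect_error(sim_config(hypo_fraction = 1.2), "fraction")
  expect_error(sim_config(residual_sd = 0), "deviation")
})

test_that("paired betas stay in (0,1), respect the truth bookkeeping and the seed", {
  cfg <- sim_config(n_probes = 2000L, fraction_planted_dml = 0.05,
                    dmr_count = 5L, seed = 7L)
  sim <- simulate_manifest(cfg)
  a <- simulate_paired_betas(sim, cfg)
  b <- simulate_paired_betas(sim, cfg)
  expect_identical(a, b)
  expect_true(all(a$beta_day0 > 0 & a$beta_day0 < 1))
  expect_true(all(a$beta_day14 > 0 & a$beta_day14 < 1))

  truth <- a$truth
  expect_length(truth$planted_dml_probes, round(0.05 * 2000))
  # planted probes avoid flagged or detection-failing probes
  man <- sim$manifest
  flagged <- man$probe_id[man$sex_chrom_flag == 1L | man$snp_flag == 1L]
  failing <- rownames(a$detection_day0)[
    apply(a$detection_day0 > 0.05, 1L, any)]
  expect_length(intersect(truth$planted_dml_probes,
                          c(flagged, failing)), 0L)
  # hypomethylated share is exact by construction
  expect_identical(sum(truth$planted_direction == "hypo"),
                   as.integer(round(0.95 * length(truth$planted_dml_probes))))
  # effects agree in sign with the recorded direction
  expect_true(all(sign(truth$planted_effect) ==
                    ifelse(truth$planted_direction == "hypo", -1, 1)))
})

test_that("planted DMR regions hold >= 2 planted probes with gaps within the limit", {
  cfg <- sim_config(n_probes = 3000L, dmr_count = 10L, seed = 11L)
  sim <- simulate_manifest(cfg)
  truth <- simulate_paired_betas(sim, cfg)$truth
  reg <- truth$planted_dmr_regions
  expect_identical(nrow(reg), 10L)
  man <- sim$manifest
  for (i in seq_len(nrow(reg))) {
    members <- man$probe_id %in% truth$planted_dml_probes &
      man$chrom == reg$chrom[i] & man$pos >= reg$start[i] &
      man$pos <= reg$end[i]
    pos <- sort(man$pos[members])
    expect_gte(length(pos), 2L)
    expect_true(all(diff(pos) <= cfg$dmr_gap))
  }
})

test_that("the logistic map gives the expected beta drop for a -2 M-shift at baseline 1", {
  # mu = 1 -> beta = 2/3; mu = -1 -> beta = 1/3
  expect_equal(m_to_beta(1) - m_to_beta(1 - 2), 1 / 3, tolerance = 1e-12)
})

test_that("an unpaired extra sample is generated on request and dropped by the fitter", {
  cfg <- sim_config(n_probes = 300L, unpaired_extra = TRUE, dmr_count = 1L,
                    seed = 5L)
  sim <- simulate_manifest(cfg)
  paired <- simulate_paired_betas(sim, cfg)
  expect_identical(ncol(paired$beta_day0), cfg$n_donors + 1L)
  expect_warning(
    fit <- fit_paired(beta_to_m(paired$beta_day0),
                      beta_to_m(paired$beta_day14),
                      paired$samples),
    "unpaired")
  expect_identical(fit$n_pairs, cfg$n_donors)
})

test_that("tissue panel plants reference-low, others-high probes deterministically", {
  cfg <- sim_config(n_probes = 1500L, n_tissues = 12L,
                    n_tissue_specific = 40L, dmr_count = 3L, seed = 9L)
  sim <- simulate_manifest(cfg)
  paired <- simulate_paired_betas(sim, cfg)
  a <- simulate_tissue_panel(sim, cfg, paired$truth, paired$baseline_m)
  b <- simulate_tissue_panel(sim, cfg, paired$truth, paired$baseline_m)
  expect_identical(a, b)
  ts <- a$truth$planted_tissue_specific
  expect_length(ts, 40L)
  others <- setdiff(colnames(a$panel), a$reference)
  n_high <- rowSums(a$panel[ts, others] > 0.8)
  expect_true(all(n_high >= 11L))
  expect_true(all(a$panel[ts, a$reference] < 0.5))
})

test_that("with no planted tissue-specific probes the marker caller finds none", {
  cfg <- sim_config(n_probes = 1500L, n_tissue_specific = 0L, dmr_count = 0L,
                    fraction_planted_dml = 0, seed = 13L)
  sim <- simulate_manifest(cfg)
  paired <- simulate_paired_betas(sim, cfg)
  pan <- simulate_tissue_panel(sim, cfg, paired$truth, paired$baseline_m)
  qn <- quantile_normalize(pan$panel)
  expect_length(call_tissue_specific(qn, pan$reference), 0L)
})

test_that("disease DML set realises the configured overlap exactly", {
  cfg <- sim_config(n_probes = 2000L, disease_size = 200L,
                    disease_overlap = 50L, dmr_count = 5L, seed = 17L)
  sim <- simulate_manifest(cfg)
  paired <- simulate_paired_betas(sim, cfg)
  dis <- simulate_disease_dmls(sim, cfg, paired$truth)
  expect_length(dis$disease_probes, 200L)
  expect_identical(
    length(intersect(dis$disease_probes, paired$truth$planted_dml_probes)),
    50L)
  expect_setequal(dis$truth$planted_overlap_probes,
                  intersect(dis$disease_probes,
                            paired$truth$planted_dml_probes))
})

test_that("expression coupling drives DML fraction; zero coupling is flat", {
  cfg <- sim_config(n_probes = 4000L, n_genes = 300L, dmr_count = 5L,
                    seed = 19L)
  sim <- simulate_manifest(cfg)
  paired <- simulate_paired_betas(sim, cfg)
  # high coupling: fractions over well-populated positive bins non-decreasing
  hi <- simulate_expression(sim, cfg, paired$truth, coupling = 3)
  fr <- expression_dml_fraction(hi$expression, hi$gene_probes,
                                paired$truth$planted_dml_probes)
  pos <- fr$bins[fr$bins$bin_lo >= 0 & fr$bins$n_genes >= 20, ]
  expect_true(all(diff(pos$fraction) >= 0))
  # zero coupling: DML genes are not shifted
  null <- simulate_expression(sim, cfg, paired$truth, coupling = 0)
  with_dml <- null$expression$log2fc[null$gene_has_dml]
  without <- null$expression$log2fc[!null$gene_has_dml]
  expect_gt(t.test(with_dml, without)$p.value, 0.01)
})
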