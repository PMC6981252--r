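#' Run the full differential-methylation pipeline
#'
#' Orchestrates simulate (or load) -> QC filter -> paired empirical-Bayes
#' test -> DML calls -> DMR merging -> annotation -> enrichment and
#' expression integration -> cross-tissue normalisation, tissue-specific
#' marker calling and disease-overlap testing, writing standard-format
#' outputs to the output directory:
#' \code{dml_results.tsv}, \code{dmrs.bed}, \code{annotation.tsv},
#' \code{enrichment.tsv}, \code{ecdf.tsv}, \code{expression_bins.tsv},
#' \code{tissue_specific.txt}, \code{overlap.json},
#' \code{run_manifest.json}. Runs are deterministic given the config and
#' seed; each file is written atomically (temp file + rename) and the run
#' manifest carries the config echo, seed and per-stage counts.
#'
#' @param config a named list, or path to a YAML/JSON file, with elements:
#'   exactly one of \code{simulate} (arguments for [sim_config()]) or
#'   \code{inputs} (named paths: manifest, beta_day0, beta_day14, samples,
#'   islands, chrom_states, genes not required; detection_day0/14,
#'   expression, disease optional), plus optional \code{thresholds}
#'   (alpha, delta_min, max_gap, min_cpgs, lo, hi, tissue_frac, bin_width,
#'   fc_threshold), \code{seed} and \code{outdir}.
#' @param outdir output directory (overrides \code{config$outdir}).
#' @param seed seed (overrides \code{config$seed}).
#' @param quiet suppress per-stage messages.
#' @return invisibly, the run manifest list (paths, counts, config echo).
#' @export
run_pipeline <- function(config, outdir = NULL, seed = NULL, quiet = FALSE) {
  if (is.character(config) && length(config) == 1L) {
    config <- read_run_config(config)
  }
  config <- validate_run_config(config, outdir = outdir, seed = seed)
  outdir <- config$outdir
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  th <- config$thresholds
  note <- function(...) if (!quiet) message(sprintf(...))

  # ---- stage: inputs -------------------------------------------------
  if (!is.null(config$simulate)) {
    sim_args <- config$simulate
    sim_args$seed <- config$seed
    cfg <- do.call(sim_config, sim_args)
    sim <- simulate_manifest(cfg)
    paired <- simulate_paired_betas(sim, cfg)
    panel_res <- simulate_tissue_panel(sim, cfg, paired$truth,
                                       baseline_m = paired$baseline_m)
    expr_res <- simulate_expression(sim, cfg, panel_res$truth)
    disease_res <- simulate_disease_dmls(sim, cfg, panel_res$truth)
    truth <- disease_res$truth
    inputs <- list(manifest = sim$manifest, islands = sim$islands,
                   chrom_states = sim$chrom_states, genes = sim$genes,
                   beta_day0 = paired$beta_day0,
                   beta_day14 = paired$beta_day14,
                   detection = cbind(paired$detection_day0,
                                     paired$detection_day14),
                   samples = paired$samples,
                   panel = panel_res$panel, reference = panel_res$reference,
                   expression = expr_res$expression,
                   gene_probes = expr_res$gene_probes,
                   disease = disease_res$disease_probes)
    note("simulate: %d probes, %d donors, %d planted DMLs, %d planted DMRs",
         nrow(sim$manifest), cfg$n_donors, length(truth$planted_dml_probes),
         nrow(truth$planted_dmr_regions))
  } else {
    inputs <- load_pipeline_inputs(config$inputs)
    truth <- inputs$truth
  }

  # ---- stage: QC filter ---------------------------------------------
  b0 <- filter_probes(inputs$beta_day0, inputs$detection, inputs$manifest,
                      quiet = quiet)
  kept <- rownames(b0)
  b14 <- inputs$beta_day14[kept, , drop = FALSE]
  note("filter: %d/%d probes retained", length(kept),
       nrow(inputs$beta_day0))

  # ---- stage: paired test and DML calls ------------------------------
  fit <- dm_fit(b0, b14, pairing = inputs$samples)
  dmls <- call_dmls(fit, alpha = th$alpha, delta_min = th$delta_min)
  sig <- dmls$probe_id[dmls$significant]
  note("dml: %d significant (%d hypo, %d hyper), prior d0 = %s",
       length(sig), sum(dmls$significant & dmls$direction == "hypo"),
       sum(dmls$significant & dmls$direction == "hyper"),
       format(fit$prior$d0, digits = 4))
  if (length(sig) == 0L) {
    warning("no DMLs called; downstream outputs will be empty")
  }

  # ---- stage: DMRs ---------------------------------------------------
  dmrs <- call_dmrs(dmls, inputs$manifest, max_gap = th$max_gap,
                    min_cpgs = th$min_cpgs)
  note("dmr: %d regions", nrow(dmrs))

  # ---- stage: annotation and enrichment ------------------------------
  ann <- annotate_probes(inputs$manifest[inputs$manifest$probe_id %in% kept,
                                         c("probe_id", "chrom", "pos")],
                         inputs$islands, inputs$chrom_states, inputs$genes)
  enr <- do.call(rbind, lapply(list(
    c("gene_feature", "feature"),
    c("island_relation", "island_relation"),
    c("chromatin_state", "category")), function(tr) {
      a <- stats::setNames(as.character(ann[[tr[2]]]), ann$probe_id)
      e <- feature_enrichment(sig, kept, a)
      cbind(track = tr[1], e)
    }))

  delta <- stats::setNames(dmls$delta_beta, dmls$probe_id)
  ecdfs <- ecdf_by_category(delta,
                            stats::setNames(ann$category, ann$probe_id))
  qgrid <- seq(0, 1, by = 0.01)
  ecdf_tab <- do.call(rbind, lapply(ecdfs, function(e) {
    data.frame(category = e$category, quantile = qgrid,
               delta_beta = stats::quantile(e$x, qgrid, names = FALSE),
               area_vs_pooled = e$area_vs_pooled, n = e$n)
  }))

  expr_frac <- expression_dml_fraction(inputs$expression, inputs$gene_probes,
                                       sig, bin_width = th$bin_width,
                                       fc_threshold = th$fc_threshold)
  note("integrate: up-fraction %.3f (n=%d), down-fraction %.3f (n=%d)",
       expr_frac$up_fraction, expr_frac$n_up, expr_frac$down_fraction,
       expr_frac$n_down)

  # ---- stage: cross-tissue -------------------------------------------
  markers <- character(0)
  conv <- NULL
  if (!is.null(inputs$panel)) {
    panel <- inputs$panel[kept, , drop = FALSE]
    full <- cbind(Day0 = rowMeans(b0), Day14 = rowMeans(b14), panel)
    qn <- quantile_normalize(full)
    markers <- call_tissue_specific(
      qn[, colnames(panel), drop = FALSE], inputs$reference,
      lo = th$lo, hi = th$hi, tissue_frac = th$tissue_frac)
    note("tissue: %d tissue-specific probes", length(markers))
    if (length(sig)) {
      conv <- convergence_report(sig, qn[, "Day0", drop = FALSE],
                                 qn[, "Day14", drop = FALSE],
                                 qn[, colnames(panel), drop = FALSE],
                                 inputs$reference)
    }
  }

  disease <- intersect(inputs$disease, kept)
  overlap <- if (length(sig) && length(disease)) {
    overlap_test(sig, disease, kept)
  } else NULL

  # ---- stage: outputs ------------------------------------------------
  paths <- list(
    dml_results = "dml_results.tsv", dmrs = "dmrs.bed",
    annotation = "annotation.tsv", enrichment = "enrichment.tsv",
    ecdf = "ecdf.tsv", expression_bins = "expression_bins.tsv",
    tissue_specific = "tissue_specific.txt", overlap = "overlap.json",
    run_manifest = "run_manifest.json")
  atomically <- function(name, writer) {
    final <- file.path(outdir, paths[[name]])
    tmp <- paste0(final, ".tmp")
    writer(tmp)
    file.rename(tmp, final)
  }
  atomically("dml_results", function(p) write_tsv(as.data.frame(dmls), p))
  atomically("dmrs", function(p) write_dmr_bed(dmrs, p))
  atomically("annotation", function(p) write_tsv(ann, p))
  atomically("enrichment", function(p) write_tsv(enr, p))
  atomically("ecdf", function(p) write_tsv(ecdf_tab, p))
  atomically("expression_bins", function(p) {
    bins <- expr_frac$bins
    bins$up_fraction <- expr_frac$up_fraction
    bins$down_fraction <- expr_frac$down_fraction
    write_tsv(bins, p)
  })
  atomically("tissue_specific", function(p) writeLines(markers, p))
  atomically("overlap", function(p) {
    ov <- if (is.null(overlap)) {
      list(N = length(kept), nA = length(sig), nB = length(disease),
           k = 0L, expected = NA, p_upper = NA)
    } else {
      list(N = overlap$N, nA = overlap$n_a, nB = overlap$n_b,
           k = overlap$k, expected = overlap$expected,
           p_upper = overlap$p_upper)
    }
    jsonlite::write_json(ov, p, auto_unbox = TRUE, digits = NA, na = "null")
  })

  counts <- list(
    probes_in = nrow(inputs$beta_day0), probes_kept = length(kept),
    n_dml = length(sig),
    n_hypo = sum(dmls$significant & dmls$direction == "hypo"),
    n_hyper = sum(dmls$significant & dmls$direction == "hyper"),
    n_dmr = nrow(dmrs), n_tissue_specific = length(markers),
    overlap_k = if (is.null(overlap)) 0L else overlap$k,
    convergence_mean_abs_day0 = if (is.null(conv)) NA else conv$mean_abs_day0,
    convergence_mean_abs_day14 = if (is.null(conv)) NA else conv$mean_abs_day14)
  manifest_out <- list(config = config_echo(config), seed = config$seed,
                       outputs = lapply(paths, identity), counts = counts)
  atomically("run_manifest", function(p) {
    jsonlite::write_json(manifest_out, p, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  })
  note("done: outputs in %s", outdir)
  invisible(manifest_out)
}

read_run_config <- function(path) {
  if (grepl("\\.json$", path)) jsonlite::read_json(path,
                                                   simplifyVector = TRUE)
  else yaml::read_yaml(path)
}

default_thresholds <- function() {
  list(alpha = 0.05, delta_min = 0.10, max_gap = 1000L, min_cpgs = 2L,
       lo = 0.5, hi = 0.8, tissue_frac = 0.9, bin_width = 0.5,
       fc_threshold = 1.0)
}

validate_run_config <- function(config, outdir = NULL, seed = NULL) {
  if (!is.list(config)) {
    stop("config validation error: config must be a list or a YAML/JSON path",
         call. = FALSE)
  }
  has_sim <- !is.null(config$simulate)
  has_inp <- !is.null(config$inputs)
  if (has_sim == has_inp) {
    stop("config validation error: exactly one of 'simulate' or 'inputs' ",
         "must be present", call. = FALSE)
  }
  if (has_inp) {
    req <- c("manifest", "beta_day0", "beta_day14")
    missing <- setdiff(req, names(config$inputs))
    if (length(missing)) {
      stop("config validation error: missing required input path(s): ",
           paste(missing, collapse = ", "), call. = FALSE)
    }
    for (nm in setdiff(names(config$inputs), "reference")) {
      p <- config$inputs[[nm]]
      if (is.character(p) && !file.exists(p)) {
        stop("config validation error: input file not found (", nm, "): ", p,
             call. = FALSE)
      }
    }
  }
  th <- default_thresholds()
  for (nm in names(config$thresholds)) th[[nm]] <- config$thresholds[[nm]]
  bad <- vapply(th[c("delta_min", "max_gap", "min_cpgs", "lo", "hi",
                     "tissue_frac", "bin_width", "fc_threshold")],
                function(v) !is.numeric(v) || v <= 0, logical(1))
  if (th$alpha < 0 || any(bad)) {
    stop("config validation error: thresholds must be positive ",
         "(alpha may be 0)", call. = FALSE)
  }
  config$thresholds <- th
  if (!is.null(seed)) config$seed <- seed
  if (is.null(config$seed)) config$seed <- 1L
  config$seed <- as.integer(config$seed)
  if (!is.null(outdir)) config$outdir <- outdir
  if (is.null(config$outdir)) {
    stop("config validation error: no output directory given", call. = FALSE)
  }
  config
}

# outdir is deliberately not echoed: the manifest stays byte-identical for
# the same config + seed wherever the run lands
config_echo <- function(config) {
  config[intersect(names(config),
                   c("simulate", "inputs", "thresholds", "seed"))]
}

load_pipeline_inputs <- function(paths) {
  manifest <- utils::read.delim(paths$manifest)
  b0 <- read_matrix_tsv(paths$beta_day0)
  b14 <- read_matrix_tsv(paths$beta_day14)
  detection <- if (!is.null(paths$detection)) {
    read_matrix_tsv(paths$detection)
  } else {
    matrix(0, nrow(b0), 1L, dimnames = list(rownames(b0), "none"))
  }
  samples <- if (!is.null(paths$samples)) utils::read.delim(paths$samples)
             else NULL
  islands <- if (!is.null(paths$islands)) read_bed(paths$islands)
             else data.frame(chrom = character(0), start = integer(0),
                             end = integer(0))
  states <- if (!is.null(paths$chrom_states)) read_bed(paths$chrom_states)
            else NULL
  genes <- if (!is.null(paths$genes)) utils::read.delim(paths$genes)
           else NULL
  expr <- if (!is.null(paths$expression)) utils::read.delim(paths$expression)
          else data.frame(gene = character(0), log2fc = numeric(0))
  panel <- if (!is.null(paths$panel)) read_matrix_tsv(paths$panel)
           else NULL
  disease <- if (!is.null(paths$disease)) readLines(paths$disease)
             else character(0)
  truth <- if (!is.null(paths$truth)) read_truth_json(paths$truth) else NULL
  gene_probes <- list()
  if (!is.null(genes)) {
    gene_probes <- lapply(seq_len(nrow(genes)), function(i) {
      g <- genes[i, ]
      manifest$probe_id[manifest$chrom == g$chrom &
                          manifest$pos >= g$start - 1500L &
                          manifest$pos <= g$end + 1500L]
    })
    names(gene_probes) <- genes$gene
  }
  list(manifest = manifest, beta_day0 = b0, beta_day14 = b14,
       detection = detection, samples = samples, islands = islands,
       chrom_states = states, genes = genes, expression = expr,
       gene_probes = gene_probes, panel = panel,
       reference = if (!is.null(paths$reference)) paths$reference
                   else "cartilage",
       disease = disease, truth = truth)
}
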