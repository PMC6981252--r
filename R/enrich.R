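#' Category enrichment of DMLs against the array background
#'
#' For each annotation category (gene feature, island relation or chromatin
#' state), counts DML probes and all tested probes, their proportions, the
#' fold enrichment (DML proportion over background proportion) and an
#' upper-tail hypergeometric p-value for drawing that many category members
#' when sampling the DML set from the tested universe.
#'
#' @param dml_probes character vector of DML probe ids.
#' @param universe_probes character vector of all tested probe ids
#'   (must contain the DMLs).
#' @param annotation named character vector or factor: category per probe
#'   id (names = probe ids). Probes annotated "Unassigned" are excluded
#'   from both numerator and denominator and reported via the
#'   \code{"unassigned"} attribute.
#' @return data.frame: \code{category}, \code{n_dml}, \code{n_universe},
#'   \code{prop_dml}, \code{prop_universe}, \code{fold}, \code{p_upper}.
#' @export
feature_enrichment <- function(dml_probes, universe_probes, annotation) {
  if (!all(dml_probes %in% universe_probes)) {
    stop("DML probes must be a subset of the tested universe", call. = FALSE)
  }
  ann_u <- as.character(annotation[universe_probes])
  unassigned <- sum(ann_u == "Unassigned" | is.na(ann_u))
  keep <- !(ann_u == "Unassigned" | is.na(ann_u))
  universe_probes <- universe_probes[keep]
  ann_u <- ann_u[keep]
  dml_probes <- intersect(dml_probes, universe_probes)
  ann_d <- as.character(annotation[dml_probes])
  cats <- sort(unique(ann_u))
  N <- length(universe_probes)
  n <- length(dml_probes)
  res <- do.call(rbind, lapply(cats, function(cc) {
    K <- sum(ann_u == cc)
    k <- sum(ann_d == cc)
    prop_d <- if (n > 0) k / n else 0
    prop_u <- K / N
    data.frame(category = cc, n_dml = k, n_universe = K,
               prop_dml = prop_d, prop_universe = prop_u,
               fold = if (prop_u > 0) prop_d / prop_u else NA_real_,
               p_upper = stats::phyper(k - 1L, K, N - K, n,
                                       lower.tail = FALSE))
  }))
  rownames(res) <- NULL
  attr(res, "unassigned") <- unassigned
  res
}

#' Empirical cumulative distributions of beta change by category
#'
#' Builds the ECDF of \code{delta_beta} over ALL tested probes within each
#' annotation category, plus a dominance summary: the signed area between
#' each category's ECDF and the pooled ECDF, computed as
#' \code{mean(pooled delta_beta) - mean(category delta_beta)}. A positive
#' area means the category's distribution is shifted toward hypomethylation
#' relative to the pool (its curve lies to the left). The area statistic is
#' a summary defined by this package, not a published quantity.
#'
#' @param delta_beta named numeric vector (names = probe ids) of beta
#'   changes over all tested probes.
#' @param annotation named character vector/factor of categories per probe.
#' @return list of class \code{ecdf_set}: per category a list with
#'   \code{category}, \code{x} (sorted delta beta), \code{f} (cumulative
#'   fractions), \code{area_vs_pooled}, \code{n}.
#' @export
ecdf_by_category <- function(delta_beta, annotation) {
  ann <- as.character(annotation[names(delta_beta)])
  keep <- !is.na(ann) & ann != "Unassigned"
  delta_beta <- delta_beta[keep]; ann <- ann[keep]
  pooled_mean <- mean(delta_beta)
  out <- lapply(sort(unique(ann)), function(cc) {
    v <- sort(unname(delta_beta[ann == cc]))
    list(category = cc, x = v, f = seq_along(v) / length(v),
         area_vs_pooled = pooled_mean - mean(v), n = length(v))
  })
  names(out) <- vapply(out, `[[`, "", "category")
  class(out) <- "ecdf_set"
  out
}

#' @export
print.ecdf_set <- function(x, ...) {
  cat("Beta-change ECDFs by category (area > 0: shifted hypomethylated vs pool)\n")
  for (e in x) {
    cat(sprintf("  %-12s n = %6d  median = %+.4f  area vs pooled = %+.4f\n",
                e$category, e$n, stats::median(e$x), e$area_vs_pooled))
  }
  invisible(x)
}

#' Fraction of genes with a DML across expression bins
#'
#' Bins genes by log2 expression fold-change into intervals of
#' \code{bin_width} and reports, per bin, the fraction of genes with at
#' least one DML probe; also the Fig.-2A-style summary: among genes at
#' least \code{fc_threshold} up- or down-regulated on log2, the fraction
#' carrying a DML. Genes in the expression table without mapped probes
#' count as having no DML (reported via the \code{"unmapped"} attribute).
#'
#' @param expression data.frame with columns \code{gene} and \code{log2fc}.
#' @param gene_probes named list: probe-id vector per gene.
#' @param dml_probes character vector of DML probe ids.
#' @param bin_width log2 fold-change bin width (default 0.5).
#' @param fc_threshold log2 threshold defining up-/down-regulated genes.
#' @return list with \code{bins} (data.frame: bin_lo, bin_hi, n_genes,
#'   n_with_dml, fraction), \code{up_fraction}, \code{down_fraction},
#'   \code{n_up}, \code{n_down}.
#' @export
expression_dml_fraction <- function(expression, gene_probes, dml_probes,
                                    bin_width = 0.5, fc_threshold = 1.0) {
  fc <- expression$log2fc
  keep <- is.finite(fc)
  expression <- expression[keep, , drop = FALSE]
  fc <- fc[keep]
  unmapped <- setdiff(expression$gene, names(gene_probes))
  has_dml <- vapply(expression$gene, function(g) {
    pr <- gene_probes[[g]]
    !is.null(pr) && any(pr %in% dml_probes)
  }, logical(1))
  lo <- floor(min(fc) / bin_width) * bin_width
  hi <- ceiling(max(fc) / bin_width) * bin_width
  if (hi <= lo) hi <- lo + bin_width
  breaks <- seq(lo, hi, by = bin_width)
  bin <- cut(fc, breaks, include.lowest = TRUE, right = FALSE)
  bins <- data.frame(bin_lo = breaks[-length(breaks)],
                     bin_hi = breaks[-1],
                     n_genes = as.integer(table(bin)),
                     n_with_dml = as.integer(tapply(has_dml, bin, sum,
                                                    default = 0L)))
  bins$fraction <- ifelse(bins$n_genes > 0, bins$n_with_dml / bins$n_genes, NA)
  up <- fc >= fc_threshold
  down <- fc <= -fc_threshold
  list(bins = bins,
       up_fraction = if (any(up)) mean(has_dml[up]) else NA_real_,
       down_fraction = if (any(down)) mean(has_dml[down]) else NA_real_,
       n_up = sum(up), n_down = sum(down),
       unmapped = unmapped)
}
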