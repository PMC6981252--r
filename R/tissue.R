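#' Call tissue-specific hypomethylated CpGs
#'
#' A probe is tissue-specific when its reference-tissue mean beta is below
#' \code{lo} AND the fraction of non-reference tissues whose mean beta
#' exceeds \code{hi} is strictly greater than \code{tissue_frac}. All three
#' thresholds are strict, matching the "< 0.5 in cartilage and > 0.8 in
#' > 90% of other tissues" marker rule; the reference tissue is excluded
#' from the denominator.
#'
#' @param panel probe x tissue matrix of mean beta values
#'   (quantile-normalised), with probe rownames and tissue colnames.
#' @param reference name of the reference (cartilage-like) column.
#' @param lo reference-tissue upper beta bound (strict <).
#' @param hi other-tissue lower beta bound (strict >).
#' @param tissue_frac minimum fraction of high other-tissues (strict >).
#' @return character vector of tissue-specific probe ids.
#' @export
call_tissue_specific <- function(panel, reference, lo = 0.5, hi = 0.8,
                                 tissue_frac = 0.9) {
  if (!reference %in% colnames(panel)) {
    stop("configuration error: reference tissue '", reference,
         "' not in panel", call. = FALSE)
  }
  others <- setdiff(colnames(panel), reference)
  if (length(others) < 2L) {
    stop("configuration error: need >= 2 non-reference tissues", call. = FALSE)
  }
  ref_lo <- panel[, reference] < lo
  frac_hi <- rowMeans(panel[, others, drop = FALSE] > hi)
  rownames(panel)[ref_lo & frac_hi > tissue_frac]
}

#' Hypergeometric overlap test between two probe sets
#'
#' Upper-tail probability (including the observed count) of seeing at
#' least k shared probes when two subsets of the given sizes are drawn from
#' a common universe. Computed with the log-stable hypergeometric survival
#' function; symmetric in the two sets.
#'
#' @param set_a,set_b character vectors of probe ids, non-empty subsets of
#'   \code{universe}.
#' @param universe character vector of all jointly tested probe ids.
#' @return list of class \code{overlap_test}: \code{N}, \code{n_a},
#'   \code{n_b}, \code{k}, \code{expected} (= n_a n_b / N),
#'   \code{p_upper}.
#' @export
overlap_test <- function(set_a, set_b, universe) {
  if (length(set_a) == 0L || length(set_b) == 0L) {
    stop("empty set: overlap test requires non-empty sets", call. = FALSE)
  }
  set_a <- unique(set_a); set_b <- unique(set_b)
  universe <- unique(universe)
  if (!all(set_a %in% universe) || !all(set_b %in% universe)) {
    stop("validation error: sets must be subsets of the universe",
         call. = FALSE)
  }
  N <- length(universe)
  n_a <- length(set_a); n_b <- length(set_b)
  k <- length(intersect(set_a, set_b))
  p <- stats::phyper(k - 1L, n_b, N - n_b, n_a, lower.tail = FALSE)
  structure(list(N = N, n_a = n_a, n_b = n_b, k = k,
                 expected = n_a * n_b / N, p_upper = p),
            class = "overlap_test")
}

#' @export
print.overlap_test <- function(x, ...) {
  cat(sprintf(
    "Hypergeometric overlap: k = %d of n_a = %d, n_b = %d in N = %d (expected %.2f)\n  upper-tail p = %.4g\n",
    x$k, x$n_a, x$n_b, x$N, x$expected, x$p_upper))
  invisible(x)
}

#' Descriptive convergence of DML methylation toward a reference tissue
#'
#' For a DML set, tabulates baseline (Day0) and followup (Day14) mean
#' betas next to the reference-tissue and other-tissue panel means, and
#' summarises whether followup methylation sits closer to the reference
#' than baseline does. Purely descriptive, no test.
#'
#' @param dml_probes character vector of DML probe ids.
#' @param beta0,beta14 probe x sample beta matrices.
#' @param panel probe x tissue mean-beta matrix.
#' @param reference reference tissue column name.
#' @return list of class \code{convergence_report}: \code{table} (per-probe
#'   data.frame), \code{mean_abs_day0}, \code{mean_abs_day14},
#'   \code{tissue_means}.
#' @export
convergence_report <- function(dml_probes, beta0, beta14, panel, reference) {
  dml_probes <- intersect(dml_probes, rownames(panel))
  if (length(dml_probes) == 0L) {
    warning("empty DML set: convergence report is empty")
    return(structure(list(table = data.frame(), mean_abs_day0 = NA_real_,
                          mean_abs_day14 = NA_real_,
                          tissue_means = numeric(0)),
                     class = "convergence_report"))
  }
  others <- setdiff(colnames(panel), reference)
  tab <- data.frame(
    probe_id = dml_probes,
    day0 = rowMeans(beta0[dml_probes, , drop = FALSE]),
    day14 = rowMeans(beta14[dml_probes, , drop = FALSE]),
    reference = panel[dml_probes, reference],
    other_mean = rowMeans(panel[dml_probes, others, drop = FALSE]),
    row.names = NULL)
  structure(list(
    table = tab,
    mean_abs_day0 = mean(abs(tab$day0 - tab$reference)),
    mean_abs_day14 = mean(abs(tab$day14 - tab$reference)),
    tissue_means = colMeans(panel[dml_probes, , drop = FALSE])),
    class = "convergence_report")
}

#' @export
print.convergence_report <- function(x, ...) {
  if (!nrow(x$table)) {
    cat("Convergence report: empty DML set\n")
    return(invisible(x))
  }
  cat(sprintf(
    "Convergence of %d DMLs toward the reference tissue\n  mean |Day0  - reference| = %.4f\n  mean |Day14 - reference| = %.4f\n",
    nrow(x$table), x$mean_abs_day0, x$mean_abs_day14))
  invisible(x)
}

#' Direction concordance between two effect sets
#'
#' Fraction of common probes whose effects share a sign. Zero effects are
#' counted as discordant and reported separately.
#'
#' @param common_probes probe ids present in both effect vectors.
#' @param delta_a,delta_b named numeric vectors of per-probe effects.
#' @return list: \code{concordance}, \code{n}, \code{n_zero}.
#' @export
direction_concordance <- function(common_probes, delta_a, delta_b) {
  a <- delta_a[common_probes]
  b <- delta_b[common_probes]
  zero <- a == 0 | b == 0
  conc <- sign(a) == sign(b) & !zero
  list(concordance = if (length(a)) mean(conc) else NA_real_,
       n = length(a), n_zero = sum(zero))
}
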