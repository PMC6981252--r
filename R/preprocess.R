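#' Convert beta values to M values
#'
#' \code{M = log2(beta / (1 - beta))} after clamping beta into
#' \code{[eps, 1 - eps]}. The clamp bounds M and avoids infinities at
#' beta = 0 or 1; within the clamp range the transform is exactly invertible
#' by [m_to_beta()].
#'
#' @param beta numeric vector or matrix of methylation fractions in [0, 1].
#' @param eps clamp width (default 0.001).
#' @return M values, same shape as the input.
#' @export
beta_to_m <- function(beta, eps = 0.001) {
  if (any(beta < 0 | beta > 1, na.rm = TRUE)) {
    stop("domain error: beta values must lie in [0, 1]", call. = FALSE)
  }
  b <- pmin(pmax(beta, eps), 1 - eps)
  out <- log2(b / (1 - b))
  if (is.matrix(beta)) out <- matrix(out, nrow(beta), dimnames = dimnames(beta))
  out
}

#' Convert M values to beta values
#'
#' Inverse of [beta_to_m()]: \code{beta = 2^M / (1 + 2^M)}, the logistic map
#' in base 2. Always returns values in (0, 1).
#'
#' @param m numeric vector or matrix of M values.
#' @return beta values, same shape as the input.
#' @export
m_to_beta <- function(m) {
  out <- stats::plogis(m * log(2))
  if (is.matrix(m)) out <- matrix(out, nrow(m), dimnames = dimnames(m))
  out
}

#' Quality-control filtering of probes
#'
#' Removes probes that fail detection (p > \code{p_max} in ANY sample), lie
#' on a sex chromosome, or are SNP-flagged in the manifest — the standard
#' 450K QC triplet. Counts removed per criterion are attached as the
#' \code{"removed"} attribute and reported via message().
#'
#' @param betas probe x sample beta matrix with probe ids as rownames.
#' @param detection probe x sample detection p-value matrix aligned to
#'   \code{betas} (same probes; columns may differ, e.g. both timepoints'
#'   detection matrices cbound together).
#' @param manifest probe manifest containing \code{probe_id},
#'   \code{sex_chrom_flag} and \code{snp_flag}.
#' @param p_max detection p-value threshold (default 0.05, strict >).
#' @param quiet suppress the per-criterion message.
#' @return the row-subset beta matrix of surviving probes.
#' @export
filter_probes <- function(betas, detection, manifest, p_max = 0.05,
                          quiet = FALSE) {
  ids <- rownames(betas)
  if (is.null(ids)) stop("betas must have probe ids as rownames", call. = FALSE)
  missing_det <- setdiff(ids, rownames(detection))
  if (length(missing_det)) {
    stop("alignment error: probes absent from detection matrix: ",
         paste(utils::head(missing_det, 5L), collapse = ", "),
         if (length(missing_det) > 5L) ", ...", call. = FALSE)
  }
  missing_man <- setdiff(ids, manifest$probe_id)
  if (length(missing_man)) {
    stop("alignment error: probes absent from manifest: ",
         paste(utils::head(missing_man, 5L), collapse = ", "),
         if (length(missing_man) > 5L) ", ...", call. = FALSE)
  }
  det <- detection[ids, , drop = FALSE]
  man <- manifest[match(ids, manifest$probe_id), ]
  fail_det <- apply(det > p_max, 1L, any)
  fail_sex <- man$sex_chrom_flag == 1L
  fail_snp <- man$snp_flag == 1L
  removed <- c(detection = sum(fail_det), sex_chromosome = sum(fail_sex),
               snp = sum(fail_snp))
  keep <- !(fail_det | fail_sex | fail_snp)
  if (!quiet) {
    message(sprintf(
      "filter_probes: removed %d (detection p > %g), %d (sex chromosome), %d (SNP); %d/%d probes retained",
      removed[["detection"]], p_max, removed[["sex_chromosome"]],
      removed[["snp"]], sum(keep), length(keep)))
  }
  out <- betas[keep, , drop = FALSE]
  attr(out, "removed") <- removed
  out
}

#' Quantile normalisation across columns
#'
#' Forces every column onto the common distribution given by the
#' across-column mean of order statistics; ties within a column receive the
#' mean of the reference values at their tied ranks. Used here on per-group
#' mean beta profiles when comparing tissues (one column per
#' tissue/condition). Row and column names are preserved. The operation is
#' idempotent.
#'
#' @param x numeric matrix (probes x samples), at least two columns, no
#'   missing values.
#' @return normalised matrix: every column has the identical sorted value
#'   multiset.
#' @export
quantile_normalize <- function(x) {
  x <- as.matrix(x)
  if (ncol(x) < 2L) {
    stop("quantile normalisation undefined for a single column", call. = FALSE)
  }
  if (anyNA(x)) {
    stop("missing values are not allowed; impute or drop beforehand",
         call. = FALSE)
  }
  out <- limma::normalizeQuantiles(x, ties = TRUE)
  dimnames(out) <- dimnames(x)
  out
}
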