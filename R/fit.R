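#' Per-probe paired differences on the M scale
#'
#' For each probe, forms donor-wise differences \code{M14 - M0} over complete
#' pairs and returns their mean, sample variance and residual degrees of
#' freedom (number of pairs minus one). Samples without a partner in the
#' other matrix are dropped with a warning.
#'
#' @param m0,m14 probe x sample M-value matrices (same probes).
#' @param pairing data.frame mapping \code{sample_id} to \code{donor} and
#'   \code{group} ("Day0"/"Day14" or equivalent baseline/followup labels);
#'   if NULL, columns are paired by position.
#' @return list of class \code{paired_fit} with per-probe vectors
#'   \code{mean_diff}, \code{s2}, \code{df}, scalar \code{n_pairs}, the
#'   per-pair difference matrix \code{diffs}, and \code{probe_id}.
#' @export
fit_paired <- function(m0, m14, pairing = NULL) {
  if (!identical(rownames(m0), rownames(m14))) {
    stop("alignment error: m0 and m14 must share the same probes in order",
         call. = FALSE)
  }
  if (is.null(pairing)) {
    if (ncol(m0) != ncol(m14)) {
      n <- min(ncol(m0), ncol(m14))
      warning("unequal sample counts; dropping ",
              abs(ncol(m0) - ncol(m14)), " unpaired sample(s)")
      m0 <- m0[, seq_len(n), drop = FALSE]
      m14 <- m14[, seq_len(n), drop = FALSE]
    }
    d0 <- m0; d14 <- m14
    donors <- paste0("pair", seq_len(ncol(m0)))
  } else {
    p0 <- pairing[match(colnames(m0), pairing$sample_id), ]
    p14 <- pairing[match(colnames(m14), pairing$sample_id), ]
    donors <- intersect(p0$donor, p14$donor)
    dropped <- setdiff(union(p0$donor, p14$donor), donors)
    if (length(dropped)) {
      warning("dropping unpaired donor(s): ", paste(dropped, collapse = ", "))
    }
    d0 <- m0[, match(donors, p0$donor), drop = FALSE]
    d14 <- m14[, match(donors, p14$donor), drop = FALSE]
  }
  n_pairs <- ncol(d0)
  if (n_pairs < 2L) {
    stop("insufficient replication: need >= 2 complete donor pairs",
         call. = FALSE)
  }
  diffs <- d14 - d0
  colnames(diffs) <- donors
  mean_diff <- rowMeans(diffs)
  s2 <- rowSums((diffs - mean_diff)^2) / (n_pairs - 1L)
  structure(list(probe_id = rownames(m0), mean_diff = mean_diff, s2 = s2,
                 df = rep(n_pairs - 1L, nrow(m0)), n_pairs = n_pairs,
                 diffs = diffs),
            class = "paired_fit")
}

#' Empirical-Bayes prior for per-probe variances
#'
#' Method-of-moments fit of the scaled-F marginal model for sample
#' variances (Smyth-style): on \code{e_g = log s2_g - digamma(df_g/2) +
#' log(df_g/2)}, the excess spread of \code{e} over its sampling component
#' \code{trigamma(df_g/2)} identifies the prior degrees of freedom
#' \code{d0} via trigamma inversion (Newton iteration, relative tolerance
#' 1e-8), and the centre identifies the prior variance \code{s0^2}. When
#' the observed spread does not exceed the sampling component the prior is
#' degenerate: \code{d0 = Inf} and \code{s0^2 = exp(mean(e))}.
#'
#' @param fit a \code{paired_fit} (or any list with \code{s2} and \code{df}).
#' @return list of class \code{variance_prior} with \code{d0} and \code{s02}.
#' @export
estimate_prior <- function(fit) {
  s2 <- fit$s2
  df <- fit$df
  use <- is.finite(s2) & s2 > 0 & df > 0
  if (sum(use) < 2L) {
    stop("need >= 2 probes with positive variance to estimate the prior",
         call. = FALSE)
  }
  s2 <- s2[use]; df <- df[use]
  e <- log(s2) - digamma(df / 2) + log(df / 2)
  emean <- mean(e)
  evar <- stats::var(e)
  excess <- evar - mean(trigamma(df / 2))
  if (!is.finite(excess) || excess <= 0) {
    prior <- list(d0 = Inf, s02 = exp(emean))
  } else {
    d0 <- 2 * trigamma_inverse(excess)
    s02 <- exp(emean + digamma(d0 / 2) - log(d0 / 2))
    prior <- list(d0 = d0, s02 = s02)
  }
  class(prior) <- "variance_prior"
  prior
}

# Solve trigamma(y) = x for y > 0 by Newton iteration on the monotone
# decreasing function, as in the standard moment-matching scheme.
trigamma_inverse <- function(x, tol = 1e-8, maxit = 100L) {
  if (x > 1e7) return(1 / sqrt(x))
  if (x < 1e-6) return(1 / x)
  y <- 0.5 + 1 / x
  for (i in seq_len(maxit)) {
    tri <- trigamma(y)
    dif <- tri * (1 - tri / x) / psigamma(y, 2L)
    y <- y + dif
    if (abs(dif) / y < tol) break
  }
  y
}

#' Moderated t statistics from a paired fit and a variance prior
#'
#' Shrinks each probe's variance toward the prior,
#' \code{s2_post = (d0 s0^2 + df s2) / (d0 + df)}, and forms the moderated
#' statistic \code{t = mean_diff / sqrt(s2_post / n_pairs)} with two-sided
#' p-values from the t distribution on \code{d0 + df} degrees of freedom
#' (the normal limit when \code{d0 = Inf}). With \code{d0 = 0} this is the
#' ordinary paired t-test. The single-contrast moderated F equals
#' \code{t^2} with an identical p-value.
#'
#' @param fit a \code{paired_fit}.
#' @param prior a \code{variance_prior} (list with \code{d0}, \code{s02}).
#' @return data.frame with columns \code{probe_id}, \code{t}, \code{F},
#'   \code{df_total}, \code{p}.
#' @export
moderate <- function(fit, prior) {
  d0 <- prior$d0; s02 <- prior$s02
  if (is.infinite(d0)) {
    s2_post <- rep(s02, length(fit$s2))
    df_total <- rep(Inf, length(fit$s2))
  } else if (d0 == 0) {
    s2_post <- fit$s2
    df_total <- fit$df
  } else {
    s2_post <- (d0 * s02 + fit$df * fit$s2) / (d0 + fit$df)
    df_total <- d0 + fit$df
  }
  tval <- fit$mean_diff / sqrt(s2_post / fit$n_pairs)
  p <- 2 * stats::pt(-abs(tval), df = df_total)
  data.frame(probe_id = fit$probe_id, t = tval, F = tval^2,
             df_total = df_total, p = p, row.names = NULL)
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate adjustment: at sorted rank i,
#' \code{adj_(i) = min_{j >= i} min(1, m p_(j) / j)}, mapped back to input
#' order.
#'
#' @param p vector of raw p-values in [0, 1].
#' @return adjusted p-values in input order.
#' @export
adjust_bh <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) {
    stop("domain error: p-values must lie in [0, 1]", call. = FALSE)
  }
  stats::p.adjust(p, method = "BH")
}

#' Fit the paired empirical-Bayes differential methylation model
#'
#' The package's central fitting function. Converts paired beta matrices to
#' M values, forms donor-wise paired differences, estimates the variance
#' prior across probes and computes moderated t/F statistics with BH-adjusted
#' p-values. Testing is on the M scale; the reported effect
#' \code{delta_beta} is the difference of group mean betas (followup minus
#' baseline), the scale on which percentage-change thresholds are applied.
#'
#' @param beta0,beta14 probe x sample beta matrices for baseline (Day0) and
#'   followup (Day14), same probes.
#' @param pairing optional sample sheet (\code{sample_id}, \code{donor},
#'   \code{group}); NULL pairs columns by position.
#' @param eps clamp for the beta-to-M transform.
#' @return object of class \code{dm_fit}: a list with the \code{paired_fit},
#'   the \code{variance_prior}, \code{n_pairs} and a per-probe \code{table}
#'   (probe_id, delta_beta, mean_diff_m, t, F, p, p_adj).
#' @seealso [call_dmls()] for thresholded DML calls.
#' @export
dm_fit <- function(beta0, beta14, pairing = NULL, eps = 0.001) {
  fit <- fit_paired(beta_to_m(beta0, eps), beta_to_m(beta14, eps), pairing)
  prior <- estimate_prior(fit)
  mod <- moderate(fit, prior)
  delta_beta <- rowMeans(beta14) - rowMeans(beta0)
  tab <- data.frame(probe_id = fit$probe_id,
                    delta_beta = unname(delta_beta),
                    mean_diff_m = unname(fit$mean_diff),
                    t = mod$t, F = mod$F, p = mod$p,
                    p_adj = adjust_bh(mod$p), row.names = NULL)
  structure(list(fit = fit, prior = prior, n_pairs = fit$n_pairs,
                 table = tab),
            class = "dm_fit")
}

#' @export
print.dm_fit <- function(x, ...) {
  cat("Paired empirical-Bayes differential methylation fit\n")
  cat(sprintf("  probes: %d, donor pairs: %d\n", nrow(x$table), x$n_pairs))
  cat(sprintf("  variance prior: d0 = %s, s0^2 = %.4g\n",
              format(x$prior$d0, digits = 4), x$prior$s02))
  cat(sprintf("  probes with adjusted p < 0.05: %d\n",
              sum(x$table$p_adj < 0.05)))
  invisible(x)
}

#' @export
summary.dm_fit <- function(object, alpha = 0.05, delta_min = 0.10, ...) {
  calls <- call_dmls(object, alpha = alpha, delta_min = delta_min)
  print(object)
  cat(sprintf("  DMLs (adj p < %g and |delta beta| > %g): %d (%d hypo, %d hyper)\n",
              alpha, delta_min, sum(calls$significant),
              sum(calls$significant & calls$direction == "hypo"),
              sum(calls$significant & calls$direction == "hyper")))
  invisible(calls)
}

#' @export
coef.dm_fit <- function(object, ...) {
  stats::setNames(object$table$mean_diff_m, object$table$probe_id)
}

#' @export
residuals.dm_fit <- function(object, ...) {
  object$fit$diffs - object$fit$mean_diff
}

#' Volcano-style plot of a differential methylation fit
#'
#' @param x a \code{dm_fit}.
#' @param alpha,delta_min thresholds used to highlight DML calls.
#' @param ... passed to [plot()].
#' @export
plot.dm_fit <- function(x, alpha = 0.05, delta_min = 0.10, ...) {
  tab <- x$table
  sig <- tab$p_adj < alpha & abs(tab$delta_beta) > delta_min
  plot(tab$delta_beta, -log10(pmax(tab$p, 1e-300)),
       pch = 20, cex = 0.4, col = ifelse(sig, "firebrick", "grey60"),
       xlab = expression(Delta * beta ~ "(Day14 - Day0)"),
       ylab = expression(-log[10] ~ p), ...)
  abline(v = c(-delta_min, delta_min), lty = 3)
  invisible(x)
}

#' Call differentially methylated loci
#'
#' A probe is a DML when its BH-adjusted p-value is below \code{alpha} AND
#' its absolute beta change strictly exceeds \code{delta_min} (the
#' ">10% methylation change" rule with the default 0.10). Direction is
#' hypo when \code{delta_beta < 0}, hyper when positive.
#'
#' @param object a \code{dm_fit}.
#' @param alpha adjusted-significance threshold (strict <).
#' @param delta_min minimum absolute beta change (strict >).
#' @return data.frame of class \code{dml_calls}: the fit table plus
#'   \code{significant} and \code{direction} columns.
#' @export
call_dmls <- function(object, alpha = 0.05, delta_min = 0.10) {
  tab <- object$table
  tab$significant <- tab$p_adj < alpha & abs(tab$delta_beta) > delta_min
  tab$direction <- ifelse(tab$delta_beta < 0, "hypo",
                   ifelse(tab$delta_beta > 0, "hyper", "none"))
  class(tab) <- c("dml_calls", "data.frame")
  tab
}

#' @export
print.dml_calls <- function(x, ...) {
  n_sig <- sum(x$significant)
  cat(sprintf("DML calls: %d significant of %d probes (%d hypo, %d hyper)\n",
              n_sig, nrow(x), sum(x$significant & x$direction == "hypo"),
              sum(x$significant & x$direction == "hyper")))
  if (n_sig) {
    print.data.frame(utils::head(
      x[x$significant, c("probe_id", "delta_beta", "t", "p", "p_adj",
                         "direction")], 10L), row.names = FALSE)
    if (n_sig > 10L) cat("  ...", n_sig - 10L, "more\n")
  }
  invisible(x)
}
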