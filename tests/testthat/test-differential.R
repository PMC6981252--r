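make_m_pair <- function(diffs) {
  # build M0/M14 matrices realising the given per-probe difference rows
  d <- as.matrix(diffs)
  m0 <- matrix(0, nrow(d), ncol(d),
               dimnames = list(sprintf("p%d", seq_len(nrow(d))),
                               sprintf("d%d_Day0", seq_len(ncol(d)))))
  m14 <- d
  dimnames(m14) <- list(rownames(m0), sprintf("d%d_Day14", seq_len(ncol(d))))
  list(m0 = m0, m14 = m14)
}

test_that("paired fit returns the mean, variance and df of donor differences", {
  mp <- make_m_pair(rbind(c(1, 1, 1), c(0, 2, 1)))
  fit <- fit_paired(mp$m0, mp$m14)
  expect_equal(unname(fit$mean_diff), c(1, 1))
  expect_equal(unname(fit$s2), c(0, 1))
  expect_equal(unname(fit$df), c(2, 2))
  # two-donor case: Delta = (0, 2) -> mean 1, var 2, df 1
  mp2 <- make_m_pair(rbind(c(0, 2)))
  fit2 <- fit_paired(mp2$m0, mp2$m14)
  expect_equal(unname(fit2$mean_diff), 1)
  expect_equal(unname(fit2$s2), 2)
  expect_equal(unname(fit2$df), 1)
  # identical matrices -> all differences zero
  m <- matrix(rnorm(20), 5, 4, dimnames = list(paste0("p", 1:5), paste0("s", 1:4)))
  expect_true(all(fit_paired(m, m)$mean_diff == 0))
  expect_error(fit_paired(m[, 1, drop = FALSE], m[, 1, drop = FALSE]),
               "insufficient")
})

test_that("pairing by donor map reorders columns correctly", {
  set.seed(1)
  m0 <- matrix(rnorm(12), 3, 4,
               dimnames = list(paste0("p", 1:3), paste0("a", 1:4)))
  m14 <- (m0 + 1)[, c(3, 1, 4, 2)]
  colnames(m14) <- paste0("b", c(3, 1, 4, 2))
  pairing <- data.frame(sample_id = c(paste0("a", 1:4), paste0("b", 1:4)),
                        donor = rep(paste0("don", 1:4), 2),
                        group = rep(c("Day0", "Day14"), each = 4))
  fit <- fit_paired(m0, m14, pairing)
  expect_equal(unname(fit$mean_diff), rep(1, 3))
  expect_equal(unname(fit$s2), rep(0, 3))
})

test_that("prior estimation recovers generating hyperparameters and limits", {
  # parameter recovery from the scaled-F marginal model
  set.seed(2024)
  n <- 20000L; d0 <- 4; s02 <- 0.25; d <- 10L
  sigma2 <- d0 * s02 / rchisq(n, df = d0)
  s2 <- sigma2 * rchisq(n, df = d) / d
  prior <- estimate_prior(list(s2 = s2, df = rep(d, n)))
  expect_lt(abs(prior$d0 - d0) / d0, 0.10)
  expect_lt(abs(prior$s02 - s02) / s02, 0.05)

  # all variances equal -> degenerate prior
  eq <- estimate_prior(list(s2 = rep(0.3, 50), df = rep(3, 50)))
  expect_identical(eq$d0, Inf)

  # two probes: the moment equations solved independently with uniroot
  s2_2 <- c(1, exp(1)); df_2 <- c(10, 10)
  prior2 <- estimate_prior(list(s2 = s2_2, df = df_2))
  e <- log(s2_2) - digamma(5) + log(5)
  excess <- var(e) - trigamma(5)
  oracle_d0 <- 2 * uniroot(function(y) trigamma(y) - excess,
                           c(1e-3, 1e3), tol = 1e-12)$root
  expect_equal(prior2$d0, oracle_d0, tolerance = 1e-6)
})

test_that("moderation matches direct evaluation of the shrinkage formulas", {
  # d = 1, s2 = 0.04, df = 2, n_pairs = 3, d0 = 4, s02 = 0.04
  fit <- list(probe_id = "p1", mean_diff = 1, s2 = 0.04, df = 2, n_pairs = 3)
  mod <- moderate(fit, list(d0 = 4, s02 = 0.04))
  expect_equal(mod$t, 1 / (0.2 / sqrt(3)))
  expect_equal(mod$df_total, 6)
  expect_equal(mod$p, 2 * pt(-sqrt(3) / 0.2, df = 6))
  expect_equal(mod$F, mod$t^2)
  # zero effect -> t = 0, p = 1
  mod0 <- moderate(list(probe_id = "p", mean_diff = 0, s2 = 0.1, df = 3,
                        n_pairs = 4), list(d0 = 4, s02 = 0.1))
  expect_equal(mod0$t, 0)
  expect_equal(mod0$p, 1)
})

test_that("with d0 = 0 moderation reproduces the ordinary paired t-test", {
  set.seed(77)
  n <- 1000L; np <- 5L
  diffs <- matrix(rnorm(n * np, 0.2, 1), n, np)
  mp <- make_m_pair(diffs)
  fit <- fit_paired(mp$m0, mp$m14)
  mod <- moderate(fit, list(d0 = 0, s02 = 1))
  oracle <- t(apply(diffs, 1L, function(x) {
    tt <- t.test(x)
    c(tt$statistic, tt$p.value)
  }))
  expect_equal(mod$t, unname(oracle[, 1]), tolerance = 1e-10)
  expect_equal(mod$p, unname(oracle[, 2]), tolerance = 1e-10)
})

test_that("the moderated fit agrees with the reference empirical-Bayes implementation", {
  set.seed(88)
  n <- 400L; np <- 4L
  diffs <- matrix(rnorm(n * np, 0, sqrt(rchisq(n, 3) / 3)), n, np)
  mp <- make_m_pair(diffs)
  fit <- fit_paired(mp$m0, mp$m14)
  prior <- estimate_prior(fit)
  mod <- moderate(fit, prior)
  lf <- limma::eBayes(limma::lmFit(diffs, matrix(1, np, 1)))
  expect_equal(prior$d0, lf$df.prior, tolerance = 1e-6)
  expect_equal(prior$s02, lf$s2.prior, tolerance = 1e-6)
  expect_equal(mod$t, lf$t[, 1], ignore_attr = TRUE, tolerance = 1e-8)
  expect_equal(mod$p, lf$p.value[, 1], ignore_attr = TRUE, tolerance = 1e-8)
})

test_that("BH adjustment follows the step-up rule and its invariants", {
  expect_equal(adjust_bh(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(adjust_bh(0.3), 0.3)
  expect_equal(adjust_bh(rep(0.07, 5)), rep(0.07, 5))
  expect_error(adjust_bh(c(0.5, 1.2)), "domain")
  set.seed(3)
  p <- runif(100)
  adj <- adjust_bh(p)
  expect_true(all(adj >= p))
  expect_true(all(diff(adj[order(p)]) >= -1e-15))
})

test_that("DML calling applies strict thresholds on adjusted p and beta change", {
  tab <- data.frame(probe_id = paste0("p", 1:4),
                    delta_beta = c(-0.09, -0.15, 0.15, -0.10),
                    mean_diff_m = 0, t = 0, F = 0,
                    p = c(0.001, 0.001, 0.001, 0.001),
                    p_adj = c(0.04, 0.04, 0.06, 0.04))
  calls <- call_dmls(structure(list(table = tab), class = "dm_fit"))
  expect_identical(calls$significant, c(FALSE, TRUE, FALSE, FALSE))
  expect_identical(calls$direction[2], "hypo")
  expect_identical(calls$direction[3], "hyper")
})

test_that("null simulation gives calibrated raw p-values and hypomethylation dominates planted calls", {
  cfg <- sim_config(n_probes = 4000L, fraction_planted_dml = 0,
                    dmr_count = 0L, seed = 23L)
  sim <- simulate_manifest(cfg)
  paired <- simulate_paired_betas(sim, cfg)
  b0 <- filter_probes(paired$beta_day0,
                      cbind(paired$detection_day0, paired$detection_day14),
                      sim$manifest, quiet = TRUE)
  fit <- dm_fit(b0, paired$beta_day14[rownames(b0), ], paired$samples)
  expect_gt(ks.test(fit$table$p, "punif")$p.value, 0.01)
  expect_lt(abs(mean(fit$table$p < 0.05) - 0.05), 0.01)

  cfg2 <- sim_config(n_probes = 4000L, seed = 23L)
  sim2 <- simulate_manifest(cfg2)
  paired2 <- simulate_paired_betas(sim2, cfg2)
  b02 <- filter_probes(paired2$beta_day0,
                       cbind(paired2$detection_day0, paired2$detection_day14),
                       sim2$manifest, quiet = TRUE)
  calls <- call_dmls(dm_fit(b02, paired2$beta_day14[rownames(b02), ],
                            paired2$samples))
  expect_gte(mean(calls$direction[calls$significant] == "hypo"), 0.9)
})

test_that("dm_fit methods expose coefficients, residuals and a summary", {
  tiny <- make_tiny_paired()
  fit <- dm_fit(tiny$paired$beta_day0, tiny$paired$beta_day14,
                tiny$paired$samples)
  expect_s3_class(fit, "dm_fit")
  expect_length(coef(fit), nrow(tiny$paired$beta_day0))
  r <- residuals(fit)
  expect_equal(dim(r), c(nrow(tiny$paired$beta_day0), tiny$cfg$n_donors))
  expect_equal(unname(rowSums(r)), rep(0, nrow(r)), tolerance = 1e-12)
  expect_output(print(fit), "donor pairs: 4")
  invisible(capture.output(s <- summary(fit)))
  expect_s3_class(s, "dml_calls")
})
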