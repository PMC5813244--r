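make_null_pvals <- function(p = 300, samples = 24, perms = 400, seed = 5,
                            max_corr = 0.6, bg = 0.1) {
  cfg <- sim_config(p, samples, seed = seed, max_correlation = max_corr,
                    background_correlation = bg)
  m <- beta_to_m(generate_beta(generate_manifest(cfg), cfg))
  permute_min_p(m, assign_labels(samples, seed = 1), perms, seed = seed,
                keep_p = TRUE)
}

test_that("density 1 reproduces the full-set permutation threshold exactly", {
  null <- make_null_pvals()
  curve <- subsample_curve(null$p_values, densities = c(0.5, 1),
                           n_replicates = 3, seed = 2)
  expect_equal(curve$alpha_5pct[curve$density == 1],
               alpha_from_null(null)$alpha, tolerance = 1e-12)
  expect_equal(curve$m_eff, 0.05 / curve$alpha_5pct)
})

test_that("independent probes give effective tests linear in density", {
  set.seed(41)
  p <- 2000; R <- 2000
  pv <- matrix(runif(p * R), p, R)     # independent uniform null P values
  curve <- subsample_curve(pv, densities = seq(0.2, 1, by = 0.2),
                           n_replicates = 5, seed = 3)
  expect_true(all(abs(curve$m_eff / (curve$density * p) - 1) < 0.25))
})

test_that("the 5% point decreases with density up to Monte-Carlo noise", {
  null <- make_null_pvals(p = 400, perms = 500)
  curve <- subsample_curve(null$p_values, densities = seq(0.1, 1, by = 0.1),
                           n_replicates = 10, seed = 7)
  # allow small inversions from subsampling noise
  expect_true(all(diff(curve$alpha_5pct) < 0.25 * curve$alpha_5pct[-1]))
  expect_lt(curve$alpha_5pct[10], curve$alpha_5pct[1])
})

test_that("degenerate densities and missing P matrices are rejected", {
  pv <- matrix(runif(100), 10, 10)
  expect_error(subsample_curve(pv, densities = c(0.05, 0.5), n_replicates = 2),
               "no probes")
  expect_error(subsample_curve(pv, densities = c(0.5, 0.4), n_replicates = 2),
               "increasing")
  expect_error(subsample_curve(NULL), "keep_p")
})

test_that("Monod fit recovers noiseless parameters and the half-saturation identity", {
  u <- 1.38e6; k <- 4.71
  d <- seq(0.01, 1, by = 0.01)
  curve <- data.frame(density = d, m_eff = u * d / (k + d))
  fit <- fit_monod(curve)
  expect_true(fit$converged)
  expect_equal(fit$u, u, tolerance = 1e-6)
  expect_equal(fit$k, k, tolerance = 1e-6)
  expect_equal(fit$alpha_genomewide, 0.05 / u)
  # f(k; u, k) = u / 2 by construction
  expect_equal(fit$u * fit$k / (fit$k + fit$k), fit$u / 2)
})

test_that("Monod asymptote is robust to 1% multiplicative noise", {
  u <- 1.38e6; k <- 4.71
  d <- seq(0.01, 1, by = 0.01)
  y0 <- u * d / (k + d)
  errs <- vapply(1:50, function(s) {
    set.seed(s)
    fit <- fit_monod(data.frame(density = d,
                                m_eff = y0 * (1 + rnorm(length(d), 0, 0.01))))
    abs(fit$u - u) / u
  }, numeric(1))
  # bound calibrated once by simulation: median relative error ~1.4%
  expect_lt(median(errs), 0.05)
})

test_that("a linear curve flags a poorly identified asymptote without crashing", {
  d <- seq(0.01, 1, by = 0.01)
  set.seed(9)
  curve <- data.frame(density = d, m_eff = 5000 * d * (1 + rnorm(100, 0, 0.002)))
  fit <- fit_monod(curve)
  expect_s3_class(fit, "monod_fit")
  if (fit$converged) expect_false(fit$identifiable)
})

test_that("extrapolated threshold is at least as stringent as the array threshold", {
  # tight clusters of near-duplicate probes: the curve saturates and the
  # asymptote is identifiable
  cfg <- sim_config(500, 40, seed = 5, max_correlation = 0.98,
                    background_correlation = 0.1, decay_scale = 2000,
                    position_model = list(cluster_fraction = 0.85,
                                          within_gap = c(2, 100),
                                          between_gap = c(2000, 20000)))
  m <- beta_to_m(generate_beta(generate_manifest(cfg), cfg))
  null <- permute_min_p(m, assign_labels(40, seed = 1), 500, seed = 5,
                        keep_p = TRUE)
  curve <- subsample_curve(null$p_values, densities = seq(0.05, 1, by = 0.05),
                           n_replicates = 10, seed = 4)
  fit <- fit_monod(curve)
  expect_true(fit$converged)
  expect_lte(fit$alpha_genomewide,
             curve$alpha_5pct[curve$density == 1] * 1.001)
})

test_that("consensus genome-wide threshold reproduces the published figures", {
  est <- consensus_genomewide(dataset_u, weights = dataset_n)
  expect_equal(signif(est$alpha, 2), 3.6e-8)
  expect_equal(est$source, "extrapolated")
  # single-dataset threshold: alpha = 0.05 / u
  expect_equal(consensus_genomewide(1.38e6)$alpha, 3.61e-8, tolerance = 0.01)
  # equal u: weights irrelevant
  expect_equal(consensus_genomewide(c(2e6, 2e6), weights = c(5, 1))$alpha,
               0.05 / 2e6)
  # failed fits are excluded; all-failed errors
  bad <- structure(list(u = NA, converged = FALSE), class = "monod_fit")
  good <- structure(list(u = 1e6, converged = TRUE), class = "monod_fit")
  expect_equal(consensus_genomewide(list(bad, good), weights = c(1, 1))$alpha,
               0.05 / 1e6)
  expect_error(consensus_genomewide(list(bad, bad), weights = c(1, 1)),
               "no successful")
})
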