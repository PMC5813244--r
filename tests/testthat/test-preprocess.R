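test_that("beta_to_m is the logit-2 transform and a strict bijection", {
  expect_equal(beta_to_m(0.5), 0)
  expect_equal(beta_to_m(0.8), 2)
  expect_equal(beta_to_m(0.2), -2)
  b <- seq(0.001, 0.999, length.out = 101)
  expect_equal(beta_to_m(b), -beta_to_m(1 - b))        # antisymmetry
  expect_true(all(diff(beta_to_m(b)) > 0))             # strictly increasing
  expect_equal(m_to_beta(beta_to_m(b)), b, tolerance = 1e-12)  # round trip
  expect_error(beta_to_m(c(0.2, 1)), "strictly")
  expect_error(beta_to_m(0), "strictly")
})

test_that("beta matrix and manifest survive a TSV round trip", {
  cfg <- sim_config(n_probes = 30, n_samples = 8, seed = 4)
  mf <- generate_manifest(cfg)
  beta <- generate_beta(mf, cfg)
  fb <- tempfile(fileext = ".tsv"); fm <- tempfile(fileext = ".tsv")
  write_beta_matrix(beta, fb)
  write_manifest(mf, fm)
  beta2 <- read_beta_matrix(fb)
  mf2 <- read_manifest(fm)
  expect_equal(beta2, beta, tolerance = 1e-12)
  expect_equal(mf2$probe_id, mf$probe_id)
  expect_equal(mf2$position, mf$position)
  unlink(c(fb, fm))
})

test_that("probes missing from the manifest are dropped on alignment", {
  cfg <- sim_config(n_probes = 20, n_samples = 8, seed = 4)
  mf <- generate_manifest(cfg)
  beta <- generate_beta(mf, cfg)
  extra <- rbind(beta, foreign = runif(8, 0.4, 0.6))
  expect_message(al <- align_to_manifest(extra, mf), "dropped")
  expect_equal(rownames(al$beta), mf$probe_id)
})

test_that("three equally spaced probes fall in a single bin of three pairs", {
  mf <- data.frame(probe_id = c("a", "b", "c"), chromosome = "chr1",
                   position = c(100L, 200L, 300L))
  class(mf) <- c("ewas_manifest", "data.frame")
  set.seed(1)
  beta <- matrix(runif(3 * 10, 0.2, 0.8), 3, 10,
                 dimnames = list(mf$probe_id, NULL))
  prof <- correlation_profile(beta, mf, "chr1", max_distance = 1000,
                              pairs_per_bin = 3)
  expect_equal(nrow(prof), 1L)
  expect_equal(prof$n_pairs, 3L)
  expect_equal(attr(prof, "n_pairs_total"), 3L)
})

test_that("sliding-window profile equals brute-force all-pairs enumeration", {
  for (seed in c(2, 17)) {
    cfg <- sim_config(n_probes = 150, n_samples = 20, seed = seed)
    mf <- generate_manifest(cfg)
    beta <- generate_beta(mf, cfg)
    prof <- correlation_profile(beta, mf, max_distance = 5000,
                                pairs_per_bin = 37)
    oracle <- brute_force_profile(beta, mf, mf$chromosome[1], 5000, 37)
    expect_equal(prof$median_distance, oracle$median_distance)
    expect_equal(prof$mean_correlation, oracle$mean_correlation,
                 tolerance = 1e-10)
    expect_equal(prof$n_pairs, oracle$n_pairs)
    expect_equal(sum(prof$n_pairs), attr(prof, "n_pairs_total"))
  }
})

test_that("independent data profiles to zero correlation in every bin", {
  cfg <- sim_config(n_probes = 400, n_samples = 100, seed = 6,
                    max_correlation = 0, background_correlation = 0)
  mf <- generate_manifest(cfg)
  beta <- generate_beta(mf, cfg)
  prof <- correlation_profile(beta, mf, pairs_per_bin = 200)
  # bin mean of n_pairs null correlations: sd ~ 1/sqrt(n_samples * n_pairs)
  bound <- 4 / sqrt(100 * prof$n_pairs)
  expect_true(all(abs(prof$mean_correlation) < pmax(bound, 0.05)))
})

test_that("profiler recovers the generator's decay curve (mutual oracles)", {
  cfg <- sim_config(n_probes = 1500, n_samples = 150, seed = 27,
                    max_correlation = 0.45, background_correlation = 0.05,
                    decay_scale = 1000)
  mf <- generate_manifest(cfg)
  beta <- generate_beta(mf, cfg)
  prof <- correlation_profile(beta, mf, pairs_per_bin = 400)
  rho <- function(d) 0.05 + 0.40 * exp(-d / 1000)
  expected <- rho(prof$median_distance)
  # copula attenuation is sub-1%; bin means carry sampling noise
  expect_lt(max(abs(prof$mean_correlation - expected)), 0.08)
  expect_lt(mean(abs(prof$mean_correlation - expected)), 0.03)
  # decay is visible: near bins clearly above far bins
  near <- prof$mean_correlation[prof$median_distance < 300]
  far <- prof$mean_correlation[prof$median_distance > 4000]
  expect_gt(min(near), max(far))
})

test_that("zero-variance pairs are skipped with a message", {
  mf <- data.frame(probe_id = c("a", "b", "c"), chromosome = "chr1",
                   position = c(100L, 150L, 220L))
  class(mf) <- c("ewas_manifest", "data.frame")
  set.seed(2)
  beta <- matrix(runif(3 * 12, 0.3, 0.7), 3, 12,
                 dimnames = list(mf$probe_id, NULL))
  beta["b", ] <- 0.5                                   # constant row
  expect_message(prof <- correlation_profile(beta, mf, pairs_per_bin = 10),
                 "zero variance")
  expect_equal(attr(prof, "n_pairs_total"), 1L)        # only (a, c) survives
})
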