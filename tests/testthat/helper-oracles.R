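# Shared oracles and reference values used across test files.

# Published EWAS sample-size table (t-test, 80% power): columns are the
# re-derived thresholds; rows are mean methylation differences 7..15.
published_sample_sizes <- list(
  deltas = 7:15,
  discordant_twin = list(
    "1e-06"   = c(178, 145, 117, 98, 81, 71, 63, 55, 50),
    "2.4e-07" = c(196, 159, 129, 108, 89, 78, 69, 61, 55),
    "3.6e-08" = c(219, 178, 144, 121, 100, 88, 78, 68, 62)
  ),
  case_control = list(
    "1e-06"   = c(211, 169, 137, 112, 96, 80, 70, 61, 54),
    "2.4e-07" = c(232, 186, 150, 123, 105, 88, 77, 67, 59),
    "3.6e-08" = c(259, 208, 168, 138, 118, 98, 86, 75, 66)
  )
)

# Per-dataset permutation/extrapolation summaries (effective tests m,
# Monod asymptotes u) and dataset sizes used for consensus weighting.
dataset_m <- c(gambian = 245563, caucasian = 204586,
               afr_am_gtp = 204046, cau_am = 139451)
dataset_u <- c(gambian = 1.38e6, caucasian = 1.18e6,
               afr_am_gtp = 1.75e6, cau_am = 6.38e5)
dataset_n <- c(gambian = 120, caucasian = 426, afr_am_gtp = 422, cau_am = 65)

# Brute-force within-cutoff pair profile: enumerate all pairs, filter by
# distance, bin by count after a stable sort on distance.
brute_force_profile <- function(beta, manifest, chromosome, max_distance,
                                pairs_per_bin) {
  mf <- manifest[manifest$chromosome == chromosome, ]
  mf <- mf[order(mf$position), ]
  x <- beta[mf$probe_id, , drop = FALSE]
  pairs <- t(combn(nrow(mf), 2))
  d <- abs(mf$position[pairs[, 1]] - mf$position[pairs[, 2]])
  keep <- d <= max_distance
  pairs <- pairs[keep, , drop = FALSE]
  d <- d[keep]
  r <- vapply(seq_len(nrow(pairs)),
              function(k) cor(x[pairs[k, 1], ], x[pairs[k, 2], ]),
              numeric(1))
  ord <- order(d)
  d <- d[ord]; r <- r[ord]
  bin <- (seq_along(d) - 1L) %/% pairs_per_bin + 1L
  data.frame(
    median_distance = as.numeric(tapply(d, bin, median)),
    mean_correlation = as.numeric(tapply(r, bin, mean)),
    n_pairs = as.integer(tapply(r, bin, length))
  )
}

# Naive two-loop permutation min-P reference sharing the package's
# permutation stream (drawn identically from the master seed).
reference_min_p <- function(m_values, labels, n_permutations, seed) {
  n <- ncol(m_values)
  n1 <- sum(labels == 1L)
  perms <- withr::with_seed(as.integer(seed), {
    out <- matrix(0L, n, n_permutations)
    for (r in seq_len(n_permutations)) out[sample.int(n, n1), r] <- 1L
    out
  })
  vapply(seq_len(n_permutations), function(r) {
    g <- perms[, r] == 1L
    min(vapply(seq_len(nrow(m_values)), function(i) {
      t.test(m_values[i, g], m_values[i, !g], var.equal = TRUE)$p.value
    }, numeric(1)))
  }, numeric(1))
}
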