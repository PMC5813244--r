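#' Assign case/control labels for permutation testing
#'
#' Randomly designates `floor(n_samples / 2)` samples as cases and the rest
#' as controls. Under the permutation scheme the initial assignment is
#' arbitrary (labels are re-permuted every replicate); it fixes the group
#' sizes.
#'
#' @param n_samples number of samples, at least 4 (two per group).
#' @param seed integer seed.
#' @return integer vector of 0 (control) / 1 (case), length `n_samples`.
#' @examples
#' table(assign_labels(120, seed = 1))  # 60 cases, 60 controls
#' @export
assign_labels <- function(n_samples, seed = 1L) {
  if (!is.numeric(n_samples) || length(n_samples) != 1L || n_samples < 4) {
    stop("`n_samples` must be >= 4 (at least two cases and two controls)",
         call. = FALSE)
  }
  n <- as.integer(n_samples)
  labels <- integer(n)
  with_seed(seed, {
    labels[sample.int(n, n %/% 2L)] <- 1L
  })
  labels
}

#' Permutation minimum-P null distribution (maxT scheme)
#'
#' For each of `n_permutations` random re-assignments of the case/control
#' labels, performs an equal-variance two-sample t-test at every CpG
#' (`df = n - 2`), takes the maximum `|t|` across CpGs and converts it to a
#' two-sided P value — the per-permutation minimum P. The 5th percentile of
#' these minimum P values is the family-wise 5% significance threshold for
#' the probe set (see [alpha_from_null()]).
#'
#' Permutations are drawn up front from the master `seed` (uniformly, with
#' replacement, from the label-permutation space), so results do not depend
#' on `chunk_size` (up to floating-point summation order in the underlying
#' matrix products); probes are processed in chunks of `chunk_size`
#' rows so peak memory is `O(chunk_size * n_permutations)`.
#'
#' A CpG with zero pooled variance under some permutation is skipped for
#' that permutation (its P value is undefined); if every CpG is degenerate
#' in some permutation an error is raised.
#'
#' @param m_values probes x samples matrix of M values.
#' @param labels 0/1 vector from [assign_labels()] (both groups >= 2).
#' @param n_permutations number of label permutations (default 10000).
#' @param seed master integer seed for the permutation stream.
#' @param chunk_size probes per processing block (default 2000).
#' @param keep_p if `TRUE`, also return the full probes x permutations
#'   matrix of per-CpG two-sided P values (needed for density subsampling,
#'   see [subsample_curve()]).
#' @return object of class `permutation_null`: a list with `min_p`
#'   (length `n_permutations`), `n_probes`, `n_samples`, `n_cases`,
#'   `n_permutations`, `seed`, `mean` and `var` of `min_p`, `n_skipped`,
#'   and `p_values` (or `NULL`).
#' @examples
#' cfg <- sim_config(n_probes = 50, n_samples = 16, seed = 2)
#' m <- beta_to_m(generate_beta(generate_manifest(cfg), cfg))
#' null <- permute_min_p(m, assign_labels(16, 1), n_permutations = 200, seed = 9)
#' alpha_from_null(null)
#' @export
permute_min_p <- function(m_values, labels, n_permutations = 10000L,
                          seed = 1L, chunk_size = 2000L, keep_p = FALSE) {
  if (!is.matrix(m_values) || !is.numeric(m_values)) {
    stop("`m_values` must be a numeric matrix (probes x samples)",
         call. = FALSE)
  }
  n <- ncol(m_values)
  p <- nrow(m_values)
  if (length(labels) != n) {
    stop("`labels` length must equal ncol(m_values)", call. = FALSE)
  }
  n1 <- sum(labels == 1L)
  n2 <- n - n1
  if (n1 < 2L || n2 < 2L) {
    stop("both groups need at least 2 samples", call. = FALSE)
  }
  if (n_permutations < 1L) stop("`n_permutations` must be >= 1", call. = FALSE)
  R <- as.integer(n_permutations)
  df <- n - 2L

  # permutation stream drawn once from the master seed: results do not
  # depend on chunking
  C <- with_seed(seed, {
    out <- matrix(0, n, R)
    for (r in seq_len(R)) out[sample.int(n, n1), r] <- 1
    out
  })

  tot <- rowSums(m_values)
  tot2 <- rowSums(m_values^2)
  se_fac <- sqrt(1 / n1 + 1 / n2)

  max_t <- rep(-Inf, R)
  n_skipped <- 0L
  p_full <- if (keep_p) matrix(NA_real_, p, R) else NULL
  for (s in seq(1L, p, by = as.integer(chunk_size))) {
    e <- min(s + as.integer(chunk_size) - 1L, p)
    X <- m_values[s:e, , drop = FALSE]
    S1 <- X %*% C
    Q1 <- (X^2) %*% C
    T1 <- tot[s:e]
    T2 <- tot2[s:e]
    mean_diff <- S1 / n1 - (T1 - S1) / n2
    ss1 <- Q1 - S1^2 / n1
    ss2 <- (T2 - Q1) - (T1 - S1)^2 / n2
    sp2 <- (ss1 + ss2) / df
    bad <- sp2 <= 0
    n_skipped <- n_skipped + sum(bad)
    sp2[bad] <- NA_real_
    tt <- abs(mean_diff) / (sqrt(sp2) * se_fac)
    if (keep_p) {
      p_full[s:e, ] <- 2 * stats::pt(-tt, df = df)
    }
    chunk_max <- suppressWarnings(apply(tt, 2L, max, na.rm = TRUE))
    max_t <- pmax(max_t, chunk_max)
  }
  if (any(!is.finite(max_t))) {
    stop("some permutation had no CpG with positive pooled variance",
         call. = FALSE)
  }
  if (n_skipped > 0L) {
    message(n_skipped, " (CpG, permutation) cell(s) skipped for zero variance")
  }
  min_p <- 2 * stats::pt(-max_t, df = df)

  structure(
    list(min_p = min_p, n_probes = p, n_samples = n, n_cases = n1,
         n_permutations = R, seed = as.integer(seed),
         mean = mean(min_p), var = stats::var(min_p),
         n_skipped = n_skipped, p_values = p_full),
    class = "permutation_null"
  )
}

#' @export
print.permutation_null <- function(x, ...) {
  cat("Permutation min-P null:", x$n_permutations, "permutations,",
      x$n_probes, "probes,", x$n_samples, "samples (", x$n_cases, "cases)\n")
  cat(sprintf("  min-P mean %.3g, var %.3g; 5%% point %.3g\n",
              x$mean, x$var, stats::quantile(x$min_p, 0.05, names = FALSE)))
  invisible(x)
}

#' Significance threshold from a permutation null
#'
#' Takes the empirical `percentile` (default 5th) of the per-permutation
#' minimum P values as the family-wise significance threshold alpha for the
#' probe set tested. Quantiles use linear interpolation between order
#' statistics (type 7, the R default).
#'
#' @param null a `permutation_null` from [permute_min_p()], or a numeric
#'   vector of minimum P values.
#' @param percentile probability in `(0, 1)`; default 0.05.
#' @return object of class `threshold_estimate`: list with `alpha`,
#'   `percentile` and `source = "array_permutation"`.
#' @export
alpha_from_null <- function(null, percentile = 0.05) {
  stop_if_not_scalar_prob(percentile, "percentile")
  min_p <- if (inherits(null, "permutation_null")) null$min_p else null
  if (length(min_p) < 100L) {
    stop("need at least 100 permutations to estimate a percentile",
         call. = FALSE)
  }
  structure(
    list(alpha = stats::quantile(min_p, percentile, names = FALSE, type = 7),
         percentile = percentile, source = "array_permutation"),
    class = "threshold_estimate"
  )
}

#' @export
print.threshold_estimate <- function(x, ...) {
  cat(sprintf("alpha = %.3g (source: %s)\n", x$alpha, x$source))
  invisible(x)
}
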