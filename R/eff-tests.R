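#' Effective number of independent tests by Bonferroni inversion
#'
#' The effective number of tests implied by a family-wise 5% threshold
#' `alpha` under the Bonferroni law: `m = 0.05 / alpha` (real-valued).
#'
#' @param alpha family-wise significance threshold in `(0, 1)`.
#' @return the effective test count `0.05 / alpha`.
#' @examples
#' bonferroni_m(0.05 / 467624)   # the array probe count back
#' @export
bonferroni_m <- function(alpha) {
  if (!is.numeric(alpha) || any(alpha <= 0 | alpha >= 1)) {
    stop("`alpha` must lie strictly in (0, 1)", call. = FALSE)
  }
  0.05 / alpha
}

#' Fit a beta(1, b) model to the minimum-P distribution
#'
#' If all tests were independent, the minimum of `m'` uniform P values would
#' follow a beta(1, m') distribution (the Sidak law), so the fitted second
#' shape parameter is itself an effective number of independent tests.
#' With the first shape fixed at 1, the method-of-moments start is
#' `b_mom = (1 - xbar) / xbar` (`xbar` = mean minimum P); the reported `b`
#' maximises the beta(1, b) log-likelihood numerically from that start
#' (bounded search on `log b`, relative tolerance 1e-10). The closed-form
#' MLE `-R / sum(log(1 - p))` is returned as `b_closed` for cross-checking.
#'
#' @param null a `permutation_null` or a numeric vector of minimum P values,
#'   all strictly inside `(0, 1)`, length at least 100.
#' @return object of class `beta_fit`: list with `a` (fixed 1), `b`,
#'   `b_mom`, `b_closed`, `loglik`, `alpha` (empirical 5% point) and
#'   `m_bonferroni = 0.05 / alpha`.
#' @examples
#' set.seed(1)
#' fit_beta_min_p(rbeta(5000, 1, 300))
#' @export
fit_beta_min_p <- function(null) {
  min_p <- if (inherits(null, "permutation_null")) null$min_p else null
  if (length(min_p) < 100L) {
    stop("need at least 100 minimum P values", call. = FALSE)
  }
  if (any(min_p <= 0 | min_p >= 1)) {
    stop("minimum P values must lie strictly in (0, 1)", call. = FALSE)
  }
  R <- length(min_p)
  xbar <- mean(min_p)
  b_mom <- (1 - xbar) / xbar
  slog <- sum(log1p(-min_p))
  loglik <- function(b) R * log(b) + (b - 1) * slog
  # bounded scalar maximisation on log b around the moment start
  opt <- stats::optimize(function(lb) loglik(exp(lb)),
                         interval = log(b_mom) + c(-8, 8),
                         maximum = TRUE, tol = 1e-10)
  b <- exp(opt$maximum)
  alpha <- stats::quantile(min_p, 0.05, names = FALSE, type = 7)
  structure(
    list(a = 1, b = b, b_mom = b_mom, b_closed = -R / slog,
         loglik = opt$objective, alpha = alpha,
         m_bonferroni = 0.05 / alpha, n_permutations = R),
    class = "beta_fit"
  )
}

#' @export
print.beta_fit <- function(x, ...) {
  cat(sprintf(
    "beta(1, b) fit to %d minimum P values:\n  b = %.4g (moment start %.4g, closed form %.4g)\n  5%% point alpha = %.3g -> m = %.4g effective tests\n",
    x$n_permutations, x$b, x$b_mom, x$b_closed, x$alpha, x$m_bonferroni))
  invisible(x)
}

#' Expected quantiles for a minimum-P QQ plot under independence
#'
#' Pairs the sorted observed minimum P values with the quantiles of the
#' beta(1, `m_ref`) distribution — the exact law of the minimum of `m_ref`
#' independent uniform P values — at plotting positions
#' `u_i = (i - 0.5) / R`: `q_i = 1 - (1 - u_i)^(1 / m_ref)`.
#' Deviation from the diagonal diagnoses how far the probe set is from
#' `m_ref` independent tests.
#'
#' @param null a `permutation_null` or numeric vector of minimum P values.
#' @param m_ref reference test count (>= 1); conventionally the number of
#'   probes actually tested.
#' @return object of class `qq_data`: list with sorted `observed`,
#'   `expected` and `m_ref`.
#' @export
qq_expected <- function(null, m_ref = NULL) {
  min_p <- if (inherits(null, "permutation_null")) null$min_p else null
  if (is.null(m_ref) && inherits(null, "permutation_null")) {
    m_ref <- null$n_probes
  }
  if (is.null(m_ref) || m_ref < 1) stop("`m_ref` must be >= 1", call. = FALSE)
  R <- length(min_p)
  u <- (seq_len(R) - 0.5) / R
  structure(
    list(observed = sort(min_p),
         expected = -expm1(log1p(-u) / m_ref),
         m_ref = m_ref),
    class = "qq_data"
  )
}

#' Consensus threshold from several effective-test estimates
#'
#' Combines per-dataset effective-test counts into one threshold:
#' `alpha = 0.05 / weighted.mean(m, weights)`, with the dataset sample
#' sizes as weights. Scale of the weights is irrelevant.
#'
#' @param m numeric vector of effective test counts (one per dataset).
#' @param weights positive weights, conventionally the dataset sample sizes.
#' @param source label recorded on the estimate, default
#'   `"weighted_consensus"`.
#' @return a `threshold_estimate` with the consensus `alpha`.
#' @examples
#' consensus_alpha(c(245563, 204586, 204046, 139451),
#'                 weights = c(120, 426, 422, 65))
#' @export
consensus_alpha <- function(m, weights = rep(1, length(m)),
                            source = "weighted_consensus") {
  if (length(m) < 1L) stop("need at least one estimate", call. = FALSE)
  if (length(weights) != length(m) || any(weights <= 0)) {
    stop("`weights` must be positive and match `m` in length", call. = FALSE)
  }
  if (any(m <= 0)) stop("effective test counts must be positive", call. = FALSE)
  structure(
    list(alpha = 0.05 / stats::weighted.mean(m, weights),
         percentile = 0.05, source = source),
    class = "threshold_estimate"
  )
}
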