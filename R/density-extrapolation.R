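#' Subsample the permutation null over a grid of CpG densities
#'
#' Emulates arrays of lower CpG density by subsampling probes. For each
#' replicate and each density `d`, `ceiling(d * n_probes)` probe rows are
#' drawn without replacement (independently per replicate and density), the
#' minimum P value over that subset is taken within every permutation, and
#' the 5th percentile across permutations recorded. The reported
#' `alpha_5pct(d)` is the mean of that 5% point over replicates, and
#' `m_eff(d) = 0.05 / alpha_5pct(d)` is the effective number of tests at
#' density `d`. The resulting curve saturates as correlated neighbours stop
#' adding independent information, which is what [fit_monod()] exploits to
#' extrapolate beyond the array.
#'
#' @param p_values probes x permutations matrix of per-CpG two-sided P
#'   values (from [permute_min_p()] with `keep_p = TRUE`, or its
#'   `p_values` element). `NA` cells (skipped tests) are ignored.
#' @param densities grid of subsampling fractions in `(0, 1]`; default
#'   `seq(0.01, 1, by = 0.01)` (the degenerate density 0 is excluded).
#' @param n_replicates subsampling replicates per density (default 100).
#' @param seed integer seed for the subset draws.
#' @param percentile percentile recorded per density (default 0.05).
#' @return a `data.frame` of class `density_curve` with columns `density`,
#'   `alpha_5pct`, `m_eff`; attributes `n_replicates`, `n_permutations`,
#'   `n_probes`.
#' @examples
#' cfg <- sim_config(n_probes = 200, n_samples = 20, seed = 5)
#' m <- beta_to_m(generate_beta(generate_manifest(cfg), cfg))
#' null <- permute_min_p(m, assign_labels(20, 1), n_permutations = 200,
#'                       seed = 3, keep_p = TRUE)
#' curve <- subsample_curve(null$p_values, densities = seq(0.2, 1, by = 0.2),
#'                          n_replicates = 5, seed = 11)
#' @export
subsample_curve <- function(p_values, densities = seq(0.01, 1, by = 0.01),
                            n_replicates = 100L, seed = 1L,
                            percentile = 0.05) {
  if (inherits(p_values, "permutation_null")) p_values <- p_values$p_values
  if (is.null(p_values) || !is.matrix(p_values)) {
    stop("`p_values` must be a probes x permutations matrix ",
         "(run permute_min_p with keep_p = TRUE)", call. = FALSE)
  }
  p <- nrow(p_values)
  if (any(densities <= 0 | densities > 1)) {
    stop("`densities` must lie in (0, 1]", call. = FALSE)
  }
  if (is.unsorted(densities, strictly = TRUE)) {
    stop("`densities` must be strictly increasing", call. = FALSE)
  }
  if (any(densities * p < 1)) {
    stop("smallest density selects no probes (d * n_probes < 1)",
         call. = FALSE)
  }
  stop_if_not_scalar_prob(percentile, "percentile")
  # NA cells (skipped tests) can never be a minimum
  if (anyNA(p_values)) p_values[is.na(p_values)] <- 1

  nd <- length(densities)
  acc <- matrix(NA_real_, n_replicates, nd)
  with_seed(seed, {
    for (r in seq_len(n_replicates)) {
      for (d in seq_len(nd)) {
        k <- ceiling(densities[d] * p)
        idx <- if (k >= p) seq_len(p) else sample.int(p, k)
        mp <- col_mins(p_values[idx, , drop = FALSE])
        acc[r, d] <- stats::quantile(mp, percentile, names = FALSE, type = 7)
      }
    }
  })
  alpha_5pct <- colMeans(acc)
  out <- data.frame(density = densities, alpha_5pct = alpha_5pct,
                    m_eff = 0.05 / alpha_5pct)
  attr(out, "n_replicates") <- as.integer(n_replicates)
  attr(out, "n_permutations") <- ncol(p_values)
  attr(out, "n_probes") <- p
  class(out) <- c("density_curve", "data.frame")
  out
}

#' Fit a Monod (saturating-growth) curve to effective tests versus density
#'
#' Least-squares fit of `m_eff(d) = u * d / (k + d)` over the density grid.
#' `u` is the asymptotic effective number of tests as CpG density saturates
#' the genome, `k` the half-saturation density (`f(k) = u / 2`), and the
#' genome-wide significance threshold is `alpha = 0.05 / u`. Fitting uses
#' Levenberg-Marquardt from `u0 = 2 * m_eff` at the highest density and
#' `k0 = 1`, with a multi-start fallback. Non-convergence or non-positive
#' estimates yield a result with `converged = FALSE` rather than an error
#' (near-independent data give an almost linear curve whose asymptote is
#' not identifiable; such fits are flagged).
#'
#' @param curve a `density_curve` from [subsample_curve()], or a data frame
#'   with columns `density` and `m_eff` (at least 5 usable points).
#' @return object of class `monod_fit`: list with `u`, `k`, `residual_ss`,
#'   `alpha_genomewide`, `converged`, and `identifiable` (`FALSE` when the
#'   fitted `k` lies far outside the observed density range, i.e. the
#'   asymptote is an extrapolation well beyond the data).
#' @examples
#' d <- seq(0.01, 1, by = 0.01)
#' fit_monod(data.frame(density = d, m_eff = 1.4e6 * d / (4.7 + d)))
#' @export
fit_monod <- function(curve) {
  if (!all(c("density", "m_eff") %in% names(curve))) {
    stop("`curve` needs columns `density` and `m_eff`", call. = FALSE)
  }
  ok <- is.finite(curve$m_eff) & curve$m_eff > 0
  d <- curve$density[ok]
  y <- curve$m_eff[ok]
  if (length(d) < 5L) {
    stop("need at least 5 usable density points", call. = FALSE)
  }
  y_top <- y[which.max(d)]
  starts <- expand.grid(u = c(2, 1, 5, 20, 0.5) * y_top,
                        k = c(1, 0.1, 10))
  fit <- NULL
  for (i in seq_len(nrow(starts))) {
    f <- tryCatch(
      minpack.lm::nlsLM(y ~ u * d / (k + d),
                        start = list(u = starts$u[i], k = starts$k[i]),
                        control = minpack.lm::nls.lm.control(maxiter = 500)),
      error = function(e) NULL)
    if (!is.null(f)) {
      cf <- stats::coef(f)
      if (all(is.finite(cf)) && cf[["u"]] > 0 && cf[["k"]] > 0) {
        fit <- f
        break
      }
    }
  }
  if (is.null(fit)) {
    return(structure(
      list(u = NA_real_, k = NA_real_, residual_ss = NA_real_,
           alpha_genomewide = NA_real_, converged = FALSE,
           identifiable = FALSE),
      class = "monod_fit"))
  }
  cf <- stats::coef(fit)
  u <- cf[["u"]]; k <- cf[["k"]]
  structure(
    list(u = u, k = k, residual_ss = sum(stats::resid(fit)^2),
         alpha_genomewide = 0.05 / u, converged = TRUE,
         identifiable = k <= 10 * max(d)),
    class = "monod_fit"
  )
}

#' @export
print.monod_fit <- function(x, ...) {
  if (!x$converged) {
    cat("Monod fit: did not converge\n")
  } else {
    cat(sprintf(
      "Monod fit: u = %.4g, k = %.4g (RSS %.3g)%s\n  genome-wide alpha = 0.05/u = %.3g\n",
      x$u, x$k, x$residual_ss,
      if (x$identifiable) "" else " [asymptote poorly identified]",
      x$alpha_genomewide))
  }
  invisible(x)
}

#' Consensus genome-wide threshold from several Monod fits
#'
#' `alpha = 0.05 / weighted.mean(u, weights)` over the successful fits,
#' weighted by dataset sample size.
#'
#' @param fits list of `monod_fit` objects, or a numeric vector of `u`
#'   estimates.
#' @param weights positive weights (dataset sample sizes).
#' @return a `threshold_estimate` with `source = "extrapolated"`.
#' @examples
#' consensus_genomewide(c(1.38e6, 1.18e6, 1.75e6, 6.38e5),
#'                      weights = c(120, 426, 422, 65))
#' @export
consensus_genomewide <- function(fits, weights = NULL) {
  if (is.list(fits) && all(vapply(fits, inherits, TRUE, "monod_fit"))) {
    ok <- vapply(fits, function(f) isTRUE(f$converged), TRUE)
    u <- vapply(fits[ok], `[[`, numeric(1), "u")
    if (!is.null(weights)) weights <- weights[ok]
  } else {
    u <- as.numeric(fits)
  }
  if (length(u) < 1L) stop("no successful Monod fits to combine", call. = FALSE)
  if (is.null(weights)) weights <- rep(1, length(u))
  est <- consensus_alpha(u, weights, source = "extrapolated")
  est
}
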