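#' Power of a two-sided t-test from the non-central t distribution
#'
#' Evaluates `1 - beta = 1 - F(t_crit) + F(-t_crit)` where `F` is the
#' non-central t CDF and `t_crit` the central-t two-sided critical value at
#' level `alpha`. The degrees of freedom and non-centrality parameter
#' depend on the design:
#'
#' * `"discordant_twin"` — paired analysis of `n` twin pairs:
#'   `df = n - 1`, `ncp = sqrt(n) * delta / sigma`;
#' * `"case_control"` — two independent groups of `n` each:
#'   `df = 2n - 2`, `ncp = sqrt(n / 2) * delta / sigma`.
#'
#' `delta` is the mean methylation difference and `sigma` the noise scale in
#' the same units (conventionally percentage points of methylation).
#'
#' @param n sample size (twin pairs, or per-group count).
#' @param delta mean methylation difference (> 0).
#' @param sigma noise standard deviation (> 0), same units as `delta`.
#' @param alpha two-sided significance level in `(0, 1)`.
#' @param design `"discordant_twin"` or `"case_control"`.
#' @return the power, a probability.
#' @examples
#' power_noncentral_t(112, delta = 10, sigma = 12.7, alpha = 1e-6,
#'                    design = "case_control")
#' @export
power_noncentral_t <- function(n, delta, sigma, alpha,
                               design = c("discordant_twin",
                                          "case_control")) {
  design <- match.arg(design)
  if (delta <= 0) stop("`delta` must be positive", call. = FALSE)
  if (sigma <= 0) stop("`sigma` must be positive", call. = FALSE)
  stop_if_not_scalar_prob(alpha, "alpha")
  if (design == "discordant_twin") {
    df <- n - 1
    ncp <- sqrt(n) * delta / sigma
  } else {
    df <- 2 * n - 2
    ncp <- sqrt(n / 2) * delta / sigma
  }
  if (any(df < 1)) stop("degrees of freedom below 1", call. = FALSE)
  tc <- stats::qt(1 - alpha / 2, df)
  1 - stats::pt(tc, df, ncp) + stats::pt(-tc, df, ncp)
}

#' Infer the noise scale from a published power anchor
#'
#' Solves `power_noncentral_t(n, delta, sigma, alpha) = power` for `sigma`
#' by bracketed root finding (power is strictly decreasing in `sigma`, so
#' the root is unique). This recovers the non-central t distribution
#' underlying a published sample-size figure so it can be re-solved at a
#' different significance threshold.
#'
#' @inheritParams power_noncentral_t
#' @param power target power in `(0, 1)`, default 0.8.
#' @return the inferred `sigma`.
#' @examples
#' solve_sigma(112, delta = 10, alpha = 1e-6, design = "case_control")
#' @export
solve_sigma <- function(n, delta, alpha, power = 0.8,
                        design = c("discordant_twin", "case_control")) {
  design <- match.arg(design)
  stop_if_not_scalar_prob(power, "power")
  f <- function(s) power_noncentral_t(n, delta, s, alpha, design) - power
  lo <- 1e-6; hi <- 1e6
  if (f(lo) < 0 || f(hi) > 0) {
    stop("target power not bracketed: no feasible sigma", call. = FALSE)
  }
  stats::uniroot(f, c(lo, hi), tol = 1e-12)$root
}

#' Sample size achieving a target power at a significance threshold
#'
#' Solves the continuous power equation for `n` (power is strictly
#' increasing in `n`), then converts to an integer. `rounding = "nearest"`
#' (the default) reports the nearest integer, matching the convention of
#' published EWAS sample-size tables; `rounding = "up"` gives the smallest
#' integer whose power meets the target.
#'
#' @inheritParams solve_sigma
#' @param sigma noise scale, typically from [solve_sigma()].
#' @param rounding `"nearest"` or `"up"`.
#' @return integer sample size; attribute `n_continuous` holds the
#'   unrounded solution.
#' @examples
#' s <- solve_sigma(112, delta = 10, alpha = 1e-6, design = "case_control")
#' solve_n(delta = 10, sigma = s, alpha = 2.4e-7, design = "case_control")
#' @export
solve_n <- function(delta, sigma, alpha, power = 0.8,
                    design = c("discordant_twin", "case_control"),
                    rounding = c("nearest", "up")) {
  design <- match.arg(design)
  rounding <- match.arg(rounding)
  stop_if_not_scalar_prob(power, "power")
  f <- function(n) power_noncentral_t(n, delta, sigma, alpha, design) - power
  lo <- 2 + 1e-9; hi <- 1e7
  if (f(hi) < 0) stop("target power infeasible below n = 1e7", call. = FALSE)
  n_cont <- if (f(lo) >= 0) lo else stats::uniroot(f, c(lo, hi), tol = 1e-9)$root
  n_int <- if (rounding == "nearest") {
    max(2L, as.integer(round(n_cont)))
  } else {
    n <- as.integer(ceiling(n_cont))
    # guard against the root landing a hair above an integer
    while (n > 2L && f(n - 1L) >= -1e-12) n <- n - 1L
    n
  }
  structure(n_int, n_continuous = n_cont)
}

#' Published EWAS power-study sample-size anchors
#'
#' Sample sizes from published power simulations for EWAS (t-test, 80%
#' power) for the discordant-twin and case-control designs, at significance
#' thresholds P < 0.05 and P < 1e-6, across mean methylation differences of
#' 7-15 percentage points. These anchor the noise-scale inference in
#' [rebuild_sample_size_table()].
#'
#' @return data frame with columns `design`, `delta`, `alpha`, `n`.
#' @export
published_power_anchors <- function() {
  path <- system.file("extdata", "published_power_anchors.tsv",
                      package = "ewasthresh", mustWork = TRUE)
  out <- data.table::fread(path, data.table = FALSE)
  out$design <- as.character(out$design)
  out
}

#' Re-solve published EWAS sample sizes at new significance thresholds
#'
#' For each design and methylation difference, infers `sigma` from the
#' published anchor at `anchor_alpha` (default 1e-6, the genome-wide level
#' used in the published simulations) and re-solves the non-central-t power
#' equation for the sample size at each of `new_alphas`. Solver failures in
#' a cell yield `NA` with a warning; remaining cells are still computed.
#'
#' @param published anchor table as from [published_power_anchors()]:
#'   columns `design`, `delta`, `alpha`, `n`.
#' @param new_alphas significance thresholds to re-solve at.
#' @param power target power (default 0.8).
#' @param anchor_alpha which published threshold anchors `sigma`.
#' @param rounding integer convention passed to [solve_n()].
#' @return data frame with one row per (design, delta): the anchor `n`, the
#'   inferred `sigma` and one `n_<alpha>` column per new threshold.
#' @examples
#' rebuild_sample_size_table(new_alphas = c(2.4e-7, 3.6e-8))
#' @export
rebuild_sample_size_table <- function(published = published_power_anchors(),
                                      new_alphas = c(2.4e-7, 3.6e-8),
                                      power = 0.8, anchor_alpha = 1e-6,
                                      rounding = "nearest") {
  anchors <- published[published$alpha == anchor_alpha, , drop = FALSE]
  if (nrow(anchors) == 0L) {
    stop("no published rows at `anchor_alpha`", call. = FALSE)
  }
  res <- anchors[, c("design", "delta", "n")]
  names(res)[3L] <- "n_anchor"
  res$sigma <- NA_real_
  for (a in new_alphas) res[[sprintf("n_%.2g", a)]] <- NA_integer_
  for (i in seq_len(nrow(res))) {
    des <- res$design[i]
    sig <- tryCatch(
      solve_sigma(res$n_anchor[i], res$delta[i], anchor_alpha, power, des),
      error = function(e) {
        warning("sigma inference failed for ", des, " delta=", res$delta[i],
                ": ", conditionMessage(e), call. = FALSE)
        NA_real_
      })
    res$sigma[i] <- sig
    if (is.na(sig)) next
    for (a in new_alphas) {
      res[[sprintf("n_%.2g", a)]][i] <- tryCatch(
        as.integer(solve_n(res$delta[i], sig, a, power, des,
                           rounding = rounding)),
        error = function(e) {
          warning("sample-size solve failed for ", des, " delta=",
                  res$delta[i], " alpha=", a, ": ", conditionMessage(e),
                  call. = FALSE)
          NA_integer_
        })
    }
  }
  res
}
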