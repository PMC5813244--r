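#' Configuration for the synthetic 450k-like methylation generator
#'
#' Bundles the parameters of the synthetic manifest/Beta-matrix generator.
#' The generator emulates the empirical features of processed Infinium 450k
#' data that the threshold-estimation pipeline relies on: irregular,
#' cluster-like CpG spacing, and co-methylation whose Pearson correlation
#' decays from `max_correlation` for adjacent sites to a flat
#' `background_correlation` beyond a couple of kilobases.
#'
#' The implied correlation between two probes at distance `d` bp is
#' `rho(d) = background + (max - background) * exp(-d / decay_scale)`
#' on the latent Gaussian scale; the Beta-scale Pearson correlation is a
#' near-identity monotone attenuation of this (attenuation below 1% at the
#' default concentration, measured by simulation).
#'
#' @param n_probes number of CpG probes to simulate.
#' @param n_samples number of samples (arrays).
#' @param seed integer seed; generation is fully deterministic given the seed.
#' @param decay_scale e-folding distance of the correlation kernel, in bp.
#' @param max_correlation latent correlation at distance 0, in `[0, 1)`.
#' @param background_correlation distance-independent floor correlation,
#'   `0 <= background_correlation <= max_correlation`.
#' @param position_model list with `cluster_fraction` (probability that the
#'   gap to the next probe is a short within-cluster gap), `within_gap`
#'   (length-2 range of within-cluster gaps, bp) and `between_gap` (range of
#'   between-cluster gaps, bp).
#' @param chromosome chromosome label written into the manifest.
#' @param concentration Beta-distribution concentration `a + b` controlling
#'   inter-individual spread at a probe (larger = tighter).
#' @param effect optional list describing a case/control mean shift:
#'   `probes` (integer indices), `delta` (shift of mean Beta, as a fraction),
#'   and optionally `cases` (column indices of case samples; defaults to the
#'   first `floor(n_samples / 2)` columns).
#' @param eps clipping bound: generated Beta values are forced into
#'   `[eps, 1 - eps]` so the M-value transform stays finite.
#'
#' @return an object of class `sim_config` (a validated list).
#' @examples
#' cfg <- sim_config(n_probes = 100, n_samples = 20, seed = 1)
#' @export
sim_config <- function(n_probes,
                       n_samples,
                       seed = 1L,
                       decay_scale = 1000,
                       max_correlation = 0.4,
                       background_correlation = 0.05,
                       position_model = list(cluster_fraction = 0.7,
                                             within_gap = c(2, 200),
                                             between_gap = c(2000, 20000)),
                       chromosome = "chr1",
                       concentration = 50,
                       effect = NULL,
                       eps = 1e-6) {
  if (!is.numeric(n_probes) || length(n_probes) != 1L || n_probes < 1 ||
      n_probes != round(n_probes)) {
    stop("`n_probes` must be a positive integer", call. = FALSE)
  }
  if (!is.numeric(n_samples) || length(n_samples) != 1L || n_samples < 1 ||
      n_samples != round(n_samples)) {
    stop("`n_samples` must be a positive integer", call. = FALSE)
  }
  if (!is.numeric(decay_scale) || decay_scale <= 0) {
    stop("`decay_scale` must be positive", call. = FALSE)
  }
  if (max_correlation < 0 || max_correlation >= 1) {
    stop("`max_correlation` must lie in [0, 1)", call. = FALSE)
  }
  if (background_correlation < 0 || background_correlation > max_correlation) {
    stop("need 0 <= background_correlation <= max_correlation < 1",
         call. = FALSE)
  }
  pm <- position_model
  if (!is.list(pm) || is.null(pm$cluster_fraction) ||
      is.null(pm$within_gap) || is.null(pm$between_gap)) {
    stop("`position_model` needs cluster_fraction, within_gap, between_gap",
         call. = FALSE)
  }
  if (pm$cluster_fraction < 0 || pm$cluster_fraction > 1) {
    stop("`cluster_fraction` must lie in [0, 1]", call. = FALSE)
  }
  if (!is.null(effect)) {
    if (!is.list(effect) || is.null(effect$probes) || is.null(effect$delta)) {
      stop("`effect` must be a list with `probes` and `delta`", call. = FALSE)
    }
    if (any(effect$probes < 1) || any(effect$probes > n_probes)) {
      stop("`effect$probes` out of range", call. = FALSE)
    }
    if (abs(effect$delta) >= 1) {
      stop("`effect$delta` is a Beta-scale shift and must lie in (-1, 1)",
           call. = FALSE)
    }
  }
  if (eps <= 0 || eps >= 0.5) stop("`eps` must lie in (0, 0.5)", call. = FALSE)
  structure(
    list(n_probes = as.integer(n_probes), n_samples = as.integer(n_samples),
         seed = as.integer(seed), decay_scale = decay_scale,
         max_correlation = max_correlation,
         background_correlation = background_correlation,
         position_model = pm, chromosome = chromosome,
         concentration = concentration, effect = effect, eps = eps),
    class = "sim_config"
  )
}

#' Generate a synthetic CpG probe manifest
#'
#' Draws probe positions along one chromosome as a cluster mixture: with
#' probability `cluster_fraction` the gap to the next probe is a short
#' within-cluster gap, otherwise a long between-cluster gap. This reproduces
#' the non-uniform, island-like spacing of array CpGs that makes the
#' effective number of tests smaller than the probe count.
#'
#' @param config a [sim_config()] object; `n_probes >= 2` required.
#' @return a `data.frame` of class `ewas_manifest` with columns `probe_id`,
#'   `chromosome`, `position` (1-based bp, strictly increasing).
#' @examples
#' mf <- generate_manifest(sim_config(n_probes = 50, n_samples = 10, seed = 7))
#' head(mf)
#' @export
generate_manifest <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  p <- config$n_probes
  if (p < 2) stop("`n_probes` must be >= 2 to form a manifest", call. = FALSE)
  pm <- config$position_model
  with_seed(config$seed, {
    short <- stats::runif(p - 1) < pm$cluster_fraction
    gaps <- numeric(p - 1)
    gaps[short] <- stats::runif(sum(short), pm$within_gap[1], pm$within_gap[2])
    gaps[!short] <- stats::runif(sum(!short), pm$between_gap[1],
                                 pm$between_gap[2])
    positions <- cumsum(c(10000, round(gaps)))
    # guard against rounding collisions: enforce strictly increasing
    positions <- positions + seq_len(p) - 1L
    out <- data.frame(
      probe_id = sprintf("cg%08d", seq_len(p)),
      chromosome = config$chromosome,
      position = as.integer(positions),
      stringsAsFactors = FALSE
    )
    class(out) <- c("ewas_manifest", "data.frame")
    out
  })
}

#' Generate a synthetic Beta-value matrix with distance-decaying correlation
#'
#' Builds a latent Gaussian field over the manifest positions with
#' correlation `rho(d) = bg + (max - bg) * exp(-d / decay_scale)` and maps it
#' probe-wise through a monotone Gaussian-copula transform to Beta scale.
#' The exponential kernel is realised exactly and in `O(n_probes)` time by an
#' Ornstein-Uhlenbeck (nonstationary AR(1)) recursion along the sorted
#' positions; the background floor is a per-sample global factor shared by
#' all probes.
#'
#' Per-probe baseline methylation follows the trimodal pattern of array data
#' (hypo-, intermediate and hypermethylated probes); inter-individual spread
#' is governed by `concentration`. An optional case/control shift adds
#' `effect$delta` to the mean Beta of `effect$probes` for the case columns.
#' All values are clipped into `[eps, 1 - eps]`.
#'
#' @param manifest an `ewas_manifest` from [generate_manifest()].
#' @param config the same [sim_config()] used for the manifest;
#'   `n_samples >= 4` required.
#' @return numeric matrix (probes x samples) of Beta values in `(0, 1)`,
#'   rownames = probe ids, colnames = sample ids.
#' @examples
#' cfg <- sim_config(n_probes = 50, n_samples = 16, seed = 7)
#' beta <- generate_beta(generate_manifest(cfg), cfg)
#' range(beta)
#' @export
generate_beta <- function(manifest, config) {
  stopifnot(inherits(config, "sim_config"))
  if (!is.data.frame(manifest) || nrow(manifest) == 0 ||
      !all(c("probe_id", "position") %in% names(manifest))) {
    stop("`manifest` must be a nonempty manifest data frame", call. = FALSE)
  }
  if (nrow(manifest) != config$n_probes) {
    stop("manifest row count does not match `config$n_probes`", call. = FALSE)
  }
  n <- config$n_samples
  if (n < 4) stop("`n_samples` must be >= 4", call. = FALSE)
  p <- nrow(manifest)
  bg <- config$background_correlation
  mx <- config$max_correlation
  L <- config$decay_scale

  with_seed(config$seed, {
    # per-probe baseline methylation: trimodal mixture as on real arrays
    state <- sample.int(3L, p, replace = TRUE, prob = c(0.35, 0.3, 0.35))
    mu <- numeric(p)
    mu[state == 1L] <- stats::runif(sum(state == 1L), 0.05, 0.20)
    mu[state == 2L] <- stats::runif(sum(state == 2L), 0.25, 0.75)
    mu[state == 3L] <- stats::runif(sum(state == 3L), 0.80, 0.95)

    x <- matrix(0, p, n)
    if (bg > 0) {
      g <- stats::rnorm(n)                      # shared background factor
      x <- x + sqrt(bg) * matrix(g, p, n, byrow = TRUE)
    }
    if (mx > bg) {
      # OU recursion: corr(z_i, z_j) = exp(-|pos_i - pos_j| / L) exactly
      phi <- exp(-diff(manifest$position) / L)
      innov <- matrix(stats::rnorm(p * n), p, n)
      z <- matrix(0, p, n)
      z[1, ] <- innov[1, ]
      for (i in seq_len(p - 1L)) {
        z[i + 1L, ] <- phi[i] * z[i, ] + sqrt(1 - phi[i]^2) * innov[i + 1L, ]
      }
      x <- x + sqrt(mx - bg) * z
    }
    if (mx < 1) {
      x <- x + sqrt(1 - mx) * matrix(stats::rnorm(p * n), p, n)
    }

    a <- mu * config$concentration
    b <- (1 - mu) * config$concentration
    beta <- matrix(stats::qbeta(stats::pnorm(x), a, b), p, n)

    if (!is.null(config$effect) && config$effect$delta != 0) {
      cases <- config$effect$cases
      if (is.null(cases)) cases <- seq_len(n %/% 2L)
      beta[config$effect$probes, cases] <-
        beta[config$effect$probes, cases] + config$effect$delta
    }
    beta <- pmin(pmax(beta, config$eps), 1 - config$eps)
    dimnames(beta) <- list(manifest$probe_id, sprintf("S%04d", seq_len(n)))
    beta
  })
}

#' Write a manifest or Beta matrix as TSV
#'
#' `write_manifest()` writes `probe_id`, `chromosome`, `position` columns;
#' `write_beta_matrix()` writes the probe id as first column followed by one
#' column per sample. Both use tab separation and can be read back with
#' [read_manifest()] / [read_beta_matrix()].
#'
#' @param manifest an `ewas_manifest` data frame.
#' @param beta a probes x samples Beta matrix with dimnames.
#' @param path output file path.
#' @return the path, invisibly.
#' @export
write_manifest <- function(manifest, path) {
  data.table::fwrite(as.data.frame(manifest), path, sep = "\t")
  invisible(path)
}

#' @rdname write_manifest
#' @export
write_beta_matrix <- function(beta, path) {
  dt <- data.table::as.data.table(beta, keep.rownames = "probe_id")
  data.table::fwrite(dt, path, sep = "\t")
  invisible(path)
}
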