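#' Convert Beta values to M values
#'
#' Applies the logit-2 transform `M = log2(Beta / (1 - Beta))`, the scale on
#' which per-CpG t-tests behave best (approximately homoscedastic, closer to
#' normal). Values must be strictly inside `(0, 1)`; clip or clean first
#' (the synthetic generator clips at `eps`, keeping `|M| <~ 20`).
#'
#' @param beta numeric matrix or vector of Beta values in `(0, 1)`.
#' @return object of the same shape on the M scale.
#' @examples
#' beta_to_m(c(0.2, 0.5, 0.8))  # -2, 0, 2
#' @export
beta_to_m <- function(beta) {
  if (!is.numeric(beta)) stop("`beta` must be numeric", call. = FALSE)
  if (anyNA(beta)) stop("`beta` contains missing values", call. = FALSE)
  if (any(beta <= 0 | beta >= 1)) {
    stop("Beta values must lie strictly in (0, 1); clip or clean first",
         call. = FALSE)
  }
  log2(beta / (1 - beta))
}

#' @rdname beta_to_m
#' @param m numeric matrix or vector of M values.
#' @export
m_to_beta <- function(m) {
  if (!is.numeric(m)) stop("`m` must be numeric", call. = FALSE)
  1 / (1 + 2^(-m))
}

#' Read a Beta matrix or probe manifest from delimited text
#'
#' `read_beta_matrix()` expects the probe id in the first column and one
#' column per sample; `read_manifest()` expects `probe_id`, `chromosome`,
#' `position` columns. The delimiter (tab or comma) is auto-detected.
#' Matrix rows containing missing values are dropped with a message.
#'
#' @param path file path (TSV or CSV).
#' @return `read_beta_matrix()`: numeric matrix with probe-id rownames;
#'   `read_manifest()`: an `ewas_manifest` data frame.
#' @export
read_beta_matrix <- function(path) {
  dt <- data.table::fread(path, header = TRUE, data.table = TRUE)
  ids <- as.character(dt[[1L]])
  m <- as.matrix(dt[, -1L, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- ids
  bad <- rowSums(is.na(m)) > 0L
  if (any(bad)) {
    message(sum(bad), " probe row(s) with missing values dropped")
    m <- m[!bad, , drop = FALSE]
  }
  m
}

#' @rdname read_beta_matrix
#' @export
read_manifest <- function(path) {
  dt <- data.table::fread(path, header = TRUE, data.table = FALSE)
  need <- c("probe_id", "chromosome", "position")
  if (!all(need %in% names(dt))) {
    stop("manifest must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  out <- dt[, need]
  out$probe_id <- as.character(out$probe_id)
  out$position <- as.integer(out$position)
  if (anyDuplicated(out$probe_id)) {
    stop("duplicated probe ids in manifest", call. = FALSE)
  }
  class(out) <- c("ewas_manifest", "data.frame")
  out
}

#' Align a Beta matrix to a manifest
#'
#' Drops matrix probes absent from the manifest (with a message) and orders
#' the rows to match the manifest (which is ordered by position within
#' chromosome).
#'
#' @param beta probes x samples matrix with probe-id rownames.
#' @param manifest an `ewas_manifest`.
#' @return list with elements `beta` and `manifest`, row-aligned.
#' @export
align_to_manifest <- function(beta, manifest) {
  keep <- rownames(beta) %in% manifest$probe_id
  if (!all(keep)) {
    message(sum(!keep), " probe(s) not in manifest dropped from matrix")
    beta <- beta[keep, , drop = FALSE]
  }
  mf <- manifest[manifest$probe_id %in% rownames(beta), , drop = FALSE]
  ord <- order(mf$chromosome, mf$position)
  mf <- mf[ord, , drop = FALSE]
  list(beta = beta[mf$probe_id, , drop = FALSE], manifest = mf)
}

#' Correlation-versus-distance profile of co-methylation
#'
#' Enumerates all probe pairs on one chromosome separated by at most
#' `max_distance` bp (sorted sliding window), computes the Pearson
#' correlation of their Beta rows, sorts pairs by inter-probe distance and
#' partitions them into consecutive equal-occupancy bins of
#' `pairs_per_bin` pairs (the last bin may be smaller). Ties in distance
#' keep enumeration order. Pairs where either probe has zero variance are
#' skipped with a message.
#'
#' Correlations are computed on the Beta scale (the scale on which
#' co-methylation is conventionally reported); association tests elsewhere
#' in the package use M values.
#'
#' @param beta probes x samples Beta matrix, rows aligned to `manifest`.
#' @param manifest an `ewas_manifest` covering the rows of `beta`.
#' @param chromosome chromosome label to profile; default: the first one
#'   present.
#' @param max_distance maximum inter-probe distance in bp (default 10000).
#' @param pairs_per_bin target number of pairs per bin (default 400).
#' @return a `data.frame` of class `decay_curve` with columns
#'   `median_distance`, `mean_correlation`, `n_pairs`; attribute
#'   `n_pairs_total` holds the number of within-cutoff pairs.
#' @examples
#' cfg <- sim_config(n_probes = 200, n_samples = 40, seed = 3)
#' mf <- generate_manifest(cfg)
#' beta <- generate_beta(mf, cfg)
#' prof <- correlation_profile(beta, mf, pairs_per_bin = 50)
#' @export
correlation_profile <- function(beta, manifest, chromosome = NULL,
                                max_distance = 10000, pairs_per_bin = 400) {
  if (max_distance <= 0) stop("`max_distance` must be positive", call. = FALSE)
  if (pairs_per_bin < 1) stop("`pairs_per_bin` must be >= 1", call. = FALSE)
  if (is.null(chromosome)) chromosome <- manifest$chromosome[1L]
  mf <- manifest[manifest$chromosome == chromosome, , drop = FALSE]
  if (nrow(mf) < 2L) {
    stop("fewer than 2 manifest probes on chromosome ", chromosome,
         call. = FALSE)
  }
  mf <- mf[order(mf$position), , drop = FALSE]
  x <- beta[mf$probe_id, , drop = FALSE]
  n <- ncol(x)
  if (n < 3L) stop("need at least 3 samples for correlations", call. = FALSE)

  # standardise rows so a pair's correlation is a dot product
  mu <- rowMeans(x)
  xc <- x - mu
  ss <- sqrt(rowSums(xc^2))
  degenerate <- ss == 0
  ss[degenerate] <- NA_real_
  xs <- xc / ss

  pos <- mf$position
  p <- nrow(mf)
  ii <- vector("list", p)
  jj <- vector("list", p)
  hi <- 1L
  for (i in seq_len(p - 1L)) {
    if (hi < i + 1L) hi <- i + 1L
    while (hi < p && pos[hi + 1L] - pos[i] <= max_distance) hi <- hi + 1L
    if (pos[hi] - pos[i] <= max_distance && hi > i) {
      ii[[i]] <- rep.int(i, hi - i)
      jj[[i]] <- (i + 1L):hi
    }
  }
  i_idx <- unlist(ii)
  j_idx <- unlist(jj)
  if (is.null(i_idx) || length(i_idx) == 0L) {
    stop("no probe pairs within `max_distance` on chromosome ", chromosome,
         call. = FALSE)
  }
  dist <- pos[j_idx] - pos[i_idx]
  corr <- numeric(length(i_idx))
  chunk <- 50000L
  for (s in seq(1L, length(i_idx), by = chunk)) {
    e <- min(s + chunk - 1L, length(i_idx))
    corr[s:e] <- rowSums(xs[i_idx[s:e], , drop = FALSE] *
                           xs[j_idx[s:e], , drop = FALSE])
  }

  skip <- is.na(corr)
  if (any(skip)) {
    message(sum(skip), " pair(s) skipped for zero variance")
    i_idx <- i_idx[!skip]; j_idx <- j_idx[!skip]
    dist <- dist[!skip]; corr <- corr[!skip]
  }
  n_total <- length(dist)

  ord <- order(dist)          # stable: distance ties keep enumeration order
  dist <- dist[ord]
  corr <- corr[ord]
  bin <- (seq_len(n_total) - 1L) %/% as.integer(pairs_per_bin) + 1L
  out <- data.frame(
    median_distance = as.numeric(tapply(dist, bin, stats::median)),
    mean_correlation = as.numeric(tapply(corr, bin, mean)),
    n_pairs = as.integer(tapply(corr, bin, length))
  )
  attr(out, "n_pairs_total") <- n_total
  attr(out, "chromosome") <- chromosome
  class(out) <- c("decay_curve", "data.frame")
  out
}
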