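# Internal helpers shared across modules.

#' Evaluate an expression under a local RNG seed
#'
#' Restores the caller's `.Random.seed` on exit so seeded generator functions
#' do not disturb the global RNG stream.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @keywords internal
#' @noRd
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    stop("`seed` must be a single integer", call. = FALSE)
  }
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

# Column minima of a numeric matrix (C-speed via max.col); NAs not allowed.
col_mins <- function(m) {
  m[cbind(max.col(t(-m), ties.method = "first"), seq_len(ncol(m)))]
}

stop_if_not_scalar_prob <- function(x, name, open = TRUE) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x)) {
    stop(sprintf("`%s` must be a single number", name), call. = FALSE)
  }
  if (open && (x <= 0 || x >= 1)) {
    stop(sprintf("`%s` must lie strictly in (0, 1)", name), call. = FALSE)
  }
  invisible(x)
}
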