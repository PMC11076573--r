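# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_field <- function(field, msg) {
  stop(sprintf("invalid `%s`: %s", field, msg), call. = FALSE)
}

check_number <- function(x, field, lo = -Inf, hi = Inf, integer = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop_field(field, "must be a single finite number")
  if (x < lo || x > hi)
    stop_field(field, sprintf("must be in [%s, %s]", lo, hi))
  if (integer && x != round(x))
    stop_field(field, "must be an integer")
  invisible(x)
}

# Fast per-sample medians over a small probe block. Columns are samples.
col_medians <- function(m) {
  k <- nrow(m)
  if (k == 1L) return(m[1L, ])
  if (k == 2L) return((m[1L, ] + m[2L, ]) / 2)
  if (k == 3L) {
    a <- m[1L, ]; b <- m[2L, ]; d <- m[3L, ]
    return(pmin(pmax(a, b), pmax(pmin(a, b), d)))
  }
  apply(m, 2L, stats::median)
}

# Weighted median via the cumulative-weight definition (midpoint at ties).
weighted_median <- function(x, w) {
  stopifnot(length(x) == length(w))
  keep <- w > 0
  x <- x[keep]; w <- w[keep]
  if (!length(x)) return(NA_real_)
  o <- order(x)
  x <- x[o]; w <- w[o]
  cw <- cumsum(w) / sum(w)
  i <- which(cw >= 0.5)[1L]
  if (abs(cw[i] - 0.5) < 1e-12 && i < length(x)) (x[i] + x[i + 1L]) / 2 else x[i]
}

# Derive a reproducible sub-stream seed (< 2^31) from a base seed and a label,
# so adding one modality never perturbs the draws of another.
derive_seed <- function(seed, label) {
  h <- sum(utf8ToInt(label) * seq_along(utf8ToInt(label)))
  (as.integer(seed) %% 1000003L) * 1009L + (h %% 65521L)
}

# Evaluate expr under a fixed RNG seed, restoring the caller's stream after.
with_preserved_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  }, add = TRUE)
  set.seed(seed)
  expr
}
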