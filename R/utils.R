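# Internal helpers shared across modules.

# Run `code` under a temporary RNG state seeded with `seed`, restoring the
# caller's RNG afterwards so generators are pure functions of their inputs.
with_seed <- function(seed, code) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.finite(seed))
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

# Fast row-wise maximum (pmax sweep over the K columns).
row_max <- function(x) {
  m <- x[, 1]
  for (j in seq_len(ncol(x))[-1]) m <- pmax(m, x[, j])
  m
}

# Numerically stable log(sum(exp(x))) along matrix rows.
row_logsumexp <- function(x) {
  m <- row_max(x)
  m + log(rowSums(exp(x - m)))
}

assert_prob_matrix <- function(p, arg = "probabilities") {
  if (!is.matrix(p) || !is.numeric(p)) {
    stop(sprintf("`%s` must be a numeric matrix", arg), call. = FALSE)
  }
  if (any(!is.finite(p)) || any(p < -1e-12)) {
    stop(sprintf("`%s` must contain finite non-negative values", arg),
         call. = FALSE)
  }
  if (any(abs(rowSums(p) - 1) > 1e-6)) {
    stop(sprintf("rows of `%s` must sum to 1", arg), call. = FALSE)
  }
  invisible(p)
}

assert_labels <- function(labels, n, K) {
  labels <- as.integer(labels)
  if (length(labels) != n) {
    stop("`labels` length must match the number of rows", call. = FALSE)
  }
  if (any(labels < 0L | labels >= K)) {
    stop(sprintf("`labels` must lie in [0, %d)", K), call. = FALSE)
  }
  labels
}

# Shannon entropy (natural log) of a non-negative count/weight vector,
# with the 0 * log 0 = 0 convention.
entropy_nat <- function(w) {
  s <- sum(w)
  if (s <= 0) return(0)
  p <- w / s
  p <- p[p > 0]
  -sum(p * log(p))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
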