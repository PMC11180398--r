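# Internal helpers shared across modules.

# Evaluate `expr` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed))
    stop("`seed` must be a single integer", call. = FALSE)
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# Derive a child seed from a parent seed and an index, staying inside the
# 32-bit signed integer range R requires.
derive_seed <- function(seed, i) {
  as.integer((as.numeric(seed) * 1009 + as.numeric(i) * 9973) %% 2147483647)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

relu <- function(x) {
  x[x < 0] <- 0
  x
}

row_max <- function(x) x[cbind(seq_len(nrow(x)), max.col(x, ties.method = "first"))]

# Row-wise numerically stable softmax. Mass below 1e-20 of the row max is
# flushed to exact zero: it is negligible against the softmax sum and
# keeps denormalized numbers (a large slowdown on most FPUs) out of the
# downstream matrix products.
softmax_rows <- function(x) {
  x <- x - row_max(x)
  e <- exp(x)
  e[e < 1e-20] <- 0
  e / rowSums(e)
}

# Row-wise log-softmax.
log_softmax_rows <- function(x) {
  x <- x - row_max(x)
  x - log(rowSums(exp(x)))
}

# rowsum() that always returns a matrix with `n` rows in index order,
# including all-zero rows for absent groups.
rowsum_full <- function(x, group, n) {
  out <- matrix(0, n, ncol(x))
  rs <- rowsum(x, group = group)
  idx <- as.integer(rownames(rs))
  out[idx, ] <- rs
  out
}

# Glorot/Xavier uniform initialization for a fan_out x fan_in matrix.
glorot <- function(n_out, n_in) {
  s <- sqrt(6 / (n_in + n_out))
  matrix(stats::runif(n_out * n_in, -s, s), n_out, n_in)
}

stop_if_not <- function(cond, msg) if (!isTRUE(cond)) stop(msg, call. = FALSE)
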