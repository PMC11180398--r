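#' Relation weight factorization
#'
#' Container for the per-relation weight matrices of a relational graph
#' convolution layer, in one of three parameterizations:
#' \describe{
#'   \item{`basis`}{`W_r = sum_b a[r, b] * V[[b]]`: `B` shared basis
#'     matrices with relation-specific coefficients, so only the
#'     coefficients depend on the relation.}
#'   \item{`block_diagonal`}{`W_r = blockdiag(Q[[r]][[1]], ..., Q[[r]][[B]])`
#'     with blocks of shape `(d_out/B) x (d_in/B)`; at `B = d` every block
#'     is `1 x 1` and `W_r` is diagonal.}
#'   \item{`full`}{unconstrained per-relation matrices.}
#' }
#'
#' @param mode One of `"basis"`, `"block_diagonal"`, `"full"`.
#' @param bases List of `B` matrices `d_out x d_in` (basis mode).
#' @param coefficients `R x B` coefficient matrix (basis mode).
#' @param blocks List of `R` lists of `B` blocks (block mode).
#' @param weights List of `R` matrices (full mode).
#' @param self_weight Optional `d_out x d_in` self-connection matrix.
#' @return A `relation_weight_factors` object.
#' @export
relation_weight_factors <- function(mode = c("basis", "block_diagonal", "full"),
                                    bases = NULL, coefficients = NULL,
                                    blocks = NULL, weights = NULL,
                                    self_weight = NULL) {
  mode <- match.arg(mode)
  out <- structure(list(mode = mode, bases = bases,
                        coefficients = coefficients, blocks = blocks,
                        weights = weights, self_weight = self_weight),
                   class = "relation_weight_factors")
  if (mode == "basis") {
    stop_if_not(is.list(bases) && length(bases) >= 1L, "basis mode needs bases")
    coefficients <- as.matrix(coefficients)
    stop_if_not(ncol(coefficients) == length(bases),
                "coefficients must be R x B with B = length(bases)")
    dims <- unique(lapply(bases, dim))
    stop_if_not(length(dims) == 1L, "all bases must share a shape")
    out$coefficients <- coefficients
  } else if (mode == "block_diagonal") {
    stop_if_not(is.list(blocks) && length(blocks) >= 1L,
                "block mode needs blocks")
  } else {
    stop_if_not(is.list(weights) && length(weights) >= 1L,
                "full mode needs weights")
  }
  out
}

#' Materialize per-relation weight matrices
#'
#' Expands a [relation_weight_factors()] object into the list of dense
#' `d_out x d_in` matrices `W_r`. In block-diagonal mode, entries outside
#' the diagonal blocks are exactly zero.
#'
#' @param factors A `relation_weight_factors` object.
#' @return List of `R` dense matrices.
#' @export
materialize_relation_weights <- function(factors) {
  stop_if_not(inherits(factors, "relation_weight_factors"),
              "factors must be a relation_weight_factors object")
  switch(factors$mode,
    basis = {
      a <- factors$coefficients
      lapply(seq_len(nrow(a)), function(r) {
        W <- a[r, 1L] * factors$bases[[1L]]
        for (b in seq_along(factors$bases)[-1L])
          W <- W + a[r, b] * factors$bases[[b]]
        W
      })
    },
    block_diagonal = lapply(factors$blocks, block_diag),
    full = factors$weights
  )
}

# Direct sum of square-ish blocks into one matrix.
block_diag <- function(blocks) {
  rs <- vapply(blocks, nrow, 0L)
  cs <- vapply(blocks, ncol, 0L)
  W <- matrix(0, sum(rs), sum(cs))
  ro <- 0L; co <- 0L
  for (b in seq_along(blocks)) {
    W[ro + seq_len(rs[b]), co + seq_len(cs[b])] <- blocks[[b]]
    ro <- ro + rs[b]; co <- co + cs[b]
  }
  W
}

# 0/1 mask of the block-diagonal sparsity pattern for d_out x d_in with B
# blocks (requires B | d_out and B | d_in).
block_mask <- function(d_out, d_in, B) {
  stop_if_not(d_out %% B == 0L && d_in %% B == 0L,
              sprintf("block count %d must divide both %d and %d",
                      B, d_out, d_in))
  M <- matrix(0, d_out, d_in)
  br <- d_out %/% B; bc <- d_in %/% B
  for (b in seq_len(B))
    M[(b - 1L) * br + seq_len(br), (b - 1L) * bc + seq_len(bc)] <- 1
  M
}

# Materialize the per-relation weights used during training from the flat
# parameter list. Basis mode keeps bases/coefficients as parameters; block
# mode keeps a full matrix whose gradient and value are masked to the block
# pattern; full mode is unconstrained.
train_relation_weights <- function(params, prefix, config) {
  R <- config$n_relations
  if (config$decomposition == "basis") {
    a <- params[[paste0(prefix, "_coef")]]
    V <- params[[paste0(prefix, "_bases")]]  # list of B matrices
    lapply(seq_len(R), function(r) {
      W <- a[r, 1L] * V[[1L]]
      for (b in seq_along(V)[-1L]) W <- W + a[r, b] * V[[b]]
      W
    })
  } else if (config$decomposition == "block_diagonal") {
    lapply(seq_len(R), function(r) {
      W <- params[[paste0(prefix, "_W", r)]]
      W * attr(W, "mask")
    })
  } else {
    lapply(seq_len(R), function(r) params[[paste0(prefix, "_W", r)]])
  }
}

# Backward of train_relation_weights: convert per-relation dW into
# gradients of the underlying parameters, accumulated into `grads`.
train_relation_weights_bwd <- function(grads, dWr, params, prefix, config) {
  R <- config$n_relations
  if (config$decomposition == "basis") {
    a <- params[[paste0(prefix, "_coef")]]
    V <- params[[paste0(prefix, "_bases")]]
    B <- length(V)
    da <- matrix(0, R, B)
    dV <- lapply(V, function(v) matrix(0, nrow(v), ncol(v)))
    for (r in seq_len(R)) {
      for (b in seq_len(B)) {
        da[r, b] <- sum(dWr[[r]] * V[[b]])
        dV[[b]] <- dV[[b]] + a[r, b] * dWr[[r]]
      }
    }
    grads[[paste0(prefix, "_coef")]] <- da
    grads[[paste0(prefix, "_bases")]] <- dV
  } else if (config$decomposition == "block_diagonal") {
    for (r in seq_len(R)) {
      W <- params[[paste0(prefix, "_W", r)]]
      grads[[paste0(prefix, "_W", r)]] <- dWr[[r]] * attr(W, "mask")
    }
  } else {
    for (r in seq_len(R)) grads[[paste0(prefix, "_W", r)]] <- dWr[[r]]
  }
  grads
}
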