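# Forward/backward passes for the model's layers. Every *_fwd function
# returns the output plus the cache its *_bwd twin needs; thin exported
# wrappers expose the forward math on its own.

## ---- layer normalization -------------------------------------------------

#' Layer-normalization parameters
#'
#' @param d Vector width.
#' @param eps Variance-stabilizing constant (> 0).
#' @return A `layer_norm_params` list with unit gain and zero bias.
#' @export
layer_norm_params <- function(d, eps = 1e-5) {
  stop_if_not(eps > 0, "eps must be > 0")
  structure(list(gamma = rep(1, d), beta = rep(0, d), eps = eps),
            class = "layer_norm_params")
}

#' Layer normalization
#'
#' Normalizes each row of `X` to zero mean and unit (population) variance,
#' then applies the elementwise affine transform
#' `xhat * gamma + beta`.
#'
#' @param X Numeric matrix (rows are vectors to normalize).
#' @param params A [layer_norm_params()] (or any list with `gamma`, `beta`,
#'   `eps`).
#' @return Matrix of the same shape.
#' @export
layer_norm <- function(X, params = layer_norm_params(ncol(X))) {
  ln_fwd(as.matrix(X), params$gamma, params$beta, params$eps)$out
}

ln_fwd <- function(X, gamma, beta, eps) {
  mu <- rowMeans(X)
  Xm <- X - mu
  v <- rowMeans(Xm^2)
  inv <- 1 / sqrt(v + eps)
  xhat <- Xm * inv
  out <- sweep(xhat, 2L, gamma, `*`)
  out <- sweep(out, 2L, beta, `+`)
  list(out = out, xhat = xhat, inv = inv, Xm = Xm)
}

ln_bwd <- function(dout, cache, gamma) {
  d <- ncol(dout)
  dxhat <- sweep(dout, 2L, gamma, `*`)
  dgamma <- colSums(dout * cache$xhat)
  dbeta <- colSums(dout)
  # dX for population-variance layer norm
  rs1 <- rowSums(dxhat)
  rs2 <- rowSums(dxhat * cache$xhat)
  dX <- cache$inv * (dxhat - rs1 / d - cache$xhat * rs2 / d)
  list(dX = dX, dgamma = dgamma, dbeta = dbeta)
}

## ---- multi-head attention ------------------------------------------------

#' Multi-head self-attention parameters
#'
#' @param d Model width (divisible by `n_heads`).
#' @param n_heads Number of attention heads.
#' @param learned_value Include a learned value projection (the
#'   conventional variant); if `FALSE` the value path is the fused input
#'   sequence itself, mirroring an attention formulation that multiplies
#'   the attention weights directly onto the summed endpoint features.
#' @param seed RNG seed for initialization.
#' @return An `attention_params` list (`Wq`, `Wk`, optionally `Wv`, `Wo`,
#'   `n_heads`, `d_k`).
#' @export
attention_params <- function(d, n_heads = 4L, learned_value = FALSE,
                             seed = 1L) {
  stop_if_not(d %% n_heads == 0L, "width must be divisible by n_heads")
  with_seed(seed, {
    p <- list(Wq = glorot(d, d), Wk = glorot(d, d), Wo = glorot(d, d),
              n_heads = as.integer(n_heads), d_k = d %/% n_heads)
    if (learned_value) p$Wv <- glorot(d, d)
    structure(p, class = "attention_params")
  })
}

#' Multi-head self-attention over a sequence of edge latents
#'
#' Per head: attention weights are the row-softmax of
#' `Q K^T / sqrt(d_k)` (each row sums to 1); head outputs are concatenated
#' and passed through the output projection. With the default fused value
#' path the values are the input latents themselves; with a learned `Wv`
#' the conventional value projection is used.
#'
#' @param Z `L x d` matrix: the batch's edge-latent sequence.
#' @param params An [attention_params()].
#' @return `L x d` matrix of refined latents. The per-head attention
#'   matrices are attached as attribute `"attention"`.
#' @export
multi_head_attention <- function(Z, params) {
  f <- attn_fwd(as.matrix(Z), params$Wq, params$Wk, params$Wv, params$Wo,
                params$n_heads)
  structure(f$out, attention = f$A)
}

attn_fwd <- function(Z, Wq, Wk, Wv, Wo, n_heads) {
  L <- nrow(Z); d <- ncol(Z)
  stop_if_not(d %% n_heads == 0L, "width must be divisible by n_heads")
  dk <- d %/% n_heads
  QQ <- Z %*% Wq
  KK <- Z %*% Wk
  VV <- if (is.null(Wv)) Z else Z %*% Wv
  C <- matrix(0, L, d)
  A <- vector("list", n_heads)
  for (h in seq_len(n_heads)) {
    cols <- (h - 1L) * dk + seq_len(dk)
    S <- tcrossprod(QQ[, cols, drop = FALSE], KK[, cols, drop = FALSE]) / sqrt(dk)
    A[[h]] <- softmax_rows(S)
    C[, cols] <- A[[h]] %*% VV[, cols, drop = FALSE]
  }
  out <- C %*% Wo
  list(out = out, A = A, C = C, QQ = QQ, KK = KK, VV = VV, dk = dk)
}

attn_bwd <- function(dout, cache, Z, Wq, Wk, Wv, Wo, n_heads) {
  dk <- cache$dk
  dC <- dout %*% t(Wo)
  dWo <- crossprod(cache$C, dout)
  L <- nrow(Z); d <- ncol(Z)
  dQQ <- matrix(0, L, d); dKK <- matrix(0, L, d); dVV <- matrix(0, L, d)
  for (h in seq_len(n_heads)) {
    cols <- (h - 1L) * dk + seq_len(dk)
    dCh <- dC[, cols, drop = FALSE]
    Ah <- cache$A[[h]]
    Vh <- cache$VV[, cols, drop = FALSE]
    dAh <- tcrossprod(dCh, Vh)
    dVV[, cols] <- crossprod(Ah, dCh)
    dS <- Ah * (dAh - rowSums(dAh * Ah))  # softmax backward, row-wise
    dS <- dS / sqrt(dk)
    dQQ[, cols] <- dS %*% cache$KK[, cols, drop = FALSE]
    dKK[, cols] <- crossprod(dS, cache$QQ[, cols, drop = FALSE])
  }
  dZ <- dQQ %*% t(Wq) + dKK %*% t(Wk)
  dWq <- crossprod(Z, dQQ)
  dWk <- crossprod(Z, dKK)
  dWv <- NULL
  if (is.null(Wv)) {
    dZ <- dZ + dVV
  } else {
    dZ <- dZ + dVV %*% t(Wv)
    dWv <- crossprod(Z, dVV)
  }
  list(dZ = dZ, dWq = dWq, dWk = dWk, dWv = dWv, dWo = dWo)
}

## ---- relational graph convolution ----------------------------------------

#' Message along one arc
#'
#' The edge-wise half of message passing: the message carried by arc
#' `(u, e, v)` is `W_r %*% (x_u + P %*% w_e)`, a function of the source
#' state, the arc's attribute (projected into the input space by `P`), and
#' the arc's relation weights. With the edge-propagation ablation the
#' attribute term is omitted.
#'
#' @param node_states `|V| x d_in` matrix.
#' @param arc Integer pair `(u, v)`: source and destination indices.
#' @param edge_feature Attribute vector of the arc (or `NULL` when ablated).
#' @param W_r Relation weight matrix `d_out x d_in`.
#' @param P Edge-feature projection `d_in x d_edge` (required with an edge
#'   feature).
#' @param use_edge Include the edge-feature term.
#' @return Message vector of length `d_out`.
#' @export
edge_message <- function(node_states, arc, edge_feature, W_r, P = NULL,
                         use_edge = TRUE) {
  u <- arc[[1L]]
  stop_if_not(u >= 1L && u <= nrow(node_states), "arc source out of range")
  x <- node_states[u, ]
  if (use_edge) {
    stop_if_not(!is.null(edge_feature) && !is.null(P),
                "edge feature and projection required unless ablated")
    x <- x + as.numeric(P %*% edge_feature)
  }
  as.numeric(W_r %*% x)
}

# Internal cached RGCN layer forward.
#   H: |V| x d_in states; rel_arcs/rel_invc: per-relation arc matrices and
#   per-arc 1/c normalizers; W0: self weight (d_out x d_in); Wr: list of
#   relation weights. Arc attributes are endpoint concatenations, so their
#   projection P [f_src; f_dst] factorizes into node-level products:
#   EL = X0 P_left^T and ER = X0 P_right^T, gathered per arc. NULL EL/ER
#   drops the attribute term.
# The per-arc input is (H + EL)[src, ] + ER[dst, ], so the message batch
# factorizes through node-level products:
#   In %*% t(W_r) = ((H + EL) %*% t(W_r))[src, ] + (ER %*% t(W_r))[dst, ]
# and the backward pass likewise reduces to rowsum-grouped node-level
# products — no arc-length matrix multiplication anywhere.
rgcn_fwd <- function(H, rel_arcs, rel_invc, W0, Wr, EL = NULL, ER = NULL,
                     activation = c("relu", "identity")) {
  activation <- match.arg(activation)
  n <- nrow(H)
  pre <- tcrossprod(H, W0)
  HE <- if (is.null(EL)) H else H + EL
  for (r in seq_along(rel_arcs)) {
    arcs <- rel_arcs[[r]]
    if (is.null(arcs) || nrow(arcs) == 0L) next
    M <- tcrossprod(HE, Wr[[r]])[arcs[, 1L], , drop = FALSE]
    if (!is.null(ER))
      M <- M + tcrossprod(ER, Wr[[r]])[arcs[, 2L], , drop = FALSE]
    M <- M * rel_invc[[r]]
    pre <- pre + rowsum_full(M, arcs[, 2L], n)
  }
  out <- if (activation == "relu") relu(pre) else pre
  list(out = out, pre = pre, HE = HE, activation = activation)
}

rgcn_bwd <- function(dout, cache, H, rel_arcs, rel_invc, W0, Wr,
                     ER = NULL, use_edge = FALSE) {
  dpre <- if (cache$activation == "relu") dout * (cache$pre > 0) else dout
  dW0 <- crossprod(dpre, H)
  dH <- dpre %*% W0
  dWr <- vector("list", length(Wr))
  n <- nrow(H)
  dEL <- if (use_edge) matrix(0, n, ncol(H)) else NULL
  dER <- if (use_edge) matrix(0, n, ncol(H)) else NULL
  for (r in seq_along(rel_arcs)) {
    arcs <- rel_arcs[[r]]
    if (is.null(arcs) || nrow(arcs) == 0L) {
      dWr[[r]] <- matrix(0, nrow(Wr[[r]]), ncol(Wr[[r]]))
      next
    }
    dM <- dpre[arcs[, 2L], , drop = FALSE] * rel_invc[[r]]
    Gsrc <- rowsum_full(dM, arcs[, 1L], n)
    dWr[[r]] <- crossprod(Gsrc, cache$HE)
    Tsrc <- Gsrc %*% Wr[[r]]
    dH <- dH + Tsrc
    if (use_edge) {
      Gdst <- rowsum_full(dM, arcs[, 2L], n)
      dWr[[r]] <- dWr[[r]] + crossprod(Gdst, ER)
      dEL <- dEL + Tsrc
      dER <- dER + Gdst %*% Wr[[r]]
    }
  }
  list(dH = dH, dW0 = dW0, dWr = dWr, dEL = dEL, dER = dER)
}

#' One relational graph convolution layer
#'
#' Updates every node state as
#' `out_i = act( W0 x_i + sum_r sum_{j in N_i^r} (1/c_ij) W_r fuse(x_j, w_ij) )`
#' where `fuse` adds the projected arc attribute to the neighbor state (the
#' edge-propagation term), and `c_ij` is the per-relation in-degree of `i`
#' (mean normalization, the default) or 1. Nodes with no neighbors receive
#' the self-connection term only.
#'
#' @param graph A `hetero_graph`.
#' @param node_states `|V| x d_in` matrix.
#' @param edge_features Optional list (one per relation) of per-arc
#'   attribute matrices aligned with `graph$relations[[r]]` rows; `NULL`
#'   drops the attribute term.
#' @param factors A [relation_weight_factors()] carrying `self_weight`.
#' @param activation `"relu"` or `"identity"`.
#' @param normalizer `"mean"` (`c_ij = |N_i^r|`) or `"none"` (`c_ij = 1`).
#' @param edge_projection `d_in x d_edge` projection applied to arc
#'   attributes before fusion (required with `edge_features`).
#' @return `|V| x d_out` matrix of updated node states.
#' @export
rgcn_layer_forward <- function(graph, node_states, edge_features = NULL,
                               factors, activation = c("relu", "identity"),
                               normalizer = c("mean", "none"),
                               edge_projection = NULL) {
  activation <- match.arg(activation)
  normalizer <- match.arg(normalizer)
  node_states <- as.matrix(node_states)
  stop_if_not(nrow(node_states) == length(graph$nodes),
              "node_states rows must match the graph's node count")
  Wr <- materialize_relation_weights(factors)
  stop_if_not(length(Wr) == graph$n_relations,
              "factors must provide one weight per relation")
  W0 <- factors$self_weight
  stop_if_not(!is.null(W0), "factors$self_weight is required")
  if (!is.null(edge_features))
    stop_if_not(!is.null(edge_projection),
                "edge_projection is required with edge_features")
  invc <- relation_inv_degree(graph, normalizer)
  n <- nrow(node_states)
  pre <- tcrossprod(node_states, W0)
  for (r in seq_along(graph$relations)) {
    arcs <- graph$relations[[r]]
    if (nrow(arcs) == 0L) next
    Xin <- node_states[arcs[, 1L], , drop = FALSE]
    if (!is.null(edge_features))
      Xin <- Xin + edge_features[[r]] %*% t(edge_projection)
    M <- tcrossprod(Xin, Wr[[r]]) * invc[[r]]
    pre <- pre + rowsum_full(M, arcs[, 2L], n)
  }
  if (activation == "relu") relu(pre) else pre
}

# Per-relation, per-arc 1/c normalizers.
relation_inv_degree <- function(graph, normalizer = "mean") {
  lapply(graph$relations, function(arcs) {
    if (nrow(arcs) == 0L) return(numeric(0L))
    if (normalizer == "none") return(rep(1, nrow(arcs)))
    deg <- table(arcs[, 2L])
    1 / as.numeric(deg[as.character(arcs[, 2L])])
  })
}
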