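# Baseline graph encoders: GCN, GAT, GraphSAGE. Single-relation
# formulations operating on the collapsed untyped adjacency; they share the
# edge-classification head with the relational encoder.

#' Baseline encoder configuration
#'
#' Convenience wrapper over [model_config()] for the baseline encoders.
#'
#' @param encoder `"gcn"`, `"gat"`, or `"sage"`.
#' @param n_relations Number of risk classes.
#' @param layers Number of encoder layers (fixed at 2 in this
#'   implementation, matching the relational encoder for fairness).
#' @param width Hidden width.
#' @param sage_aggregator `"mean"` or `"pooling"`.
#' @param gat_heads GAT attention heads.
#' @return A `model_config`.
#' @export
baseline_config <- function(encoder = c("gcn", "gat", "sage"), n_relations,
                            layers = 2L, width = 64L,
                            sage_aggregator = c("mean", "pooling"),
                            gat_heads = 1L) {
  encoder <- match.arg(encoder)
  stop_if_not(layers == 2L, "this implementation uses 2 encoder layers")
  stop_if_not(width > 0L, "width must be > 0")
  model_config(n_relations = n_relations, encoder = encoder, hidden = width,
               sage_aggregator = match.arg(sage_aggregator),
               gat_heads = gat_heads)
}

#' One graph-convolution (GCN) layer
#'
#' `H' = act( D^{-1/2} (A + I) D^{-1/2} H W )` with self-loops added and
#' symmetric degree normalization.
#'
#' @param adjacency Square 0/1 adjacency matrix.
#' @param H `|V| x d` node feature matrix.
#' @param W `d x d'` weight matrix.
#' @param activation `"relu"` or `"identity"`.
#' @return `|V| x d'` matrix.
#' @export
gcn_layer <- function(adjacency, H, W, activation = c("relu", "identity")) {
  activation <- match.arg(activation)
  A <- as.matrix(adjacency)
  stop_if_not(nrow(A) == ncol(A), "adjacency must be square")
  stop_if_not(nrow(A) == nrow(H), "adjacency and H disagree on |V|")
  At <- A + diag(nrow(A))
  dhalf <- 1 / sqrt(rowSums(At))
  pre <- (At * tcrossprod(dhalf)) %*% as.matrix(H) %*% W
  if (activation == "relu") relu(pre) else pre
}

# Numerically stable softmax of z within groups g (per destination node).
group_softmax <- function(z, g) {
  gmax <- tapply(z, g, max)
  zc <- z - gmax[as.character(g)]
  ez <- exp(zc)
  den <- tapply(ez, g, sum)
  as.numeric(ez / den[as.character(g)])
}

# Backward: given dalpha, return dz for a grouped softmax.
group_softmax_bwd <- function(dalpha, alpha, g) {
  s <- tapply(dalpha * alpha, g, sum)
  alpha * (dalpha - as.numeric(s[as.character(g)]))
}

leaky_relu <- function(x, slope = 0.2) ifelse(x > 0, x, slope * x)

# Internal GAT layer used in training. arcs: (src, dst) including
# self-loops. Multi-head outputs are concatenated.
gat_fwd <- function(H, arcs, p, prefix, heads) {
  n <- nrow(H)
  src <- arcs[, 1L]; dst <- arcs[, 2L]
  per <- vector("list", heads)
  out_cols <- list()
  for (h in seq_len(heads)) {
    W <- p[[paste0(prefix, "_W", h)]]
    aL <- p[[paste0(prefix, "_aL", h)]]; aR <- p[[paste0(prefix, "_aR", h)]]
    G <- as.matrix(H) %*% W
    z <- leaky_relu(G[dst, , drop = FALSE] %*% aL +
                    G[src, , drop = FALSE] %*% aR)
    zpre <- G[dst, , drop = FALSE] %*% aL + G[src, , drop = FALSE] %*% aR
    alpha <- group_softmax(as.numeric(z), dst)
    Oh <- rowsum_full(G[src, , drop = FALSE] * alpha, dst, n)
    per[[h]] <- list(G = G, zpre = as.numeric(zpre), alpha = alpha)
    out_cols[[h]] <- Oh
  }
  pre <- do.call(cbind, out_cols)
  list(out = relu(pre), pre = pre, per = per)
}

gat_bwd <- function(dout, cache, H, arcs, p, prefix, heads) {
  n <- nrow(H)
  src <- arcs[, 1L]; dst <- arcs[, 2L]
  dpre <- dout * (cache$pre > 0)
  dh <- ncol(dpre) %/% heads
  dH <- matrix(0, n, ncol(H))
  grads <- list()
  for (h in seq_len(heads)) {
    cols <- (h - 1L) * dh + seq_len(dh)
    dOh <- dpre[, cols, drop = FALSE]
    ch <- cache$per[[h]]
    W <- p[[paste0(prefix, "_W", h)]]
    aL <- p[[paste0(prefix, "_aL", h)]]; aR <- p[[paste0(prefix, "_aR", h)]]
    G <- ch$G; alpha <- ch$alpha
    dOd <- dOh[dst, , drop = FALSE]
    dalpha <- rowSums(dOd * G[src, , drop = FALSE])
    dG <- rowsum_full(dOd * alpha, src, n)
    dz <- group_softmax_bwd(dalpha, alpha, dst)
    dz <- dz * ifelse(ch$zpre > 0, 1, 0.2)          # LeakyReLU backward
    dsL <- rowsum_full(matrix(dz), dst, n)          # z = G[dst]aL + G[src]aR
    dsR <- rowsum_full(matrix(dz), src, n)
    grads[[paste0(prefix, "_aL", h)]] <- as.numeric(crossprod(G, dsL))
    grads[[paste0(prefix, "_aR", h)]] <- as.numeric(crossprod(G, dsR))
    dG <- dG + dsL %*% rbind(aL) + dsR %*% rbind(aR)
    grads[[paste0(prefix, "_W", h)]] <- crossprod(as.matrix(H), dG)
    dH <- dH + dG %*% t(W)
  }
  list(dH = dH, grads = grads)
}

#' One graph-attention (GAT) layer
#'
#' Attention coefficients over each node's in-neighborhood (with an added
#' self-loop) from the single-layer feed-forward scorer
#' `LeakyReLU(a^T [W h_i || W h_j])`, normalized by softmax across the
#' neighborhood; aggregation is the coefficient-weighted sum of projected
#' neighbor features, then the activation.
#'
#' @param adjacency Square 0/1 adjacency matrix.
#' @param H `|V| x d` features.
#' @param params List with `W` (`d x d'`), `a_left`, `a_right` (length
#'   `d'`; the two halves of the scorer vector `a`).
#' @param activation `"relu"` or `"identity"`.
#' @return `|V| x d'` matrix with per-arc coefficients attached as
#'   attribute `"coefficients"` (data frame `src`, `dst`, `alpha`).
#' @export
gat_layer <- function(adjacency, H, params,
                      activation = c("relu", "identity")) {
  activation <- match.arg(activation)
  A <- as.matrix(adjacency)
  stop_if_not(nrow(A) == ncol(A), "adjacency must be square")
  n <- nrow(A)
  nz <- which(A > 0, arr.ind = TRUE)
  # A[i, j] > 0: j is a neighbor of i, contributing arc src = j, dst = i
  arcs <- unique(rbind(cbind(nz[, 2L], nz[, 1L]),
                       cbind(seq_len(n), seq_len(n))))
  arcs <- arcs[order(arcs[, 2L], arcs[, 1L]), , drop = FALSE]
  p <- list(g_W1 = params$W, g_aL1 = params$a_left, g_aR1 = params$a_right)
  f <- gat_fwd(H, arcs, p, "g", 1L)
  out <- if (activation == "relu") f$out else f$pre
  structure(out, coefficients = data.frame(src = arcs[, 1L],
                                           dst = arcs[, 2L],
                                           alpha = f$per[[1L]]$alpha))
}

# Internal pooling-aggregator GraphSAGE layer.
sage_pool_fwd <- function(H, nbrs, Wp, b, Wc) {
  H <- as.matrix(H)
  n <- nrow(H); d <- ncol(Wp)
  Ppre <- sweep(H %*% Wp, 2L, b, `+`)
  Pn <- relu(Ppre)
  agg <- matrix(0, n, d)
  arg <- matrix(0L, n, d)
  for (i in seq_len(n)) {
    nb <- nbrs[[i]]
    if (length(nb)) {
      sub <- Pn[nb, , drop = FALSE]
      w <- apply(sub, 2L, which.max)
      arg[i, ] <- nb[w]
      agg[i, ] <- sub[cbind(w, seq_len(d))]
    }
  }
  Xcat <- cbind(H, agg)
  pre <- Xcat %*% Wc
  list(out = relu(pre), pre = pre, Ppre = Ppre, Pn = Pn, agg = agg,
       arg = arg, Xcat = Xcat)
}

sage_pool_bwd <- function(dout, cache, H, nbrs, Wp, b, Wc) {
  H <- as.matrix(H)
  n <- nrow(H); din <- ncol(H); d <- ncol(Wp)
  dpre <- dout * (cache$pre > 0)
  dWc <- crossprod(cache$Xcat, dpre)
  dXcat <- dpre %*% t(Wc)
  dH <- dXcat[, seq_len(din), drop = FALSE]
  dagg <- dXcat[, din + seq_len(d), drop = FALSE]
  dPn <- matrix(0, n, d)
  for (i in seq_len(n)) {
    a <- cache$arg[i, ]
    sel <- a > 0L
    if (any(sel)) {
      idx <- cbind(a[sel], which(sel))
      dPn[idx] <- dPn[idx] + dagg[i, sel]
    }
  }
  dPpre <- dPn * (cache$Ppre > 0)
  dWp <- crossprod(H, dPpre)
  db <- colSums(dPpre)
  dH <- dH + dPpre %*% t(Wp)
  list(dH = dH, dWp = dWp, db = db, dWc = dWc)
}

#' One GraphSAGE layer
#'
#' Mean mode averages each node's own state with its neighbors' states and
#' projects: `h'_v = act( MEAN({h_v} U {h_u}) W )`. Pooling mode passes
#' every neighbor through a fully connected layer and takes the
#' element-wise max, `max({act(W_pool h_u + b)})`, then combines it with the
#' node's own state through `W`.
#'
#' @param adjacency Square 0/1 adjacency matrix.
#' @param H `|V| x d` features.
#' @param params Mean mode: list with `W` (`d x d'`). Pooling mode: list
#'   with `W_pool` (`d x p`), `b` (length `p`), and `W`
#'   (`(d + p) x d'`).
#' @param aggregator `"mean"` or `"pooling"`.
#' @param activation `"relu"` or `"identity"`.
#' @return `|V| x d'` matrix.
#' @export
sage_layer <- function(adjacency, H, params,
                       aggregator = c("mean", "pooling"),
                       activation = c("relu", "identity")) {
  aggregator <- match.arg(aggregator)
  activation <- match.arg(activation)
  A <- as.matrix(adjacency)
  stop_if_not(nrow(A) == ncol(A), "adjacency must be square")
  if (aggregator == "mean") {
    At <- A + diag(nrow(A))
    pre <- (At / rowSums(At)) %*% as.matrix(H) %*% params$W
    if (activation == "relu") relu(pre) else pre
  } else {
    nbrs <- lapply(seq_len(nrow(A)), function(i) which(A[i, ] > 0))
    f <- sage_pool_fwd(H, nbrs, params$W_pool, params$b, params$W)
    if (activation == "relu") f$out else f$pre
  }
}
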