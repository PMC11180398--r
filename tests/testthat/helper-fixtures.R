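# Shared fixtures, built in code. Heavier objects are memoized per session.

.fixture_env <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (!exists(key, envir = .fixture_env))
    assign(key, force(expr), envir = .fixture_env)
  get(key, envir = .fixture_env)
}

# Small synthetic network + graph for unit tests.
tiny_net <- function(seed = 5L, n = 12L) {
  generate_network(synthetic_config(n_drugs = n, edge_density = 0.3,
                                    n_clusters = 4L, seed = seed))
}

tiny_graph <- function(seed = 5L, n = 12L) {
  net <- tiny_net(seed, n)
  build_hetero_graph(net$events, net$drugs, 4L)
}

# Deterministic random hetero graph over n nodes without chemistry.
random_graph <- function(n, R = 3L, p = 0.4, seed = 1L) {
  ids <- sprintf("N%02d", seq_len(n))
  ev <- with_seed_test(seed, {
    pairs <- which(upper.tri(diag(n)), arr.ind = TRUE)
    keep <- runif(nrow(pairs)) < p
    pairs <- pairs[keep, , drop = FALSE]
    data.frame(drug_a = ids[pairs[, 1L]], drug_b = ids[pairs[, 2L]],
               label = sample(0:(R - 1L), nrow(pairs), replace = TRUE))
  })
  build_hetero_graph(ev, ids, R)
}

with_seed_test <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  expr
}

# Independent dense RGCN oracle: explicit per-node neighbor loops over the
# relation arc lists, with edge attributes as endpoint concatenations.
dense_rgcn_oracle <- function(graph, H, X0attr, W0, Wr, P = NULL,
                              activation = identity) {
  n <- nrow(H)
  out <- matrix(0, n, nrow(W0))
  for (i in seq_len(n)) {
    acc <- W0 %*% H[i, ]
    for (r in seq_along(graph$relations)) {
      arcs <- graph$relations[[r]]
      into <- which(arcs[, 2L] == i)
      if (!length(into)) next
      c_ij <- length(into)
      for (a in into) {
        j <- arcs[a, 1L]
        x <- H[j, ]
        if (!is.null(P)) x <- x + as.numeric(P %*% c(X0attr[j, ], X0attr[i, ]))
        acc <- acc + (Wr[[r]] %*% x) / c_ij
      }
    }
    out[i, ] <- activation(acc)
  }
  out
}

# Independent multi-head attention oracle: per-head scalar loops.
dense_attention_oracle <- function(Z, Wq, Wk, Wo, n_heads, Wv = NULL) {
  L <- nrow(Z); d <- ncol(Z); dk <- d %/% n_heads
  V <- if (is.null(Wv)) Z else Z %*% Wv
  QQ <- Z %*% Wq; KK <- Z %*% Wk
  C <- matrix(0, L, d)
  for (h in seq_len(n_heads)) {
    cols <- (h - 1L) * dk + seq_len(dk)
    for (i in seq_len(L)) {
      s <- sapply(seq_len(L), function(j)
        sum(QQ[i, cols] * KK[j, cols]) / sqrt(dk))
      w <- exp(s - max(s)); w <- w / sum(w)
      C[i, cols] <- colSums(V[, cols, drop = FALSE] * w)
    }
  }
  C %*% Wo
}
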