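#' Model configuration
#'
#' Architecture and ablation settings for the edge classifier. The default
#' encoder is the two-layer relational graph convolution with edge-feature
#' propagation and a multi-head self-attention scoring head; `gcn`, `gat`
#' and `sage` select the baseline encoders, which collapse the typed
#' relations into one untyped adjacency and share the same classification
#' head (relation information reaches them only through edge features).
#'
#' @param n_relations Number of edge relations / risk classes `R`.
#' @param encoder One of `"aergcn"`, `"gcn"`, `"gat"`, `"sage"`.
#' @param hidden Hidden width `d`.
#' @param n_heads Attention heads (must divide `hidden`).
#' @param n_bases Number of basis matrices `B` for the relation-weight
#'   decomposition (default `R`, one basis per risk level).
#' @param decomposition `"basis"`, `"block_diagonal"`, or `"full"`.
#' @param ablation `"none"`, `"no_fp"` (one-hot node features in place of
#'   fingerprints), `"no_at"` (attention block replaced by identity), or
#'   `"no_ep"` (edge-feature terms dropped from propagation and scoring).
#' @param learned_value Use a learned value projection in attention instead
#'   of the fused-input value path.
#' @param sage_aggregator `"mean"` or `"pooling"` (GraphSAGE only).
#' @param gat_heads Attention heads for the GAT baseline.
#' @param attn_block Maximum edge-batch block size the attention head
#'   operates over; larger query batches are partitioned (randomly
#'   reshuffled each training epoch, in input order at inference), which
#'   bounds the quadratic attention cost and varies the attended context.
#' @param eps Layer-norm epsilon.
#' @return A `model_config` list.
#' @export
model_config <- function(n_relations, encoder = c("aergcn", "gcn", "gat", "sage"),
                         hidden = 64L, n_heads = 2L, n_bases = NULL,
                         decomposition = c("basis", "block_diagonal", "full"),
                         ablation = c("none", "no_fp", "no_at", "no_ep"),
                         learned_value = FALSE,
                         sage_aggregator = c("mean", "pooling"),
                         gat_heads = 1L, attn_block = 256L, eps = 1e-5) {
  encoder <- match.arg(encoder)
  decomposition <- match.arg(decomposition)
  ablation <- match.arg(ablation)
  sage_aggregator <- match.arg(sage_aggregator)
  stop_if_not(hidden %% n_heads == 0L, "hidden must be divisible by n_heads")
  stop_if_not(hidden %% gat_heads == 0L, "hidden must be divisible by gat_heads")
  structure(list(n_relations = as.integer(n_relations), encoder = encoder,
                 hidden = as.integer(hidden), n_heads = as.integer(n_heads),
                 n_bases = as.integer(n_bases %||% n_relations),
                 decomposition = decomposition, ablation = ablation,
                 learned_value = learned_value,
                 sage_aggregator = sage_aggregator,
                 gat_heads = as.integer(gat_heads),
                 attn_block = as.integer(attn_block), eps = eps),
            class = "model_config")
}

# Initialize the flat parameter list for a given input feature width.
model_init_params <- function(config, k_in, seed = 1L) {
  d <- config$hidden; R <- config$n_relations; B <- config$n_bases
  with_seed(seed, {
    p <- list()
    init_rel <- function(prefix, d_out, d_in) {
      if (config$decomposition == "basis") {
        p[[paste0(prefix, "_bases")]] <<- lapply(seq_len(B), function(b)
          glorot(d_out, d_in))
        p[[paste0(prefix, "_coef")]] <<- matrix(stats::rnorm(R * B, sd = 1 / sqrt(B)),
                                                R, B)
      } else if (config$decomposition == "block_diagonal") {
        msk <- block_mask(d_out, d_in, B)
        for (r in seq_len(R)) {
          W <- glorot(d_out, d_in) * msk
          attr(W, "mask") <- msk
          p[[paste0(prefix, "_W", r)]] <<- W
        }
      } else {
        for (r in seq_len(R)) p[[paste0(prefix, "_W", r)]] <<- glorot(d_out, d_in)
      }
    }
    if (config$encoder == "aergcn") {
      p$W0_1 <- glorot(d, k_in); init_rel("l1", d, k_in)
      p$W0_2 <- glorot(d, d);    init_rel("l2", d, d)
      if (config$ablation != "no_ep") {
        p$P1 <- glorot(k_in, 2L * k_in)
        p$P2 <- glorot(d, 2L * k_in)
      }
    } else if (config$encoder == "gcn") {
      p$gcn_W1 <- glorot(k_in, d); p$gcn_W2 <- glorot(d, d)
    } else if (config$encoder == "gat") {
      hds <- config$gat_heads; dh <- d %/% hds
      for (h in seq_len(hds)) {
        p[[paste0("gat1_W", h)]] <- glorot(k_in, dh)
        p[[paste0("gat1_aL", h)]] <- stats::rnorm(dh, sd = 0.1)
        p[[paste0("gat1_aR", h)]] <- stats::rnorm(dh, sd = 0.1)
        p[[paste0("gat2_W", h)]] <- glorot(d, dh)
        p[[paste0("gat2_aL", h)]] <- stats::rnorm(dh, sd = 0.1)
        p[[paste0("gat2_aR", h)]] <- stats::rnorm(dh, sd = 0.1)
      }
    } else if (config$encoder == "sage") {
      if (config$sage_aggregator == "mean") {
        p$sage_W1 <- glorot(k_in, d); p$sage_W2 <- glorot(d, d)
      } else {
        p$pool_Wp1 <- glorot(k_in, d); p$pool_b1 <- rep(0, d)
        p$comb_W1 <- glorot(k_in + d, d)
        p$pool_Wp2 <- glorot(d, d); p$pool_b2 <- rep(0, d)
        p$comb_W2 <- glorot(2L * d, d)
      }
    }
    # shared edge head: fuse endpoint states (+ edge attribute), then score
    p$U1 <- glorot(d, d)
    if (config$ablation != "no_ep") p$U2 <- glorot(d, 2L * k_in)
    if (config$encoder == "aergcn" && config$ablation != "no_at") {
      p$Wq <- glorot(d, d); p$Wk <- glorot(d, d); p$Wo <- glorot(d, d)
      if (config$learned_value) p$Wv <- glorot(d, d)
      p$ln_gamma <- rep(1, d); p$ln_beta <- rep(0, d)
    }
    p$Wc <- glorot(R, d); p$bc <- rep(0, R)
    p
  })
}

# Precompute the static per-graph tensors the encoders consume.
#   X0: node attribute matrix (defines arc attributes by concatenation).
graph_tensors <- function(graph, X0, config) {
  n <- length(graph$nodes)
  gd <- list(n = n)
  if (config$encoder == "aergcn") {
    gd$arcs <- graph$relations
    gd$invc <- relation_inv_degree(graph, "mean")
  } else {
    und <- all_edges(graph)
    A <- matrix(0, n, n)
    if (nrow(und)) { A[und] <- 1; A[und[, 2:1, drop = FALSE]] <- 1 }
    gd$A <- A
    if (config$encoder == "gcn") {
      At <- A + diag(n)
      dhalf <- 1 / sqrt(rowSums(At))
      gd$Ahat <- At * tcrossprod(dhalf)
    } else if (config$encoder == "gat") {
      arcs <- rbind(cbind(c(und[, 1L], und[, 2L]), c(und[, 2L], und[, 1L])),
                    cbind(seq_len(n), seq_len(n)))  # self-loops
      gd$gat_arcs <- arcs[order(arcs[, 2L], arcs[, 1L]), , drop = FALSE]
    } else if (config$encoder == "sage") {
      if (config$sage_aggregator == "mean") {
        At <- A + diag(n)
        gd$Anorm <- At / rowSums(At)
      } else {
        gd$nbrs <- lapply(seq_len(n), function(i) which(A[i, ] > 0))
      }
    }
  }
  gd
}

#' Build an (untrained) edge-classification model
#'
#' Assembles the model object: parameters, configuration, the graph's
#' message-passing tensors, and the node attribute matrix. Under the
#' `no_fp` ablation the supplied features are replaced by one-hot identity
#' rows, so the encoder sees only the topology.
#'
#' @param graph A `hetero_graph` (its edges define message passing).
#' @param features `|V| x k` node attribute matrix, rows ordered like
#'   `graph$nodes`.
#' @param config A [model_config()].
#' @param seed RNG seed for parameter initialization.
#' @return A `ddirisk_model` object.
#' @export
build_model <- function(graph, features, config, seed = 1L) {
  stop_if_not(inherits(config, "model_config"), "config must be a model_config")
  features <- as.matrix(features)
  stop_if_not(nrow(features) == length(graph$nodes),
              "features rows must match graph nodes")
  if (config$ablation == "no_fp") features <- diag(length(graph$nodes))
  params <- model_init_params(config, ncol(features), seed)
  structure(list(params = params, config = config, nodes = graph$nodes,
                 features = features,
                 gd = graph_tensors(graph, features, config),
                 seed = as.integer(seed)),
            class = "ddirisk_model")
}

#' @export
print.ddirisk_model <- function(x, ...) {
  cat(sprintf("<ddirisk_model> encoder=%s hidden=%d relations=%d ablation=%s (%d parameter tensors)\n",
              x$config$encoder, x$config$hidden, x$config$n_relations,
              x$config$ablation, length(x$params)))
  invisible(x)
}

# ---- encoder forward/backward dispatch -------------------------------------

encoder_fwd <- function(p, cfg, gd, X0) {
  switch(cfg$encoder,
    aergcn = {
      use_ep <- cfg$ablation != "no_ep"
      Wr1 <- train_relation_weights(p, "l1", cfg)
      Wr2 <- train_relation_weights(p, "l2", cfg)
      k0 <- ncol(X0)
      if (use_ep) {
        EL1 <- X0 %*% t(p$P1[, seq_len(k0), drop = FALSE])
        ER1 <- X0 %*% t(p$P1[, k0 + seq_len(k0), drop = FALSE])
        EL2 <- X0 %*% t(p$P2[, seq_len(k0), drop = FALSE])
        ER2 <- X0 %*% t(p$P2[, k0 + seq_len(k0), drop = FALSE])
      } else EL1 <- ER1 <- EL2 <- ER2 <- NULL
      l1 <- rgcn_fwd(X0, gd$arcs, gd$invc, p$W0_1, Wr1, EL1, ER1)
      l2 <- rgcn_fwd(l1$out, gd$arcs, gd$invc, p$W0_2, Wr2, EL2, ER2)
      list(H = l2$out, cache = list(l1 = l1, l2 = l2, Wr1 = Wr1, Wr2 = Wr2,
                                    ER1 = ER1, ER2 = ER2))
    },
    gcn = {
      AH1 <- gd$Ahat %*% X0
      pre1 <- AH1 %*% p$gcn_W1; H1 <- relu(pre1)
      AH2 <- gd$Ahat %*% H1
      pre2 <- AH2 %*% p$gcn_W2; H2 <- relu(pre2)
      list(H = H2, cache = list(AH1 = AH1, pre1 = pre1, H1 = H1,
                                AH2 = AH2, pre2 = pre2))
    },
    gat = {
      l1 <- gat_fwd(X0, gd$gat_arcs, p, "gat1", cfg$gat_heads)
      l2 <- gat_fwd(l1$out, gd$gat_arcs, p, "gat2", cfg$gat_heads)
      list(H = l2$out, cache = list(l1 = l1, l2 = l2))
    },
    sage = {
      if (cfg$sage_aggregator == "mean") {
        M1 <- gd$Anorm %*% X0
        pre1 <- M1 %*% p$sage_W1; H1 <- relu(pre1)
        M2 <- gd$Anorm %*% H1
        pre2 <- M2 %*% p$sage_W2; H2 <- relu(pre2)
        list(H = H2, cache = list(M1 = M1, pre1 = pre1, H1 = H1,
                                  M2 = M2, pre2 = pre2))
      } else {
        l1 <- sage_pool_fwd(X0, gd$nbrs, p$pool_Wp1, p$pool_b1, p$comb_W1)
        l2 <- sage_pool_fwd(l1$out, gd$nbrs, p$pool_Wp2, p$pool_b2, p$comb_W2)
        list(H = l2$out, cache = list(l1 = l1, l2 = l2))
      }
    })
}

encoder_bwd <- function(dH, fwd, p, cfg, gd, X0, grads) {
  switch(cfg$encoder,
    aergcn = {
      use_ep <- cfg$ablation != "no_ep"
      c2 <- fwd$cache$l2; c1 <- fwd$cache$l1
      b2 <- rgcn_bwd(dH, c2, c1$out, gd$arcs, gd$invc,
                     p$W0_2, fwd$cache$Wr2, ER = fwd$cache$ER2,
                     use_edge = use_ep)
      grads$W0_2 <- b2$dW0
      if (use_ep)
        grads$P2 <- cbind(crossprod(b2$dEL, X0), crossprod(b2$dER, X0))
      grads <- train_relation_weights_bwd(grads, b2$dWr, p, "l2", cfg)
      b1 <- rgcn_bwd(b2$dH, c1, X0, gd$arcs, gd$invc,
                     p$W0_1, fwd$cache$Wr1, ER = fwd$cache$ER1,
                     use_edge = use_ep)
      grads$W0_1 <- b1$dW0
      if (use_ep)
        grads$P1 <- cbind(crossprod(b1$dEL, X0), crossprod(b1$dER, X0))
      train_relation_weights_bwd(grads, b1$dWr, p, "l1", cfg)
    },
    gcn = {
      cc <- fwd$cache
      dpre2 <- dH * (cc$pre2 > 0)
      grads$gcn_W2 <- crossprod(cc$AH2, dpre2)
      dH1 <- gd$Ahat %*% (dpre2 %*% t(p$gcn_W2))  # Ahat symmetric
      dpre1 <- dH1 * (cc$pre1 > 0)
      grads$gcn_W1 <- crossprod(cc$AH1, dpre1)
      grads
    },
    gat = {
      cc <- fwd$cache
      g2 <- gat_bwd(dH, cc$l2, cc$l1$out, gd$gat_arcs, p, "gat2",
                    cfg$gat_heads)
      grads <- modifyList(grads, g2$grads)
      g1 <- gat_bwd(g2$dH, cc$l1, X0, gd$gat_arcs, p, "gat1",
                    cfg$gat_heads)
      modifyList(grads, g1$grads)
    },
    sage = {
      cc <- fwd$cache
      if (cfg$sage_aggregator == "mean") {
        dpre2 <- dH * (cc$pre2 > 0)
        grads$sage_W2 <- crossprod(cc$M2, dpre2)
        dH1 <- crossprod(gd$Anorm, dpre2 %*% t(p$sage_W2))
        dpre1 <- dH1 * (cc$pre1 > 0)
        grads$sage_W1 <- crossprod(cc$M1, dpre1)
        grads
      } else {
        b2 <- sage_pool_bwd(dH, cc$l2, cc$l1$out, gd$nbrs,
                            p$pool_Wp2, p$pool_b2, p$comb_W2)
        grads$pool_Wp2 <- b2$dWp; grads$pool_b2 <- b2$db
        grads$comb_W2 <- b2$dWc
        b1 <- sage_pool_bwd(b2$dH, cc$l1, X0, gd$nbrs,
                            p$pool_Wp1, p$pool_b1, p$comb_W1)
        grads$pool_Wp1 <- b1$dWp; grads$pool_b1 <- b1$db
        grads$comb_W1 <- b1$dWc
        grads
      }
    })
}

# ---- full model forward / backward ----------------------------------------

# query: list(qi, qj, wq) with wq the q x 2k edge attributes (NULL if
# no_ep), plus optional `blocks`: a list of index vectors partitioning the
# query edges; self-attention runs within each block (bounding its
# quadratic cost and, with reshuffled blocks during training, varying the
# context each latent attends over). Default: one block = the whole batch.
model_fwd <- function(p, cfg, gd, X0, query) {
  enc <- encoder_fwd(p, cfg, gd, X0)
  H <- enc$H
  S <- H[query$qi, , drop = FALSE] + H[query$qj, , drop = FALSE]
  Zpre <- tcrossprod(S, p$U1)
  if (cfg$ablation != "no_ep") {
    k0 <- ncol(X0)
    # query-edge attribute term, factorized over the two endpoint halves
    Zpre <- Zpre +
      X0[query$qi, , drop = FALSE] %*% t(p$U2[, seq_len(k0), drop = FALSE]) +
      X0[query$qj, , drop = FALSE] %*% t(p$U2[, k0 + seq_len(k0), drop = FALSE])
  }
  Z <- relu(Zpre)
  if (cfg$encoder == "aergcn" && cfg$ablation != "no_at") {
    blocks <- query$blocks %||% list(seq_len(nrow(Z)))
    at <- vector("list", length(blocks))
    ln <- vector("list", length(blocks))
    Zn <- Z
    for (b in seq_along(blocks)) {
      idx <- blocks[[b]]
      at[[b]] <- attn_fwd(Z[idx, , drop = FALSE], p$Wq, p$Wk, p$Wv, p$Wo,
                          cfg$n_heads)
      ln[[b]] <- ln_fwd(Z[idx, , drop = FALSE] + at[[b]]$out,
                        p$ln_gamma, p$ln_beta, cfg$eps)
      Zn[idx, ] <- ln[[b]]$out
    }
  } else {
    blocks <- NULL; at <- NULL; ln <- NULL; Zn <- Z
  }
  logits <- sweep(tcrossprod(Zn, p$Wc), 2L, p$bc, `+`)
  dimnames(logits) <- NULL
  list(logits = logits,
       cache = list(enc = enc, S = S, Zpre = Zpre, Z = Z, at = at,
                    ln = ln, Zn = Zn, blocks = blocks))
}

model_bwd <- function(dlogits, fwd, p, cfg, gd, X0, query) {
  cc <- fwd$cache
  grads <- list()
  grads$Wc <- crossprod(dlogits, cc$Zn)
  grads$bc <- colSums(dlogits)
  dZn <- dlogits %*% p$Wc
  if (cfg$encoder == "aergcn" && cfg$ablation != "no_at") {
    d <- ncol(dZn)
    grads$ln_gamma <- numeric(d); grads$ln_beta <- numeric(d)
    grads$Wq <- matrix(0, d, d); grads$Wk <- matrix(0, d, d)
    grads$Wo <- matrix(0, d, d)
    if (!is.null(p$Wv)) grads$Wv <- matrix(0, d, d)
    dZ <- matrix(0, nrow(dZn), d)
    for (b in seq_along(cc$blocks)) {
      idx <- cc$blocks[[b]]
      Zb <- cc$Z[idx, , drop = FALSE]
      lb <- ln_bwd(dZn[idx, , drop = FALSE], cc$ln[[b]], p$ln_gamma)
      grads$ln_gamma <- grads$ln_gamma + lb$dgamma
      grads$ln_beta <- grads$ln_beta + lb$dbeta
      ab <- attn_bwd(lb$dX, cc$at[[b]], Zb, p$Wq, p$Wk, p$Wv, p$Wo,
                     cfg$n_heads)
      grads$Wq <- grads$Wq + ab$dWq; grads$Wk <- grads$Wk + ab$dWk
      grads$Wo <- grads$Wo + ab$dWo
      if (!is.null(ab$dWv)) grads$Wv <- grads$Wv + ab$dWv
      dZ[idx, ] <- lb$dX + ab$dZ  # residual + attention path
    }
  } else {
    dZ <- dZn
  }
  dZpre <- dZ * (cc$Zpre > 0)
  grads$U1 <- crossprod(dZpre, cc$S)
  if (cfg$ablation != "no_ep")
    grads$U2 <- cbind(crossprod(dZpre, X0[query$qi, , drop = FALSE]),
                      crossprod(dZpre, X0[query$qj, , drop = FALSE]))
  dS <- dZpre %*% p$U1
  n <- nrow(X0)
  dH <- rowsum_full(dS, query$qi, n) + rowsum_full(dS, query$qj, n)
  encoder_bwd(dH, cc$enc, p, cfg, gd, X0, grads)
}

#' Per-edge class logits
#'
#' Runs the full scoring pipeline for a set of query drug pairs: two
#' encoder layers over the model's graph, recomputation of each query
#' edge's latent by fusing its two endpoint states with the edge's
#' attribute, refinement of the batch's latent sequence by multi-head
#' self-attention with a residual connection and layer normalization, and
#' a final linear score per risk class. Ablation flags set at
#' [model_config()] bypass the attention block (`no_at`) or the
#' edge-attribute terms (`no_ep`).
#'
#' @param model A [build_model()] or [train_model()] result.
#' @param query_edges Two-column matrix of drug-id pairs (character) or
#'   node indices (integer).
#' @return `nrow(query_edges) x R` matrix of class logits.
#' @export
edge_scores <- function(model, query_edges) {
  q <- resolve_query(model, query_edges)
  q$blocks <- make_blocks(length(q$qi), model$config$attn_block)
  model_fwd(model$params, model$config, model$gd, model$features, q)$logits
}

# Partition 1..m into consecutive blocks of at most `size` (shuffled first
# when `perm` is given).
make_blocks <- function(m, size, perm = NULL) {
  idx <- perm %||% seq_len(m)
  if (m <= size) return(list(idx))
  unname(split(idx, ceiling(seq_along(idx) / size)))
}

#' Per-edge class probabilities
#'
#' @param object A `ddirisk_model`.
#' @param query_edges As in [edge_scores()].
#' @param ... Unused.
#' @return Matrix of softmax class probabilities (rows sum to 1).
#' @export
predict.ddirisk_model <- function(object, query_edges, ...) {
  softmax_rows(edge_scores(object, query_edges))
}

resolve_query <- function(model, query_edges) {
  if (is.character(query_edges))
    query_edges <- matrix(query_edges, ncol = 2L)
  if (is.data.frame(query_edges))
    query_edges <- as.matrix(query_edges[, 1:2])
  if (is.character(query_edges[1L])) {
    qi <- match(query_edges[, 1L], model$nodes)
    qj <- match(query_edges[, 2L], model$nodes)
    stop_if_not(!anyNA(qi) && !anyNA(qj), "query references unknown drug_id")
  } else {
    qi <- as.integer(query_edges[, 1L]); qj <- as.integer(query_edges[, 2L])
    stop_if_not(all(c(qi, qj) >= 1L & c(qi, qj) <= length(model$nodes)),
                "query node index out of range")
  }
  list(qi = qi, qj = qj)
}
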