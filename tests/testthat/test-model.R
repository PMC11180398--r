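# End-to-end scoring pipeline and its gradients.

test_that("zeroed classifier weights give uniform class probabilities", {
  net <- tiny_net()
  g <- build_hetero_graph(net$events, net$drugs, 4L)
  X <- with_seed_test(1, matrix(rnorm(12 * 5), 12, 5))
  model <- build_model(g, X, model_config(4L, hidden = 8L, n_heads = 2L),
                       seed = 2L)
  model$params$Wc[] <- 0
  model$params$bc[] <- 0
  probs <- predict(model, cbind(net$events$drug_a, net$events$drug_b)[1:6, ])
  expect_equal(probs, matrix(0.25, 6, 4), tolerance = 1e-12)
})

test_that("the no_at flag is exactly the pipeline with attention bypassed", {
  net <- tiny_net()
  g <- build_hetero_graph(net$events, net$drugs, 4L)
  X <- with_seed_test(3, matrix(rnorm(12 * 5), 12, 5))
  q <- cbind(net$events$drug_a, net$events$drug_b)[1:7, ]
  m_abl <- build_model(g, X, model_config(4L, hidden = 8L, n_heads = 2L,
                                          ablation = "no_at"), seed = 4L)
  # same seed, full config: overwrite with identity attention by hand
  m_full <- build_model(g, X, model_config(4L, hidden = 8L, n_heads = 2L),
                        seed = 4L)
  for (nm in names(m_abl$params)) m_full$params[[nm]] <- m_abl$params[[nm]]
  s_abl <- edge_scores(m_abl, q)
  qq <- ddirisk:::resolve_query(m_full, q)
  fwd <- ddirisk:::model_fwd(m_full$params, m_abl$config, m_full$gd,
                             m_full$features, qq)
  expect_equal(s_abl, fwd$logits, tolerance = 1e-12)
  expect_error(model_config(4L, ablation = "no_such"), "arg")
})

test_that("edge scores match a dense end-to-end re-implementation", {
  net <- tiny_net(seed = 6L, n = 6L)
  g <- build_hetero_graph(net$events, net$drugs, 4L)
  X <- with_seed_test(5, matrix(rnorm(6 * 3), 6, 3))
  rownames(X) <- g$nodes
  cfg <- model_config(4L, hidden = 8L, n_heads = 2L)
  model <- build_model(g, X, cfg, seed = 7L)
  q <- cbind(net$events$drug_a, net$events$drug_b)
  logits <- edge_scores(model, q)

  # independent dense path: exported layer ops + loop oracles
  p <- model$params
  k0 <- ncol(X)
  Wr1 <- materialize_relation_weights(
    relation_weight_factors("basis", bases = p$l1_bases,
                            coefficients = p$l1_coef))
  Wr2 <- materialize_relation_weights(
    relation_weight_factors("basis", bases = p$l2_bases,
                            coefficients = p$l2_coef))
  H1 <- dense_rgcn_oracle(g, X, X, p$W0_1, Wr1, p$P1,
                          activation = function(x) pmax(x, 0))
  H2 <- dense_rgcn_oracle(g, H1, X, p$W0_2, Wr2, p$P2,
                          activation = function(x) pmax(x, 0))
  qi <- match(q[, 1], g$nodes); qj <- match(q[, 2], g$nodes)
  Z <- t(sapply(seq_along(qi), function(e) {
    pmax(p$U1 %*% (H2[qi[e], ] + H2[qj[e], ]) +
           p$U2 %*% c(X[qi[e], ], X[qj[e], ]), 0)
  }))
  O <- dense_attention_oracle(Z, p$Wq, p$Wk, p$Wo, cfg$n_heads)
  Zn <- layer_norm(Z + O, list(gamma = p$ln_gamma, beta = p$ln_beta,
                               eps = cfg$eps))
  oracle <- sweep(Zn %*% t(p$Wc), 2, p$bc, `+`)
  expect_equal(logits, oracle, tolerance = 1e-8)
})

test_that("analytic gradients agree with finite differences", {
  net <- tiny_net()
  g <- build_hetero_graph(net$events, net$drugs, 4L)
  X <- with_seed_test(8, matrix(rnorm(12 * 5), 12, 5))
  q_edges <- cbind(net$events$drug_a, net$events$drug_b)[1:8, ]
  labels <- net$events$label[1:8]
  configs <- list(
    model_config(4L, "aergcn", hidden = 8L, n_heads = 2L),
    model_config(4L, "aergcn", hidden = 8L, n_heads = 2L, ablation = "no_ep"),
    model_config(4L, "gcn", hidden = 8L),
    model_config(4L, "gat", hidden = 8L, gat_heads = 2L),
    model_config(4L, "sage", hidden = 8L, sage_aggregator = "pooling"))
  for (cfg in configs) {
    model <- build_model(g, X, cfg, seed = 9L)
    q <- ddirisk:::resolve_query(model, q_edges)
    p <- model$params
    lossfn <- function(pp) {
      f <- ddirisk:::model_fwd(pp, cfg, model$gd, model$features, q)
      ddirisk:::ce_from_logits(f$logits, labels)$loss
    }
    fwd <- ddirisk:::model_fwd(p, cfg, model$gd, model$features, q)
    ce <- ddirisk:::ce_from_logits(fwd$logits, labels)
    gr <- ddirisk:::model_bwd(ce$dlogits, fwd, p, cfg, model$gd,
                              model$features, q)
    eps <- 1e-6
    for (nm in names(gr)) {
      pick <- function(v) with_seed_test(17, sample(length(v), min(3, length(v))))
      target <- if (is.list(p[[nm]]) && !is.matrix(p[[nm]])) {
        list(nm = nm, b = 1L, idx = pick(p[[nm]][[1L]]))
      } else list(nm = nm, b = NA, idx = pick(p[[nm]]))
      for (i in target$idx) {
        p2 <- p
        if (is.na(target$b)) {
          p2[[nm]][i] <- p2[[nm]][i] + eps; up <- lossfn(p2)
          p2[[nm]][i] <- p2[[nm]][i] - 2 * eps; dn <- lossfn(p2)
          gv <- gr[[nm]][i]
        } else {
          p2[[nm]][[1L]][i] <- p2[[nm]][[1L]][i] + eps; up <- lossfn(p2)
          p2[[nm]][[1L]][i] <- p2[[nm]][[1L]][i] - 2 * eps; dn <- lossfn(p2)
          gv <- gr[[nm]][[1L]][i]
        }
        num <- (up - dn) / (2 * eps)
        expect_lt(abs(num - gv) / max(1e-6, abs(num) + abs(gv)), 1e-4)
      }
    }
  }
})

test_that("checkpoints round-trip parameters and manifest", {
  net <- tiny_net()
  g <- build_hetero_graph(net$events, net$drugs, 4L)
  X <- with_seed_test(10, matrix(rnorm(12 * 5), 12, 5))
  model <- build_model(g, X, model_config(4L, hidden = 8L, n_heads = 2L),
                       seed = 11L)
  f <- withr::local_tempfile(fileext = ".json")
  save_checkpoint(model, f)
  back <- load_checkpoint(f)
  expect_equal(back$manifest$encoder, "aergcn")
  expect_equal(back$manifest$ablation, "none")
  expect_equal(back$seed, 11L)
  expect_equal(back$params$W0_1, model$params$W0_1, tolerance = 1e-12)
  expect_equal(back$params$l1_bases[[2]], model$params$l1_bases[[2]],
               tolerance = 1e-12)
  expect_equal(back$params$bc, model$params$bc)
})
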