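test_that("layer normalization matches hand arithmetic and edge cases", {
  p <- layer_norm_params(4L)
  x <- matrix(c(1, 2, 3, 4), 1)
  expect_equal(layer_norm(x, p),
               matrix((c(1, 2, 3, 4) - 2.5) / sqrt(1.25 + 1e-5), 1),
               tolerance = 1e-12)
  # constant vector: numerator vanishes
  expect_equal(layer_norm(matrix(7, 1, 4), p), matrix(0, 1, 4))
  # zero gain: output is the bias everywhere
  p0 <- layer_norm_params(4L); p0$gamma <- rep(0, 4); p0$beta <- rep(5, 4)
  expect_equal(layer_norm(x, p0), matrix(5, 1, 4))
  # unit-gain output has mean ~0, population variance ~1
  X <- with_seed_test(1, matrix(rnorm(40), 10, 4))
  out <- layer_norm(X, p)
  expect_equal(rowMeans(out), rep(0, 10), tolerance = 1e-10)
  expect_equal(apply(out, 1, function(v) mean((v - mean(v))^2)),
               rep(1, 10), tolerance = 1e-4)
  expect_error(layer_norm_params(4L, eps = 0), "eps")
})

test_that("multi-head attention matches a per-head loop oracle", {
  set.seed(2)
  Z <- matrix(rnorm(5 * 8), 5, 8)
  for (learned in c(FALSE, TRUE)) {
    p <- attention_params(8L, n_heads = 2L, learned_value = learned, seed = 3L)
    out <- multi_head_attention(Z, p)
    oracle <- dense_attention_oracle(Z, p$Wq, p$Wk, p$Wo, 2L, p$Wv)
    expect_equal(unclass(out), oracle, tolerance = 1e-10, ignore_attr = TRUE)
    A <- attr(out, "attention")
    for (h in seq_along(A)) expect_equal(rowSums(A[[h]]), rep(1, 5))
  }
})

test_that("attention softmax behaves on singleton and constant-key inputs", {
  p <- attention_params(8L, n_heads = 2L, seed = 4L)
  z1 <- matrix(rnorm(8), 1, 8)
  out1 <- multi_head_attention(z1, p)
  # singleton softmax weight is exactly 1: output = value path projected
  expect_equal(unclass(out1), z1 %*% p$Wo, ignore_attr = TRUE)
  # identical rows give uniform weights 1/L
  zc <- matrix(rep(rnorm(8), 4), 4, 8, byrow = TRUE)
  A <- attr(multi_head_attention(zc, p), "attention")
  for (h in seq_along(A))
    expect_equal(A[[h]], matrix(0.25, 4, 4), tolerance = 1e-12)
  expect_error(attention_params(9L, n_heads = 2L), "divisible")
})

test_that("edge messages fuse source state with projected edge attributes", {
  set.seed(5)
  H <- matrix(rnorm(12), 4, 3)
  W_r <- matrix(rnorm(6), 2, 3)
  P <- matrix(rnorm(3 * 4), 3, 4)
  w_e <- rnorm(4)
  m <- edge_message(H, c(2L, 3L), w_e, W_r, P)
  expect_equal(m, as.numeric(W_r %*% (H[2, ] + P %*% w_e)), tolerance = 1e-12)
  # zero states and features give a zero message (bias-free linearity)
  expect_equal(edge_message(matrix(0, 4, 3), c(1L, 2L), rep(0, 4), W_r, P),
               rep(0, 2))
  # identity weight, no edge term: message is the source state
  expect_equal(edge_message(H, c(4L, 1L), NULL, diag(3), use_edge = FALSE),
               H[4, ])
  expect_error(edge_message(H, c(1L, 2L), NULL, W_r, P), "required")
})

test_that("rgcn layer matches the dense neighbor-loop oracle", {
  g <- random_graph(8L, R = 3L, p = 0.5, seed = 7L)
  set.seed(8)
  k <- 4L; d <- 5L
  H <- matrix(rnorm(8 * k), 8, k)
  W0 <- matrix(rnorm(d * k), d, k)
  Wr <- lapply(1:3, function(r) matrix(rnorm(d * k), d, k))
  P <- matrix(rnorm(k * 2 * k), k, 2 * k)
  fac <- relation_weight_factors("full", weights = Wr, self_weight = W0)
  wfeat <- lapply(g$relations, function(a) assemble_edge_features(H, a))
  out <- rgcn_layer_forward(g, H, wfeat, fac, activation = "relu",
                            edge_projection = P)
  oracle <- dense_rgcn_oracle(g, H, H, W0, Wr, P, activation = function(x) pmax(x, 0))
  expect_equal(out, oracle, tolerance = 1e-10)
  # without edge features
  out2 <- rgcn_layer_forward(g, H, NULL, fac, activation = "identity")
  oracle2 <- dense_rgcn_oracle(g, H, H, W0, Wr, NULL)
  expect_equal(out2, oracle2, tolerance = 1e-10)
})

test_that("edgeless graphs reduce to the self-connection term", {
  ids <- c("A", "B", "C")
  g <- build_hetero_graph(data.frame(drug_a = character(),
                                     drug_b = character(),
                                     label = integer()), ids, 2L)
  H <- matrix(rnorm(6), 3, 2)
  W0 <- matrix(rnorm(4), 2, 2)
  fac <- relation_weight_factors(
    "full", weights = list(matrix(0, 2, 2), matrix(0, 2, 2)),
    self_weight = W0)
  expect_equal(rgcn_layer_forward(g, H, NULL, fac, activation = "identity"),
               H %*% t(W0), tolerance = 1e-12)
})

test_that("one undirected edge with c = 1 matches the two-line computation", {
  g <- build_hetero_graph(data.frame(drug_a = "A", drug_b = "B", label = 0L),
                          c("A", "B"), 1L)
  H <- rbind(c(1, 2), c(3, -1))
  W0 <- diag(2); W1 <- matrix(c(0, 1, 1, 0), 2, 2)
  fac <- relation_weight_factors("full", weights = list(W1),
                                 self_weight = W0)
  out <- rgcn_layer_forward(g, H, NULL, fac, activation = "identity",
                            normalizer = "none")
  expect_equal(out[1, ], H[1, ] + as.numeric(W1 %*% H[2, ]))
  expect_equal(out[2, ], H[2, ] + as.numeric(W1 %*% H[1, ]))
})

test_that("mean normalization makes duplicated neighborhoods idempotent", {
  # duplicating every edge of a relation leaves mean-normalized output
  # unchanged: 2 arcs / c = 2 equals 1 arc / c = 1
  ev <- data.frame(drug_a = c("A", "A"), drug_b = c("B", "C"),
                   label = c(0L, 0L))
  g1 <- build_hetero_graph(ev, c("A", "B", "C"), 1L)
  g2 <- g1
  g2$relations[[1]] <- rbind(g2$relations[[1]], g2$relations[[1]])
  H <- with_seed_test(9, matrix(rnorm(9), 3, 3))
  fac <- relation_weight_factors(
    "full", weights = list(with_seed_test(10, matrix(rnorm(9), 3, 3))),
    self_weight = diag(3))
  expect_equal(rgcn_layer_forward(g1, H, NULL, fac),
               rgcn_layer_forward(g2, H, NULL, fac), tolerance = 1e-12)
})

test_that("rgcn output is permutation-equivariant", {
  g <- random_graph(7L, R = 2L, p = 0.5, seed = 11L)
  set.seed(12)
  H <- matrix(rnorm(7 * 3), 7, 3)
  fac <- relation_weight_factors(
    "full", weights = lapply(1:2, function(r) matrix(rnorm(9), 3, 3)),
    self_weight = matrix(rnorm(9), 3, 3))
  out <- rgcn_layer_forward(g, H, NULL, fac)
  perm <- with_seed_test(13, sample(7))
  gp <- g
  gp$relations <- lapply(g$relations, function(a)
    cbind(match(a[, 1L], perm), match(a[, 2L], perm)))
  # node i of g becomes node match(i, perm) of gp
  Hp <- H[perm, ]
  outp <- rgcn_layer_forward(gp, Hp, NULL, fac)
  expect_equal(outp, out[perm, ], tolerance = 1e-10)
})
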