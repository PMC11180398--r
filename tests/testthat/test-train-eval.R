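test_that("cross-entropy has its closed forms and matches a hand sum", {
  onehot <- diag(4)[c(1, 3, 2, 4), ]
  expect_equal(cross_entropy_loss(onehot, c(0L, 2L, 1L, 3L)), 0)
  unif <- matrix(0.25, 5, 4)
  expect_equal(cross_entropy_loss(unif, c(0L, 1L, 2L, 3L, 0L)), log(4),
               tolerance = 1e-12)
  probs <- with_seed_test(1, {
    x <- matrix(rexp(9), 3, 3); x / rowSums(x)
  })
  y <- c(2L, 0L, 1L)
  hand <- -(log(probs[1, 3]) + log(probs[2, 1]) + log(probs[3, 2])) / 3
  expect_equal(cross_entropy_loss(probs, y), hand, tolerance = 1e-12)
  # zero probability at truth: clamped, finite
  z <- rbind(c(1, 0, 0))
  expect_true(is.finite(cross_entropy_loss(z, 1L)))
  expect_error(cross_entropy_loss(probs * 2, y), "sum to 1")
})

test_that("task splits on a complete graph match analytic counts", {
  ids <- sprintf("D%02d", 1:10)
  pairs <- t(combn(ids, 2))
  events <- data.frame(drug_a = pairs[, 1], drug_b = pairs[, 2], label = 0L)
  spec <- make_task_splits(events, novel_fraction = 0.2, seed = 3L,
                           drug_ids = ids)
  expect_length(spec$novel_drugs, 2L)
  expect_equal(nrow(spec$task1_edges), choose(8, 2))  # 28
  expect_equal(nrow(spec$task2_edges), 2 * 8)         # 16
  expect_equal(nrow(spec$task3_edges), choose(2, 2))  # 1
  # determinism
  spec2 <- make_task_splits(events, 0.2, 3L, drug_ids = ids)
  expect_identical(spec, spec2)
  # one novel drug: task2 edges equal its degree, task3 empty
  spec1 <- make_task_splits(events, novel_fraction = 0.05, seed = 4L,
                            drug_ids = ids)
  expect_length(spec1$novel_drugs, 1L)
  expect_equal(nrow(spec1$task2_edges), 9L)
  expect_equal(nrow(spec1$task3_edges), 0L)
})

test_that("task splits never leak novel endpoints into training", {
  net <- memo("split_net", generate_network(
    synthetic_config(n_drugs = 40L, edge_density = 0.2, seed = 8L)))
  for (s in 1:100) {
    spec <- make_task_splits(net$events, 0.25, seed = s,
                             drug_ids = net$drugs$drug_id)
    expect_length(intersect(spec$confirmed_drugs, spec$novel_drugs), 0L)
    expect_setequal(c(spec$confirmed_drugs, spec$novel_drugs),
                    net$drugs$drug_id)
    train_ends <- c(spec$task1_edges$drug_a, spec$task1_edges$drug_b)
    expect_length(intersect(train_ends, spec$novel_drugs), 0L)
    n_ends <- function(d) (d$drug_a %in% spec$novel_drugs) +
      (d$drug_b %in% spec$novel_drugs)
    expect_true(all(n_ends(spec$task2_edges) == 1L))
    expect_true(all(n_ends(spec$task3_edges) == 2L))
    expect_equal(nrow(spec$task1_edges) + nrow(spec$task2_edges) +
                   nrow(spec$task3_edges), nrow(net$events))
  }
})

test_that("metrics reproduce hand-counted confusion arithmetic", {
  # fixed 4-class scenario: probabilities put all mass on the prediction
  y <- c(0L, 0L, 0L, 1L, 1L, 2L, 2L, 3L)
  pred <- c(0L, 0L, 1L, 1L, 2L, 2L, 2L, 0L)
  probs <- diag(4)[pred + 1L, ]
  probs <- (probs + 0.001) / rowSums(probs + 0.001)
  rep <- compute_metrics(y, probs)
  # per-class counts by hand: class 0: TP 2 FP 1 FN 1; class 1: TP 1 FP 1
  # FN 1; class 2: TP 2 FP 1 FN 0; class 3: TP 0 FP 0 FN 1
  expect_equal(rep$per_class$TP, c(2, 1, 2, 0))
  expect_equal(rep$per_class$FP, c(1, 1, 1, 0))
  expect_equal(rep$per_class$FN, c(1, 1, 0, 1))
  expect_equal(rep$per_class$TP + rep$per_class$TN + rep$per_class$FP +
                 rep$per_class$FN, rep(8, 4))
  expect_equal(rep$acc, 5 / 8)
  p_c <- c(2 / 3, 1 / 2, 2 / 3, 0)
  r_c <- c(2 / 3, 1 / 2, 1, 0)
  f_c <- ifelse(p_c + r_c > 0, 2 * p_c * r_c / (p_c + r_c), 0)
  expect_equal(rep$precision, mean(p_c))
  expect_equal(rep$recall, mean(r_c))
  expect_equal(rep$f1_macro, mean(f_c))
})

test_that("micro recall equals accuracy for argmax predictions", {
  probs <- with_seed_test(2, {
    x <- matrix(rexp(200 * 4), 200, 4); x / rowSums(x)
  })
  y <- with_seed_test(3, sample(0:3, 200, replace = TRUE))
  rep <- compute_metrics(y, probs)
  expect_equal(rep$recall_micro, rep$acc)
  # perfect predictions: everything 1
  perfect <- diag(4)[y + 1L, ]
  perfect <- (perfect + 1e-9) / rowSums(perfect + 1e-9)
  rp <- compute_metrics(y, perfect)
  expect_equal(rp$acc, 1)
  expect_equal(rp$f1_macro, 1)
  expect_equal(rp$auc_micro, 1)
  expect_equal(rp$aupr_micro, 1)
  # constant majority prediction on balanced labels
  yb <- rep(0:3, each = 10)
  const <- matrix(c(0.97, 0.01, 0.01, 0.01), 40, 4, byrow = TRUE)
  expect_equal(compute_metrics(yb, const)$acc, 0.25)
  # single observed class: rank metrics undefined, not zero
  expect_warning(r1 <- compute_metrics(rep(1L, 5), matrix(0.25, 5, 4)),
                 "absent")
  expect_true(is.na(r1$auc_micro))
})

test_that("rank metrics agree with an independent implementation", {
  skip_if_not_installed("pROC")
  y <- with_seed_test(4, rbinom(80, 1, 0.3))
  s <- with_seed_test(5, rnorm(80))
  expect_equal(ddirisk:::auc_binary(y, s),
               as.numeric(pROC::auc(pROC::roc(y, s, quiet = TRUE))),
               tolerance = 1e-10)
})

test_that("training overfits a toy graph and is seed-reproducible", {
  net <- memo("train_net", generate_network(
    synthetic_config(n_drugs = 20L, edge_density = 0.25, n_clusters = 4L,
                     seed = 12L)))
  ids <- sort(net$drugs$drug_id)
  X <- with_seed_test(6, matrix(rnorm(20 * 8), 20, 8))
  tc <- train_config(epochs = 200L, seed = 13L, hidden = 16L, n_heads = 2L,
                     n_relations = 4L)
  m1 <- train_model(net$events, ids, X, tc)
  expect_lt(tail(m1$history$loss, 1), 0.05)  # capacity sanity
  m2 <- train_model(net$events, ids, X, tc)
  expect_identical(m1$history, m2$history)   # bitwise seeding contract
  expect_identical(m1$params, m2$params)
  # loss history is recorded per epoch
  expect_equal(nrow(m1$history), 200L)
})

test_that("five-fold partitions are disjoint, exhaustive, and summarized", {
  net <- memo("train_net", generate_network(
    synthetic_config(n_drugs = 20L, edge_density = 0.25, n_clusters = 4L,
                     seed = 12L)))
  fold <- ddirisk:::stratified_folds(net$events$label, 5L, 3L)
  expect_setequal(unique(fold), 1:5)
  expect_equal(length(fold), nrow(net$events))
  # each class spread as evenly as possible
  for (cl in unique(net$events$label)) {
    counts <- table(fold[net$events$label == cl])
    expect_lte(diff(range(counts)), 1)
  }
  cv <- five_fold_cv(net$events, net$drugs,
                     train_config(epochs = 30L, seed = 14L, hidden = 16L,
                                  n_heads = 2L, feature_dim = 8L,
                                  n_relations = 4L),
                     task = 1L, fp_config = fingerprint_config(2L, 256L))
  expect_length(cv$per_fold, 5L)
  accs <- vapply(cv$per_fold, `[[`, 0, "acc")
  expect_equal(cv$summary$mean[cv$summary$metric == "acc"], mean(accs))
  expect_equal(cv$summary$sd[cv$summary$metric == "acc"], sd(accs))
})

test_that("cold-start folds run and shared-model evaluation matches them", {
  net <- memo("split_net", generate_network(
    synthetic_config(n_drugs = 40L, edge_density = 0.2, seed = 8L)))
  tc <- train_config(epochs = 20L, seed = 15L, hidden = 16L,
                     n_heads = 2L, feature_dim = 8L, n_relations = 4L)
  fp <- fingerprint_config(2L, 256L)
  cv <- five_fold_cv(net$events, net$drugs, tc, task = 2L,
                     novel_fraction = 0.2, fp_config = fp)
  expect_gte(length(cv$per_fold), 4L)
  expect_true(all(is.finite(vapply(cv$per_fold, `[[`, 0, "acc"))))
  # one trained model per repeat serves both cold-start tasks, with
  # results identical to the per-task protocol
  # tiny novel-novel folds trigger the (intended) absent-class warnings
  cold <- suppressWarnings(
    cold_start_eval(net$events, net$drugs, tc, tasks = c(2L, 3L),
                    novel_fraction = 0.2, fp_config = fp))
  expect_equal(vapply(cold$task2$per_fold, `[[`, 0, "acc"),
               vapply(cv$per_fold, `[[`, 0, "acc"), tolerance = 1e-12)
  expect_equal(cold$task3$task, 3L)
})

test_that("ablation harness pairs variants over identical folds", {
  net <- memo("train_net", generate_network(
    synthetic_config(n_drugs = 20L, edge_density = 0.25, n_clusters = 4L,
                     seed = 12L)))
  res <- run_ablation(net$events, net$drugs, variants = c("none", "no_at"),
                      tconfig = train_config(epochs = 20L, seed = 16L,
                                             hidden = 16L, n_heads = 2L,
                                             feature_dim = 8L,
                                             n_relations = 4L),
                      tasks = 1L, fp_config = fingerprint_config(2L, 256L))
  expect_equal(nrow(res$table), 2L)
  expect_setequal(res$table$variant, c("none", "no_at"))
  # paired design: same per-fold test sizes across variants
  n1 <- vapply(res$runs$task1_none$per_fold, function(r) sum(r$per_class$TP +
    r$per_class$FN), 0)
  n2 <- vapply(res$runs$task1_no_at$per_fold, function(r) sum(r$per_class$TP +
    r$per_class$FN), 0)
  expect_equal(n1, n2)
  expect_error(run_ablation(net$events, net$drugs, variants = "no_xx"),
               "unknown ablation")
})
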