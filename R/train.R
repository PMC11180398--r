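#' Cross-entropy loss
#'
#' `J = -(1/m) * sum_i log(p[i, y_i])` over predicted class probabilities.
#' Probabilities at the true label are clamped below by `eps` so a
#' confident wrong prediction yields a large finite loss rather than `Inf`.
#'
#' @param probs `m x R` matrix of class probabilities (rows sum to 1).
#' @param labels Integer vector of true classes in `[0, R)`.
#' @param eps Clamping floor for probabilities.
#' @return Nonnegative scalar loss.
#' @export
cross_entropy_loss <- function(probs, labels, eps = 1e-12) {
  probs <- as.matrix(probs)
  m <- nrow(probs)
  stop_if_not(length(labels) == m, "one label per probability row")
  stop_if_not(all(labels >= 0L & labels < ncol(probs)),
              "labels must be in [0, n_classes)")
  stop_if_not(max(abs(rowSums(probs) - 1)) < 1e-6, "rows must sum to 1")
  p <- probs[cbind(seq_len(m), labels + 1L)]
  -mean(log(pmax(p, eps)))
}

# Loss and gradient directly from logits (numerically stable path used in
# training): J = -(1/m) sum log softmax(logits)[i, y_i].
ce_from_logits <- function(logits, labels) {
  m <- nrow(logits)
  lp <- log_softmax_rows(logits)
  loss <- -mean(lp[cbind(seq_len(m), labels + 1L)])
  P <- exp(lp)
  P[cbind(seq_len(m), labels + 1L)] <- P[cbind(seq_len(m), labels + 1L)] - 1
  list(loss = loss, dlogits = P / m)
}

#' Training configuration
#'
#' @param epochs Maximum number of full-batch epochs.
#' @param learning_rate AdamW step size.
#' @param weight_decay AdamW decoupled weight decay.
#' @param seed RNG seed covering initialization (and any sampling).
#' @param ablation Passed through to [model_config()].
#' @param feature_dim Reduced node-feature dimension `k`.
#' @param validation_fraction Fraction of training edges held out
#'   (stratified) for early stopping; the returned parameters are those
#'   with the best validation loss, and held-out edges are excluded from
#'   the message-passing graph so their relation labels cannot leak.
#'   Validation is skipped (all edges train to `epochs`) when the held-out
#'   set would have fewer than 20 edges, or when the fraction is 0.
#' @param patience Epochs without validation improvement before stopping.
#' @param val_every Evaluate the held-out set every this many epochs (the
#'   full-graph validation forward pass is a sizable fraction of a
#'   training step, and selection at a 5-epoch grain loses nothing
#'   measurable).
#' @param hidden,n_heads,encoder,... Further [model_config()] arguments.
#' @return A `train_config` list.
#' @export
train_config <- function(epochs = 300L, learning_rate = 1e-3,
                         weight_decay = 1e-2, seed = 1L,
                         ablation = c("none", "no_fp", "no_at", "no_ep"),
                         feature_dim = 64L, validation_fraction = 0.1,
                         patience = 50L, val_every = 5L, hidden = 64L,
                         n_heads = 2L, encoder = "aergcn", ...) {
  stop_if_not(epochs >= 1L, "epochs must be >= 1")
  stop_if_not(learning_rate > 0, "learning_rate must be > 0")
  stop_if_not(validation_fraction >= 0 && validation_fraction < 1,
              "validation_fraction must be in [0, 1)")
  structure(list(epochs = as.integer(epochs), learning_rate = learning_rate,
                 weight_decay = weight_decay, seed = as.integer(seed),
                 ablation = match.arg(ablation),
                 feature_dim = as.integer(feature_dim),
                 validation_fraction = validation_fraction,
                 patience = as.integer(patience),
                 val_every = as.integer(val_every),
                 hidden = as.integer(hidden), n_heads = as.integer(n_heads),
                 encoder = encoder, extra = list(...)),
            class = "train_config")
}

# ---- AdamW ----------------------------------------------------------------

adamw_init <- function(params) {
  zero_like <- function(p) {
    if (is.list(p)) lapply(p, zero_like)
    else { z <- p; z[] <- 0; attributes(z) <- attributes(p); z }
  }
  list(m = lapply(params, zero_like), v = lapply(params, zero_like), t = 0L)
}

# One decoupled-weight-decay Adam step on the flat (possibly nested)
# parameter list. Bias vectors and layer-norm parameters are exempt from
# weight decay, the usual convention.
adamw_step <- function(params, grads, state, lr, wd,
                       beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  t <- state$t
  no_decay <- c("bc", "ln_gamma", "ln_beta", "pool_b1", "pool_b2")
  upd <- function(p, g, m, v, decay) {
    if (is.list(p)) {
      for (i in seq_along(p)) {
        r <- upd(p[[i]], g[[i]], m[[i]], v[[i]], decay)
        p[[i]] <- r$p; m[[i]] <- r$m; v[[i]] <- r$v
      }
      return(list(p = p, m = m, v = v))
    }
    m <- beta1 * m + (1 - beta1) * g
    v <- beta2 * v + (1 - beta2) * g^2
    mh <- m / (1 - beta1^t)
    vh <- v / (1 - beta2^t)
    p <- p - lr * (mh / (sqrt(vh) + eps)) - if (decay) lr * wd * p else 0
    list(p = p, m = m, v = v)
  }
  for (nm in names(grads)) {
    r <- upd(params[[nm]], grads[[nm]], state$m[[nm]], state$v[[nm]],
             !(nm %in% no_decay))
    a <- attributes(params[[nm]])
    params[[nm]] <- r$p
    if (!is.null(a$mask)) attr(params[[nm]], "mask") <- a$mask
    state$m[[nm]] <- r$m; state$v[[nm]] <- r$v
  }
  list(params = params, state = state)
}

# ---- training loop --------------------------------------------------------

#' Train an edge classifier on confirmed (training) edges
#'
#' Full-batch AdamW on the cross-entropy loss over the training edges only.
#' Message passing runs on the training graph, which contains no held-out
#' or novel-endpoint edge, so cold-start evaluation is leak-free by
#' construction. All randomness is governed by `tconfig$seed`.
#'
#' @param train_events Data frame of training events (`drug_a`, `drug_b`,
#'   `label`); these define both the supervision set and the
#'   message-passing graph.
#' @param drug_ids Character vector of all drug ids (the node space; novel
#'   drugs are present as isolated nodes).
#' @param features `|V| x k` node attribute matrix, rows ordered by sorted
#'   drug id.
#' @param tconfig A [train_config()].
#' @return The trained `ddirisk_model` with a `history` data frame
#'   (`epoch`, `loss`) attached.
#' @export
train_model <- function(train_events, drug_ids, features, tconfig) {
  stop_if_not(nrow(train_events) > 0L, "training edge set is empty")
  R <- max(train_events$label) + 1L
  R <- max(R, tconfig$extra$n_relations %||% R)
  # early-stopping split: supervision and message passing use train_sub
  # only, so a held-out edge's relation label never reaches the model
  n_val <- floor((tconfig$validation_fraction %||% 0) * nrow(train_events))
  if (n_val >= 20L) {
    vfold <- stratified_folds(train_events$label,
                              max(2L, round(1 / tconfig$validation_fraction)),
                              derive_seed(tconfig$seed, 77L))
    val_events <- train_events[vfold == 1L, , drop = FALSE]
    sub_events <- train_events[vfold != 1L, , drop = FALSE]
  } else {
    val_events <- NULL
    sub_events <- train_events
  }
  graph <- build_hetero_graph(sub_events, drug_ids, R)
  cfg <- do.call(model_config, c(
    list(n_relations = R, encoder = tconfig$encoder, hidden = tconfig$hidden,
         n_heads = tconfig$n_heads, ablation = tconfig$ablation),
    tconfig$extra[setdiff(names(tconfig$extra), "n_relations")]))
  model <- build_model(graph, features, cfg, seed = tconfig$seed)
  q <- resolve_query(model, cbind(sub_events$drug_a, sub_events$drug_b))
  labels <- sub_events$label
  qv <- if (!is.null(val_events)) {
    v <- resolve_query(model, cbind(val_events$drug_a, val_events$drug_b))
    v$blocks <- make_blocks(nrow(val_events), cfg$attn_block)
    v
  }
  state <- adamw_init(model$params)
  history <- data.frame(epoch = seq_len(tconfig$epochs), loss = NA_real_,
                        val_loss = NA_real_)
  p <- model$params
  best <- list(acc = -Inf, loss = Inf, params = p, epoch = 0L)
  best_loss <- Inf; best_loss_epoch <- 0L
  m_edges <- length(q$qi)
  for (epoch in seq_len(tconfig$epochs)) {
    if (cfg$encoder == "aergcn" && cfg$ablation != "no_at")
      q$blocks <- with_seed(derive_seed(tconfig$seed, epoch),
                            make_blocks(m_edges, cfg$attn_block,
                                        sample.int(m_edges)))
    fwd <- model_fwd(p, cfg, model$gd, model$features, q)
    ce <- ce_from_logits(fwd$logits, labels)
    if (!is.finite(ce$loss))
      stop(sprintf("non-finite loss at epoch %d (loss=%g); try a smaller learning rate",
                   epoch, ce$loss), call. = FALSE)
    history$loss[epoch] <- ce$loss
    grads <- model_bwd(ce$dlogits, fwd, p, cfg, model$gd, model$features, q)
    st <- adamw_step(p, grads, state, tconfig$learning_rate,
                     tconfig$weight_decay)
    p <- st$params; state <- st$state
    if (!is.null(qv) &&
        (epoch %% (tconfig$val_every %||% 5L) == 0L ||
           epoch == tconfig$epochs)) {
      vlog <- model_fwd(p, cfg, model$gd, model$features, qv)$logits
      vce <- ce_from_logits(vlog, val_events$label)
      history$val_loss[epoch] <- vce$loss
      # select on validation accuracy (ties broken by loss): robust to the
      # calibration noise the stochastic attention blocks introduce
      vacc <- mean(max.col(vlog) - 1L == val_events$label)
      if (vacc > best$acc || (vacc == best$acc && vce$loss < best$loss))
        best <- list(acc = vacc, loss = vce$loss, params = p, epoch = epoch)
      # the stopping clock runs on validation loss, which keeps falling as
      # long as genuine structure is still being learned; only meaningful
      # improvements (> 1e-4) reset it
      if (vce$loss < best_loss - 1e-4) {
        best_loss <- vce$loss; best_loss_epoch <- epoch
      }
      if (epoch - max(best$epoch, best_loss_epoch) >=
            (tconfig$patience %||% 50L)) break
    }
  }
  model$params <- if (is.null(qv)) p else best$params
  model$history <- history[!is.na(history$loss), , drop = FALSE]
  model$best_epoch <- if (is.null(qv)) nrow(model$history) else best$epoch
  model
}

#' Save / load a model checkpoint
#'
#' Serializes every parameter tensor alongside a JSON manifest (encoder,
#' dimensions, heads, ablation flags, seed) into a single plain-text JSON
#' archive.
#'
#' @param model A trained `ddirisk_model`.
#' @param path Output file.
#' @export
save_checkpoint <- function(model, path) {
  strip <- function(p) {
    if (is.list(p)) lapply(p, strip)
    else if (is.matrix(p)) list(dim = dim(p), data = as.numeric(p))
    else list(dim = length(p), data = as.numeric(p))
  }
  jsonlite::write_json(
    list(manifest = model$config[!vapply(model$config, is.null, TRUE)],
         nodes = model$nodes, seed = model$seed,
         params = lapply(model$params, strip)),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname save_checkpoint
#' @return `load_checkpoint()` returns the manifest and rebuilt parameter
#'   list (`graph` tensors must be rebuilt from data before scoring).
#' @export
load_checkpoint <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE,
                             simplifyDataFrame = FALSE)
  rebuild <- function(p) {
    if (is.list(p) && !is.null(p$dim)) {
      if (length(p$dim) == 2L) matrix(as.numeric(p$data), p$dim[1L], p$dim[2L])
      else as.numeric(p$data)
    } else lapply(p, rebuild)
  }
  list(manifest = raw$manifest, nodes = raw$nodes, seed = raw$seed,
       params = lapply(raw$params, rebuild))
}
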