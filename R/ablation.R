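#' Ablation harness
#'
#' Runs five-fold cross-validation for each requested model variant under
#' identical splits and seeds (a paired comparison: every variant sees
#' exactly the same train/test edges), for each requested task. Variants:
#' `none` (full model), `no_fp` (one-hot node features in place of
#' fingerprints: topology information only), `no_at` (attention block
#' bypassed), `no_ep` (edge-attribute propagation dropped).
#'
#' @param events Data frame of events.
#' @param drugs Drug table.
#' @param variants Subset of `c("none", "no_fp", "no_at", "no_ep")`.
#' @param tconfig Base [train_config()] (its `ablation` field is
#'   overridden per variant).
#' @param tasks Integer vector of tasks to run.
#' @param ... Passed to [five_fold_cv()].
#' @return An `ablation_result`: `table` (one row per task and variant
#'   with mean/sd per metric) and `runs` (the underlying `cv_result`s).
#' @export
run_ablation <- function(events, drugs, variants = c("none", "no_fp", "no_at", "no_ep"),
                         tconfig = train_config(), tasks = 1L, ...) {
  stop_if_not(all(variants %in% c("none", "no_fp", "no_at", "no_ep")),
              "unknown ablation variant")
  dots <- list(...)
  # featurize once; build_model substitutes one-hot rows under no_fp anyway
  fz <- featurize_drugs(drugs[order(drugs$drug_id), , drop = FALSE],
                        k = tconfig$feature_dim,
                        fp_config = dots$fp_config %||% fingerprint_config()
                        )$features
  runs <- list()
  rows <- list()
  for (task in tasks) {
    for (v in variants) {
      tc <- tconfig
      tc$ablation <- v
      cv <- five_fold_cv(events, drugs, tc, task = task, features = fz, ...)
      runs[[sprintf("task%d_%s", task, v)]] <- cv
      s <- cv$summary
      row <- as.data.frame(as.list(stats::setNames(s$mean, s$metric)))
      row_sd <- as.data.frame(as.list(stats::setNames(s$sd, paste0(s$metric, "_sd"))))
      rows[[length(rows) + 1L]] <- cbind(data.frame(task = task, variant = v),
                                         row, row_sd)
    }
  }
  structure(list(table = do.call(rbind, rows), runs = runs),
            class = "ablation_result")
}

#' @export
print.ablation_result <- function(x, ...) {
  print(x$table[, c("task", "variant", "acc", "f1_macro", "auc_micro")],
        digits = 4)
  invisible(x)
}
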