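#' Multi-class classification metrics
#'
#' Pooled accuracy from argmax correctness, macro-averaged precision,
#' recall and F1 over the per-class one-vs-rest confusion counts, plus
#' micro-averaged AUPR and AUC over the flattened binarized label matrix
#' (each element of the label indicator matrix treated as one binary
#' label). Micro-mode recall is also reported; for single-label argmax
#' predictions it equals accuracy. Macro averages skip (with a warning)
#' classes absent from the truth vector, whose recall is undefined; a
#' class never predicted contributes precision 0. With a single observed
#' class, AUC/AUPR are undefined and reported as `NA` rather than 0.
#'
#' @param y_true Integer vector of true classes in `[0, R)`.
#' @param probs `m x R` matrix of predicted class probabilities.
#' @return A `metrics_report` list: `acc`, `precision`, `recall` (macro),
#'   `recall_micro`, `f1_macro`, `auc_micro`, `aupr_micro`, and
#'   `per_class` (data frame of TP/TN/FP/FN per binarized class).
#' @export
compute_metrics <- function(y_true, probs) {
  probs <- as.matrix(probs)
  m <- nrow(probs); R <- ncol(probs)
  stop_if_not(length(y_true) == m, "one true label per row")
  stop_if_not(max(abs(rowSums(probs) - 1)) < 1e-6,
              "probability rows must sum to 1")
  pred <- max.col(probs, ties.method = "first") - 1L
  classes <- 0:(R - 1L)
  per <- data.frame(class = classes,
                    TP = vapply(classes, function(c) sum(pred == c & y_true == c), 0),
                    FP = vapply(classes, function(c) sum(pred == c & y_true != c), 0),
                    FN = vapply(classes, function(c) sum(pred != c & y_true == c), 0))
  per$TN <- m - per$TP - per$FP - per$FN
  present <- classes %in% y_true
  if (!all(present))
    warning(sprintf("class(es) %s absent from truth; excluded from macro averages",
                    paste(classes[!present], collapse = ", ")), call. = FALSE)
  prec_c <- ifelse(per$TP + per$FP > 0, per$TP / (per$TP + per$FP), 0)
  rec_c <- per$TP / (per$TP + per$FN)            # defined where present
  f1_c <- ifelse(prec_c + rec_c > 0, 2 * prec_c * rec_c / (prec_c + rec_c), 0)
  macro <- function(v) mean(v[present])
  acc <- mean(pred == y_true)
  # micro recall pools counts over classes: sum TP / sum (TP + FN)
  recall_micro <- sum(per$TP) / sum(per$TP + per$FN)
  Yb <- matrix(0L, m, R)
  Yb[cbind(seq_len(m), y_true + 1L)] <- 1L
  two_sided <- length(unique(y_true)) > 1L
  structure(list(acc = acc,
                 precision = macro(prec_c),
                 recall = macro(rec_c),
                 recall_micro = recall_micro,
                 f1_macro = macro(f1_c),
                 auc_micro = if (two_sided) auc_binary(as.vector(Yb), as.vector(probs)) else NA_real_,
                 aupr_micro = if (two_sided) average_precision(as.vector(Yb), as.vector(probs)) else NA_real_,
                 per_class = per),
            class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf("acc %.4f | precision %.4f | recall %.4f | F1 %.4f | AUC %.4f | AUPR %.4f\n",
              x$acc, x$precision, x$recall, x$f1_macro, x$auc_micro,
              x$aupr_micro))
  invisible(x)
}

# Rank-based (Mann-Whitney) binary AUC with midrank tie handling.
auc_binary <- function(y, score) {
  pos <- y == 1
  n1 <- sum(pos); n0 <- sum(!pos)
  if (n1 == 0L || n0 == 0L) return(NA_real_)
  r <- rank(score, ties.method = "average")
  (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

# Average precision: sum over positive-hit ranks of precision@k times the
# recall increment (step-wise integral under the precision-recall curve).
average_precision <- function(y, score) {
  n1 <- sum(y == 1)
  if (n1 == 0L || n1 == length(y)) return(NA_real_)
  ord <- order(score, decreasing = TRUE)
  ys <- y[ord]
  cum_tp <- cumsum(ys)
  prec <- cum_tp / seq_along(ys)
  sum(prec[ys == 1]) / n1
}
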