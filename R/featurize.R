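#' Fit a PCA projection
#'
#' Principal components of the rows of `X`: columns of the projection are
#' the top-`k` eigenvectors of the `1/m`-scaled covariance of mean-centered
#' `X` (computed by singular value decomposition), with the matching
#' eigenvalues as explained variances. Eigenvector sign is fixed by forcing
#' the largest-magnitude entry of each column positive, so the model is
#' reproducible across linear-algebra backends.
#'
#' @param X Numeric `m x n` matrix (`m >= 2` rows/observations).
#' @param k Number of components, `1 <= k <= min(m, n)`.
#' @return A `pca_model`: `mean` (length `n`), `projection` (`n x k`,
#'   orthonormal columns), `explained_variance` (length `k`, nonincreasing).
#' @export
fit_pca <- function(X, k) {
  X <- as.matrix(X)
  m <- nrow(X); n <- ncol(X)
  stop_if_not(m >= 2L, "PCA needs at least 2 rows")
  stop_if_not(k >= 1L && k <= min(m, n), "k must be in 1..min(m, n)")
  mu <- colMeans(X)
  Xc <- sweep(X, 2L, mu)
  total_var <- sum(Xc^2) / m
  if (total_var <= .Machine$double.eps)
    stop("X has zero variance; PCA is undefined", call. = FALSE)
  sv <- svd(Xc, nu = 0L, nv = k)
  P <- sv$v[, seq_len(k), drop = FALSE]
  # sign convention: largest-magnitude entry of each column positive
  for (j in seq_len(k)) {
    piv <- which.max(abs(P[, j]))
    if (P[piv, j] < 0) P[, j] <- -P[, j]
  }
  ev <- (sv$d[seq_len(k)]^2) / m
  structure(list(mean = mu, projection = P, explained_variance = ev,
                 total_variance = total_var),
            class = "pca_model")
}

#' Project data through a fitted PCA model
#'
#' Computes `(X - mean) %*% projection`.
#'
#' @param model A [fit_pca()] result.
#' @param X Numeric matrix whose column count matches `length(model$mean)`.
#' @return `m x k` score matrix (rownames preserved).
#' @export
apply_pca <- function(model, X) {
  stop_if_not(inherits(model, "pca_model"), "model must be a pca_model")
  X <- as.matrix(X)
  stop_if_not(ncol(X) == length(model$mean),
              sprintf("X has %d columns; model expects %d",
                      ncol(X), length(model$mean)))
  out <- sweep(X, 2L, model$mean) %*% model$projection
  rownames(out) <- rownames(X)
  out
}

#' Cumulative explained-variance sweep over PCA dimensions
#'
#' Utility behind choosing the reduced feature dimension: fits once at
#' `max(ks)` and reports the cumulative explained-variance fraction at each
#' requested `k` (monotone nondecreasing, plateauing at the data's rank).
#'
#' @param X Numeric matrix.
#' @param ks Integer vector of candidate dimensions.
#' @return Data frame with columns `k` and `cum_var_fraction`.
#' @export
pca_k_sweep <- function(X, ks) {
  ks <- sort(unique(as.integer(ks)))
  model <- fit_pca(X, max(ks))
  cum <- cumsum(model$explained_variance) / model$total_variance
  data.frame(k = ks, cum_var_fraction = cum[ks])
}

#' Assemble edge attributes by endpoint concatenation
#'
#' The attribute of arc `(i, j)` is the concatenation of the feature
#' vectors of its two endpoint drugs, in arc order: the undirected edge is
#' represented by both orderings on its two double-entry arcs.
#'
#' @param node_features `|V| x k` numeric matrix.
#' @param edges Two-column integer matrix of (src, dst) index pairs.
#' @return `nrow(edges) x 2k` matrix of per-arc attribute vectors.
#' @export
assemble_edge_features <- function(node_features, edges) {
  edges <- matrix(as.integer(edges), ncol = 2L)
  if (nrow(edges) == 0L)
    return(matrix(0, 0L, 2L * ncol(node_features)))
  stop_if_not(all(edges >= 1L & edges <= nrow(node_features)),
              "edge endpoint index out of range")
  cbind(node_features[edges[, 1L], , drop = FALSE],
        node_features[edges[, 2L], , drop = FALSE])
}

#' Featurize drugs: fingerprints then PCA
#'
#' The full node-attribute pipeline: Morgan fingerprints of every drug,
#' converted to 0/1 numeric vectors, then reduced to `k` dimensions by PCA.
#' PCA is fit on all drugs by default (features derive only from chemistry,
#' not labels, so this leaks no label information); pass the row indices of
#' training drugs in `fit_rows` for a strict protocol that fits the
#' projection on training drugs only.
#'
#' @param drugs Data frame with `drug_id` and `smiles`.
#' @param k Reduced feature dimension (default 300; capped at the PCA rank
#'   bound `min(n_drugs, n_bits)`).
#' @param fp_config A [fingerprint_config()].
#' @param fit_rows Optional integer vector of rows used to fit the PCA.
#' @return List with `features` (`n_drugs x k`, rownames = drug_id),
#'   `pca` (the fitted model), `fingerprints`, and `config`.
#' @export
featurize_drugs <- function(drugs, k = 300L,
                            fp_config = fingerprint_config(),
                            fit_rows = NULL) {
  fps <- drug_fingerprints(drugs, fp_config)
  k <- min(as.integer(k), nrow(fps), ncol(fps))
  fit_on <- if (is.null(fit_rows)) fps else fps[fit_rows, , drop = FALSE]
  pca <- fit_pca(fit_on, k)
  feats <- apply_pca(pca, fps)
  list(features = feats, pca = pca, fingerprints = fps,
       config = list(radius = fp_config$radius, n_bits = fp_config$n_bits,
                     k = k))
}

#' Persist / load a featurized node matrix
#'
#' Writes the dense numeric feature table (rows keyed by `drug_id`) as TSV
#' with a JSON sidecar recording the fingerprint configuration and `k`.
#'
#' @param featurized A [featurize_drugs()] result.
#' @param path Output TSV path; the sidecar is written to `<path>.json`.
#' @export
save_node_features <- function(featurized, path) {
  tab <- data.frame(drug_id = rownames(featurized$features),
                    featurized$features, check.names = FALSE)
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(featurized$config, paste0(path, ".json"),
                       auto_unbox = TRUE)
  invisible(path)
}

#' @rdname save_node_features
#' @return `load_node_features()` returns a list with `features` and
#'   `config`.
#' @export
load_node_features <- function(path) {
  tab <- utils::read.table(path, sep = "\t", header = TRUE,
                           check.names = FALSE)
  feats <- as.matrix(tab[, -1L, drop = FALSE])
  dimnames(feats) <- list(tab[[1L]], NULL)
  config <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  list(features = feats, config = config)
}
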