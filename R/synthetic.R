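# Synthetic multi-relational DDI network generator with planted cluster
# structure, so label recoverability is known by construction.

#' Synthetic network configuration
#'
#' @param n_drugs Number of drug nodes.
#' @param n_relations Number of event classes `R`.
#' @param class_proportions Length-`R` simplex vector of class shares.
#' @param feature_label_coupling In `[0, 1]`: probability that an edge's
#'   label comes from the deterministic cluster-pair table (1 = labels a
#'   deterministic function of the endpoint feature clusters, 0 = labels
#'   independent of features).
#' @param n_clusters Number of latent drug clusters (each decorated with
#'   its own substructure motif; `n_clusters * (n_clusters + 1) / 2` must
#'   be at least `n_relations` so every class is reachable).
#' @param edge_density Fraction of all unordered drug pairs that carry an
#'   event, in `(0, 1]`.
#' @param seed RNG seed; identical config + seed gives identical output.
#' @return A `synthetic_config` list.
#' @export
synthetic_config <- function(n_drugs = 300L, n_relations = 4L,
                             class_proportions = rep(1 / n_relations, n_relations),
                             feature_label_coupling = 1.0, n_clusters = 8L,
                             edge_density = 0.1, seed = 1L) {
  stop_if_not(abs(sum(class_proportions) - 1) < 1e-8,
              "class_proportions must sum to 1")
  stop_if_not(length(class_proportions) == n_relations,
              "need one proportion per relation")
  stop_if_not(edge_density > 0 && edge_density <= 1,
              "edge_density must be in (0, 1]")
  stop_if_not(feature_label_coupling >= 0 && feature_label_coupling <= 1,
              "feature_label_coupling must be in [0, 1]")
  stop_if_not(n_clusters * (n_clusters + 1) / 2 >= n_relations,
              "too few cluster pairs to reach every class")
  structure(list(n_drugs = as.integer(n_drugs),
                 n_relations = as.integer(n_relations),
                 class_proportions = as.numeric(class_proportions),
                 feature_label_coupling = feature_label_coupling,
                 n_clusters = as.integer(n_clusters),
                 edge_density = edge_density, seed = as.integer(seed)),
            class = "synthetic_config")
}

#' Class-imbalance presets
#'
#' `ddinter4` mirrors the 4-level risk regime of a curated DDI severity
#' resource (unknown / minor / moderate / major shares of roughly 21.3%,
#' 4.9%, 58.6% and 15.2%, scaled to the synthetic size); `drugbank65` is a
#' 65-type long-tailed regime with power-law class shares.
#'
#' @param name `"ddinter4"` or `"drugbank65"`.
#' @param ... Overrides passed to [synthetic_config()].
#' @return A `synthetic_config`.
#' @export
imbalance_preset <- function(name = c("ddinter4", "drugbank65"), ...) {
  name <- match.arg(name)
  if (name == "ddinter4") {
    counts <- c(unknown = 47182, minor = 10861, moderate = 129472,
                major = 33617)
    args <- list(n_relations = 4L, class_proportions = as.numeric(counts / sum(counts)))
  } else {
    p <- (1:65)^-1.5
    args <- list(n_relations = 65L, class_proportions = p / sum(p),
                 n_clusters = 14L)
  }
  do.call(synthetic_config, utils::modifyList(args, list(...)))
}

# Base molecules (valid small-molecule SMILES, each ending in an atom that
# can accept one more single bond) and per-cluster substructure motifs
# (branch units that chain-extend validly and imprint cluster-specific
# circular substructures on the fingerprint).
smiles_bank <- function() c(
  "CCO", "CC(=O)O", "c1ccccc1", "CCN", "CC(C)C", "CCCCC", "C1CCCCC1",
  "c1ccncc1", "CC(=O)N", "COC", "CCS", "CC=C", "c1ccc2ccccc2c1",
  "CC(N)C(=O)O", "C1CCNCC1", "CCOCC", "CN(C)C", "c1ccsc1", "CC(C)(C)C",
  "C=CC", "CCCN", "OCCO", "CC(O)C", "c1ccc(cc1)O", "CCCCCCCC", "C1CCOC1",
  "CC1CCCCC1", "NCCO", "CSC", "CC(=O)C", "C#CC", "CCOC", "CCC(C)C",
  "COCCO", "CN", "CCc1ccccc1", "OC1CCCCC1", "CC(C)O", "CCCO", "NC(=O)C",
  "CCCC(=O)O", "CC(C)N", "COc1ccccc1", "CCSCC", "OCC(O)C", "CC=CC",
  "NCCCN", "CC(C)CO", "CCCCN", "CCCCO")

cluster_motifs <- function() c(
  "C(Cl)", "C(Br)", "C(F)", "C(O)", "C(N)", "C(=O)", "C(C#N)",
  "C(c1ccccc1)", "C(C(F)(F)F)", "C(OC)", "C(N(C)C)", "C(SC)",
  "C(CCl)", "C(ON)")

# Greedy proportion-respecting assignment of unordered cluster pairs to
# classes: pairs (weighted by their sampling probability under uniform
# cluster membership) fill the class with the largest remaining quota;
# one random pair is pre-assigned to each class so the map is surjective.
make_label_table <- function(n_clusters, proportions) {
  R <- length(proportions)
  pairs <- which(upper.tri(diag(n_clusters), diag = TRUE), arr.ind = TRUE)
  w <- ifelse(pairs[, 1L] == pairs[, 2L], 1, 2) / n_clusters^2
  ord <- sample(nrow(pairs))
  assign <- integer(nrow(pairs))
  quota <- proportions
  seed_pairs <- ord[seq_len(R)]
  assign[seed_pairs] <- sample(R)
  quota <- quota - tapply(w[seed_pairs], assign[seed_pairs], sum)[as.character(1:R)]
  for (t in ord[-seq_len(R)]) {
    k <- which.max(quota)
    assign[t] <- k
    quota[k] <- quota[k] - w[t]
  }
  tab <- matrix(NA_integer_, n_clusters, n_clusters)
  tab[pairs] <- assign - 1L
  tab[pairs[, c(2L, 1L), drop = FALSE]] <- assign - 1L
  tab
}

#' Generate a synthetic DDI network
#'
#' Drugs are assigned latent clusters; each drug's SMILES is a valid base
#' molecule decorated with its cluster's substructure motif (so
#' fingerprints correlate with clusters). A seeded sample of unordered
#' pairs becomes the event list: with probability
#' `feature_label_coupling` an edge takes the deterministic label of its
#' endpoint cluster pair, otherwise an independent draw from
#' `class_proportions`. At coupling 1 the Bayes-optimal classifier on the
#' cluster pair is perfect by construction; at coupling 0 no feature-based
#' classifier can beat the majority-class rate in expectation.
#'
#' @param config A [synthetic_config()].
#' @return A `synthetic_network`: `drugs` (drug_id, smiles), `events`
#'   (drug_a, drug_b, label), `clusters` (named integer vector),
#'   `label_table` (cluster-pair to class matrix), `config`.
#' @export
generate_network <- function(config = synthetic_config()) {
  stop_if_not(inherits(config, "synthetic_config"),
              "config must be a synthetic_config")
  n <- config$n_drugs; cK <- config$n_clusters
  stop_if_not(cK <= length(cluster_motifs()),
              sprintf("at most %d clusters supported", length(cluster_motifs())))
  with_seed(config$seed, {
    ids <- sprintf(paste0("D%0", nchar(as.character(n)), "d"), seq_len(n))
    clusters <- sample.int(cK, n, replace = TRUE)
    names(clusters) <- ids
    bases <- sample(smiles_bank(), n, replace = TRUE)
    smiles <- paste0(bases, strrep(cluster_motifs()[clusters], 3L))
    tab <- make_label_table(cK, config$class_proportions)
    n_pairs <- (n * (n - 1L)) %/% 2L
    m <- max(1L, round(config$edge_density * n_pairs))
    stop_if_not(m <= n_pairs, "edge_density exceeds complete-graph capacity")
    pair_idx <- which(upper.tri(matrix(FALSE, n, n)), arr.ind = TRUE)
    sel <- pair_idx[sample.int(n_pairs, m), , drop = FALSE]
    planted <- tab[cbind(clusters[sel[, 1L]], clusters[sel[, 2L]])]
    use_planted <- stats::runif(m) < config$feature_label_coupling
    random_lab <- sample.int(config$n_relations, m, replace = TRUE,
                             prob = config$class_proportions) - 1L
    labels <- ifelse(use_planted, planted, random_lab)
    bad <- !is_valid_smiles(smiles)
    stop_if_not(!any(bad), "internal error: generator emitted invalid SMILES")
    structure(list(drugs = data.frame(drug_id = ids, smiles = smiles,
                                      stringsAsFactors = FALSE),
                   events = data.frame(drug_a = ids[sel[, 1L]],
                                       drug_b = ids[sel[, 2L]],
                                       label = as.integer(labels),
                                       stringsAsFactors = FALSE),
                   clusters = clusters, label_table = tab, config = config),
              class = "synthetic_network")
  })
}

#' @export
print.synthetic_network <- function(x, ...) {
  cat(sprintf("<synthetic_network> %d drugs, %d events, %d classes, coupling %.2f, %d clusters\n",
              nrow(x$drugs), nrow(x$events), x$config$n_relations,
              x$config$feature_label_coupling, x$config$n_clusters))
  invisible(x)
}

#' Write a synthetic network to disk
#'
#' Emits exactly the formats the loaders consume: a two-column `.smi` drug
#' table, a CSV edge list, and a ground-truth JSON (cluster assignment and
#' cluster-pair label table) for oracle checks.
#'
#' @param net A [generate_network()] result.
#' @param dir Output directory (created if missing).
#' @return The directory, invisibly.
#' @export
write_synthetic <- function(net, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  writeLines(paste(net$drugs$drug_id, net$drugs$smiles),
             file.path(dir, "drugs.smi"))
  utils::write.csv(net$events, file.path(dir, "events.csv"),
                   row.names = FALSE, quote = FALSE)
  jsonlite::write_json(list(clusters = as.list(net$clusters),
                            label_table = net$label_table,
                            config = unclass(net$config)),
                       file.path(dir, "truth.json"), auto_unbox = TRUE)
  invisible(dir)
}
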