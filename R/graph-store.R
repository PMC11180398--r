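#' Read a typed DDI edge list
#'
#' Reads a tab- or comma-separated file with columns `drug_a`, `drug_b`,
#' `label` (string or integer risk class) into a data frame of DDI events.
#' An optional header row is detected and skipped. Row order is preserved.
#'
#' @param path Path to a TSV/CSV edge-list file with at least three columns.
#' @param label_map Named integer vector (or list) mapping label strings to
#'   integer risk classes in `[0, R)`. Numeric label columns already inside
#'   the map's value range pass through unchanged when `label_map` is `NULL`.
#' @return A data frame with columns `drug_a`, `drug_b` (character) and
#'   `label` (integer), one row per event.
#' @examples
#' f <- tempfile(fileext = ".csv")
#' writeLines(c("D1,D2,Major", "D1,D3,Minor"), f)
#' read_edge_list(f, c(Minor = 1, Moderate = 2, Major = 3))
#' @export
read_edge_list <- function(path, label_map = NULL) {
  stop_if_not(file.exists(path), sprintf("edge list not found: %s", path))
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  stop_if_not(length(lines) > 0L, "edge list file is empty")
  sep <- if (grepl("\t", lines[[1L]])) "\t" else ","
  parts <- strsplit(lines, sep, fixed = TRUE)
  ncols <- lengths(parts)
  stop_if_not(all(ncols >= 3L), "every edge-list row needs >= 3 columns")
  tab <- do.call(rbind, lapply(parts, function(p) trimws(p[1:3])))
  # A header is a first row whose label cell is neither a mapped label
  # string nor an integer.
  first_lab <- tab[1L, 3L]
  is_header <- is.na(suppressWarnings(as.integer(first_lab))) &&
    (is.null(label_map) || !(first_lab %in% names(label_map)))
  if (is_header) tab <- tab[-1L, , drop = FALSE]
  stop_if_not(nrow(tab) > 0L, "edge list contains no data rows")
  lab_chr <- tab[, 3L]
  if (is.null(label_map)) {
    labels <- suppressWarnings(as.integer(lab_chr))
    bad <- which(is.na(labels))
    if (length(bad))
      stop(sprintf("row %d: label '%s' is not an integer and no label_map was given",
                   bad[1L], lab_chr[bad[1L]]), call. = FALSE)
  } else {
    label_map <- unlist(label_map)
    bad <- which(!(lab_chr %in% names(label_map)))
    if (length(bad))
      stop(sprintf("row %d: unknown label '%s'", bad[1L], lab_chr[bad[1L]]),
           call. = FALSE)
    labels <- as.integer(label_map[lab_chr])
  }
  events <- data.frame(drug_a = tab[, 1L], drug_b = tab[, 2L],
                       label = labels, stringsAsFactors = FALSE)
  validate_events(events)
  events
}

# Shared invariants for a set of DDI events: no self-pairs, each unordered
# pair at most once, nonnegative integer labels.
validate_events <- function(events) {
  self <- which(events$drug_a == events$drug_b)
  if (length(self))
    stop(sprintf("row %d: self-interaction %s-%s is not allowed",
                 self[1L], events$drug_a[self[1L]], events$drug_b[self[1L]]),
         call. = FALSE)
  key <- pair_key(events$drug_a, events$drug_b)
  dup <- which(duplicated(key))
  if (length(dup))
    stop(sprintf("duplicate unordered pair %s at row %d",
                 key[dup[1L]], dup[1L]), call. = FALSE)
  stop_if_not(all(events$label >= 0L), "labels must be >= 0")
  invisible(events)
}

pair_key <- function(a, b) {
  paste(pmin(a, b), pmax(a, b), sep = "\r")
}

#' Read a two-column drug/SMILES table
#'
#' Reads a `.smi`-style text file (`drug_id` and SMILES, whitespace- or
#' comma-separated). Records whose SMILES do not parse are dropped and
#' counted in the attached drop report, mirroring the common curation step
#' of removing drugs without usable structure descriptors.
#'
#' @param path Path to the drug table.
#' @return A data frame with columns `drug_id` and `smiles`, with attribute
#'   `drop_report`: a list with `n_dropped` and the dropped `drug_id`s.
#' @export
read_smiles_table <- function(path) {
  stop_if_not(file.exists(path), sprintf("drug table not found: %s", path))
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  stop_if_not(length(lines) > 0L, "drug table is empty")
  parts <- strsplit(trimws(lines), "[,[:space:]]+")
  stop_if_not(all(lengths(parts) >= 2L), "every drug row needs an id and a SMILES")
  ids <- vapply(parts, `[[`, "", 1L)
  smi <- vapply(parts, `[[`, "", 2L)
  dup <- which(duplicated(ids))
  if (length(dup))
    stop(sprintf("duplicate drug_id '%s'", ids[dup[1L]]), call. = FALSE)
  ok <- is_valid_smiles(smi)
  if (any(!ok))
    warning(sprintf("dropped %d drug(s) with unparseable SMILES: %s",
                    sum(!ok), paste(ids[!ok], collapse = ", ")), call. = FALSE)
  out <- data.frame(drug_id = ids[ok], smiles = smi[ok],
                    stringsAsFactors = FALSE)
  attr(out, "drop_report") <- list(n_dropped = sum(!ok),
                                   dropped_ids = ids[!ok])
  out
}

#' Build the heterogeneous DDI graph
#'
#' Treats drugs as nodes and risk classes as edge relations: each event with
#' label `r` becomes an undirected edge in relation `r`, stored as a
#' double-entry pair of directed arcs (message passing iterates directed
#' arcs). Nodes are ordered by lexicographic `drug_id` so the index space is
#' a deterministic function of the drug set, independent of file row order.
#' Isolated drugs are retained as nodes.
#'
#' @param events Data frame of events (`drug_a`, `drug_b`, `label`).
#' @param drugs Data frame with a `drug_id` column (a `drug_id` per event
#'   endpoint must be present); or a character vector of drug ids.
#' @param n_relations Number of relation types `R`; all labels must lie in
#'   `[0, n_relations)`.
#' @return An object of class `hetero_graph`: `nodes` (ordered drug ids),
#'   `relations` (list of `R` two-column arc matrices, symmetric-closed),
#'   `n_relations`, and optional `node_features` / `edge_features`.
#' @export
build_hetero_graph <- function(events, drugs, n_relations) {
  ids <- if (is.character(drugs)) drugs else drugs$drug_id
  stop_if_not(!anyDuplicated(ids), "drug ids must be unique")
  validate_events(events)
  stop_if_not(all(events$label < n_relations),
              "event labels must be < n_relations")
  unknown <- setdiff(c(events$drug_a, events$drug_b), ids)
  if (length(unknown))
    stop(sprintf("event references unknown drug_id '%s'", unknown[1L]),
         call. = FALSE)
  nodes <- sort(ids)
  ia <- match(events$drug_a, nodes)
  ib <- match(events$drug_b, nodes)
  relations <- vector("list", n_relations)
  for (r in seq_len(n_relations)) {
    sel <- events$label == (r - 1L)
    # double entry: arc (i,j) and (j,i) for every undirected edge
    relations[[r]] <- cbind(src = c(ia[sel], ib[sel]),
                            dst = c(ib[sel], ia[sel]))
  }
  structure(list(nodes = nodes, relations = relations,
                 n_relations = as.integer(n_relations),
                 node_features = NULL, edge_features = NULL),
            class = "hetero_graph")
}

#' @export
print.hetero_graph <- function(x, ...) {
  cat(sprintf("<hetero_graph> %d nodes, %d relations, %d undirected edges\n",
              length(x$nodes), x$n_relations, n_edges(x)))
  invisible(x)
}

# Number of undirected edges (double-entry arcs / 2), per relation or total.
n_edges <- function(graph, relation = NULL) {
  if (is.null(relation))
    sum(vapply(graph$relations, nrow, 0L)) %/% 2L
  else nrow(graph$relations[[relation]]) %/% 2L
}

#' Risk-rating matrix of a heterogeneous DDI graph
#'
#' Builds the symmetric drug-drug risk-rating matrix `Y`: `Y[i, j]` is the
#' integer risk class of the recorded pair, and a sentinel (default `NA`)
#' marks unrecorded pairs and the diagonal (no self-interactions).
#'
#' @param graph A `hetero_graph`.
#' @param sentinel Value used for unrecorded pairs and the diagonal.
#' @return An `n x n` matrix with `dimnames` equal to the node ids.
#' @export
risk_matrix <- function(graph, sentinel = NA_integer_) {
  n <- length(graph$nodes)
  Y <- matrix(sentinel, n, n, dimnames = list(graph$nodes, graph$nodes))
  for (r in seq_along(graph$relations)) {
    arcs <- graph$relations[[r]]
    if (nrow(arcs)) {
      filled <- Y[arcs]
      clash <- !is.na(filled) & filled != (r - 1L)
      if (any(clash))
        stop("relations overlap on an unordered pair", call. = FALSE)
      Y[arcs] <- r - 1L
    }
  }
  diag(Y) <- sentinel
  Y
}

# Inverse of risk_matrix: extract the unordered labeled pairs as events.
events_from_risk_matrix <- function(Y) {
  idx <- which(!is.na(Y) & upper.tri(Y), arr.ind = TRUE)
  data.frame(drug_a = rownames(Y)[idx[, 1L]],
             drug_b = colnames(Y)[idx[, 2L]],
             label = as.integer(Y[idx]),
             stringsAsFactors = FALSE)
}

# Untyped unordered edge index pairs of the whole graph (for baselines).
all_edges <- function(graph) {
  arcs <- do.call(rbind, graph$relations)
  if (is.null(arcs) || nrow(arcs) == 0L)
    return(matrix(integer(), 0L, 2L))
  und <- arcs[arcs[, 1L] < arcs[, 2L], , drop = FALSE]
  und[order(und[, 1L], und[, 2L]), , drop = FALSE]
}
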