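# Weighted protein networks: STRING-style edge lists, top-k pruning,
# symmetric normalization with self-loops, mini-batch neighborhoods.

#' Build a protein graph from an edge table
#'
#' @param nodes Ordered node identifiers.
#' @param edges data.frame with columns `from`, `to`, `weight` (one row per
#'   undirected edge, weights in (0, 1]).
#' @return A `protein_graph`: list with `nodes` and the sparse symmetric
#'   weighted `adjacency` (no self-loops stored).
#' @export
protein_graph <- function(nodes, edges) {
  i <- match(edges$from, nodes); j <- match(edges$to, nodes)
  stopifnot(!anyNA(i), !anyNA(j), all(edges$weight > 0), all(edges$weight <= 1))
  keep <- i != j
  i <- i[keep]; j <- j[keep]; w <- edges$weight[keep]
  adj <- Matrix::sparseMatrix(i = c(i, j), j = c(j, i), x = c(w, w),
                              dims = c(length(nodes), length(nodes)),
                              dimnames = list(nodes, nodes), use.last.ij = FALSE)
  # duplicate pairs: sparseMatrix sums duplicates, so rebuild with max
  key <- paste(pmin(i, j), pmax(i, j))
  if (anyDuplicated(key)) {
    mx <- tapply(w, key, max)
    ij <- do.call(rbind, strsplit(names(mx), " "))
    i <- as.integer(ij[, 1]); j <- as.integer(ij[, 2]); w <- as.numeric(mx)
    adj <- Matrix::sparseMatrix(i = c(i, j), j = c(j, i), x = c(w, w),
                                dims = c(length(nodes), length(nodes)),
                                dimnames = list(nodes, nodes))
  }
  structure(list(nodes = nodes, adjacency = adj), class = "protein_graph")
}

#' @export
print.protein_graph <- function(x, ...) {
  cat("protein_graph:", length(x$nodes), "nodes,",
      Matrix::nnzero(x$adjacency) / 2, "edges\n")
  invisible(x)
}

#' Load a STRING-style weighted edge list
#'
#' Lines hold `protein1 protein2 combined_score` (tab-separated, integer
#' scores on a 0-1000 scale). Weights are `score / score_scale` clipped to
#' (0, 1]; duplicate pairs keep the maximum weight; self-pairs, non-numeric
#' and non-positive scores are dropped (with a message count).
#'
#' @param path TSV path or character vector of lines.
#' @param score_scale Score divisor (default 1000, the STRING convention).
#' @param nodes Optional node universe; defaults to proteins seen in edges.
#' @return A `protein_graph`.
#' @export
load_string_edges <- function(path, score_scale = 1000, nodes = NULL) {
  lines <- if (length(path) == 1L && file.exists(path)) readLines(path, warn = FALSE) else path
  lines <- lines[nzchar(lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  ok <- vapply(fields, length, integer(1)) >= 3L
  fields <- fields[ok]
  from <- vapply(fields, `[[`, character(1), 1L)
  to <- vapply(fields, `[[`, character(1), 2L)
  score <- suppressWarnings(as.numeric(vapply(fields, `[[`, character(1), 3L)))
  bad <- is.na(score) | score <= 0
  n_dropped <- sum(!ok) + sum(bad) + sum(!bad & from == to)
  if (n_dropped > 0L) message(n_dropped, " edge line(s) dropped")
  keep <- !bad & from != to
  from <- from[keep]; to <- to[keep]
  w <- pmin(score[keep] / score_scale, 1)
  if (is.null(nodes)) nodes <- sort(unique(c(from, to)))
  protein_graph(nodes, data.frame(from = from, to = to, weight = w,
                                  stringsAsFactors = FALSE))
}

#' Keep only each node's heaviest edges
#'
#' An edge survives if it is among the `k` largest-weight edges of either
#' endpoint (union rule, preserving symmetry). Ties are broken by
#' lexicographic neighbour identifier.
#'
#' @param graph A `protein_graph`.
#' @param k Edges kept per node (>= 1).
#' @return The pruned `protein_graph` with original weights.
#' @export
top_k_prune <- function(graph, k) {
  stopifnot(k >= 1)
  adj <- graph$adjacency
  n <- length(graph$nodes)
  trip <- Matrix::summary(adj)  # both (i,j) and (j,i) present
  keep_key <- character(0)
  per_row <- split(seq_len(nrow(trip)), trip$i)
  for (rows in per_row) {
    w <- trip$x[rows]
    nb <- graph$nodes[trip$j[rows]]
    ord <- order(-w, nb)
    sel <- rows[ord[seq_len(min(k, length(rows)))]]
    keep_key <- c(keep_key, paste(pmin(trip$i[sel], trip$j[sel]),
                                  pmax(trip$i[sel], trip$j[sel])))
  }
  keep_key <- unique(keep_key)
  upper <- trip[trip$i < trip$j, , drop = FALSE]
  kept <- upper[paste(upper$i, upper$j) %in% keep_key, , drop = FALSE]
  protein_graph(graph$nodes,
                data.frame(from = graph$nodes[kept$i], to = graph$nodes[kept$j],
                           weight = kept$x, stringsAsFactors = FALSE))
}

#' Symmetrically normalized adjacency with unit self-loops
#'
#' Computes `D^{-1/2} (A + I) D^{-1/2}` where `D` is the degree matrix of
#' `A + I`. Isolated nodes reduce to a unit diagonal entry.
#'
#' @param graph A `protein_graph`.
#' @return A `normalized_adjacency`: list with `nodes` and sparse `matrix`.
#' @export
normalized_adjacency <- function(graph) {
  a_tilde <- graph$adjacency + Matrix::Diagonal(length(graph$nodes))
  deg <- Matrix::rowSums(a_tilde)
  d_inv_sqrt <- Matrix::Diagonal(x = 1 / sqrt(deg))
  mat <- d_inv_sqrt %*% a_tilde %*% d_inv_sqrt
  dimnames(mat) <- list(graph$nodes, graph$nodes)
  structure(list(nodes = graph$nodes, matrix = methods::as(mat, "CsparseMatrix")),
            class = "normalized_adjacency")
}

#' Extract the mini-batch neighborhood of a seed set
#'
#' Includes the seeds plus every node reachable within `hops` nonzero
#' entries of the normalized adjacency, and restricts the matrix to those
#' nodes without renormalizing — so a `hops`-layer forward pass on the
#' subgraph reproduces the full-graph values on the seed rows.
#'
#' @param normalized A `normalized_adjacency`.
#' @param seeds Seed node identifiers.
#' @param hops Number of message-passing layers the batch must support.
#' @return A `batch_subgraph`: list with `seeds`, `nodes` (included), sparse
#'   `matrix`, `seed_index` (rows of seeds in the local matrix) and
#'   `global_index` (positions of included nodes in the full node order).
#' @export
batch_neighborhood <- function(normalized, seeds, hops) {
  idx <- match(seeds, normalized$nodes)
  if (anyNA(idx)) stop("unknown seed identifier(s): ",
                       paste(seeds[is.na(idx)], collapse = ", "))
  frontier <- idx
  included <- idx
  if (hops > 0) {
    for (h in seq_len(hops)) {
      nb <- unique(Matrix::summary(normalized$matrix[frontier, , drop = FALSE])$j)
      frontier <- setdiff(nb, included)
      included <- union(included, nb)
      if (length(frontier) == 0L) break
    }
  }
  included <- sort(included)
  structure(
    list(seeds = seeds,
         nodes = normalized$nodes[included],
         matrix = normalized$matrix[included, included, drop = FALSE],
         seed_index = match(idx, included),
         global_index = included),
    class = "batch_subgraph"
  )
}

#' Write a protein graph as a STRING-style edge TSV
#' @param graph A `protein_graph`.
#' @param path Output file.
#' @param score_scale Multiplier back to integer scores (default 1000).
#' @export
write_string_edges <- function(graph, path, score_scale = 1000) {
  trip <- Matrix::summary(graph$adjacency)
  trip <- trip[trip$i < trip$j, , drop = FALSE]
  utils::write.table(
    data.frame(graph$nodes[trip$i], graph$nodes[trip$j],
               as.integer(round(trip$x * score_scale))),
    path, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
}
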