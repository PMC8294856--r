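# Formula-defined baselines: BLAST-KNN, Net-KNN and per-term logistic
# regression on InterPro signature features.

#' Read a BLAST outfmt-6-like homology table
#'
#' Columns: query, subject, bitscore, evalue, percent identity.
#'
#' @param path TSV path (no header).
#' @return data.frame with those columns.
#' @export
read_homology_tsv <- function(path) {
  df <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE,
                          col.names = c("query", "subject", "bitscore",
                                        "evalue", "pident"))
  df
}

#' BLAST-KNN: bit-score-weighted GO transfer from training homologs
#'
#' For query p_i with training-set homolog set Z_i (pairs passing the
#' e-value cutoff), the score for term GO_j is the bit-score-weighted
#' fraction of homologs annotated with it:
#' `S_B(p_i, GO_j) = sum_{k in Z_i} I(p_k, GO_j) B(p_i, p_k) /
#'   sum_{k in Z_i} B(p_i, p_k)`.
#' Queries without homologs get an all-zero row (coverage flag FALSE).
#'
#' @param queries Query protein identifiers.
#' @param homology data.frame (query, subject, bitscore, evalue).
#' @param train_table Propagated training `annotation_table`.
#' @param e_cutoff Maximum e-value for a pair to count (default 1e-3).
#' @return A `score_matrix` with a logical `covered` attribute per protein.
#' @export
blast_knn <- function(queries, homology, train_table, e_cutoff = 1e-3) {
  hom <- homology
  if (!is.null(hom$evalue)) hom <- hom[hom$evalue <= e_cutoff, , drop = FALSE]
  hom <- hom[hom$query %in% queries & hom$subject %in% train_table$proteins, ,
             drop = FALSE]
  # every training homolog in Z_i enters the denominator, annotated or not
  .neighbor_score(queries, hom$query, hom$subject, hom$bitscore, train_table,
                  restrict_annotated = FALSE)
}

#' Net-KNN: edge-weight-weighted GO transfer from network neighbours
#'
#' For query p_i in the network, the score for term GO_j is
#' `S_N(p_i, GO_j) = sum_k I(p_k, GO_j) w(p_i, p_k) / sum_k w(p_i, p_k)`,
#' with both sums over neighbours that carry at least one training
#' annotation in the target domain (a query whose neighbours are all
#' unannotated gets a zero row). The unpruned graph is used. A query absent
#' from the network copies the row of its highest-bit-score in-network
#' homolog when a homology table is supplied.
#'
#' @param queries Query protein identifiers.
#' @param graph A `protein_graph` (unpruned).
#' @param train_table Propagated training `annotation_table`.
#' @param homology Optional homology data.frame for off-network fallback.
#' @return A `score_matrix` with `coverage` strata.
#' @export
net_knn <- function(queries, graph, train_table, homology = NULL) {
  trip <- Matrix::summary(graph$adjacency)
  from <- graph$nodes[trip$i]; to <- graph$nodes[trip$j]

  in_graph <- queries[queries %in% graph$nodes]
  keep <- from %in% in_graph
  res_in <- .neighbor_score(in_graph, from[keep], to[keep], trip$x[keep],
                            train_table)

  out <- matrix(0, length(queries), length(train_table$terms))
  coverage <- rep("NONE", length(queries))
  hit <- queries %in% graph$nodes
  out[hit, ] <- res_in$scores[match(queries[hit], res_in$proteins), , drop = FALSE]
  coverage[hit] <- "STRI"
  if (!is.null(homology) && any(!hit)) {
    fb <- best_homolog(queries[!hit], homology, graph$nodes)
    has <- !is.na(fb)
    if (any(has)) {
      fb_rows <- .neighbor_score(unique(fb[has]),
                                 from[from %in% fb[has]],
                                 to[from %in% fb[has]],
                                 trip$x[from %in% fb[has]], train_table)
      out[which(!hit)[has], ] <-
        fb_rows$scores[match(fb[has], fb_rows$proteins), , drop = FALSE]
      coverage[which(!hit)[has]] <- "HOMO"
    }
  }
  score_matrix(queries, train_table$terms, out, coverage = coverage)
}

# shared weighted-vote kernel: for each query, scores = sum_k I * w / sum_k w
# over (query, neighbor, weight) triples; optionally restricted to
# neighbors carrying at least one training annotation in the domain.
.neighbor_score <- function(queries, q, nb, w, train_table,
                            restrict_annotated = TRUE) {
  if (restrict_annotated) {
    ann <- Matrix::rowSums(train_table$matrix) > 0
    annotated <- train_table$proteins[ann]
    keep <- nb %in% annotated
    q <- q[keep]; nb <- nb[keep]; w <- w[keep]
  }
  out <- matrix(0, length(queries), length(train_table$terms))
  covered <- rep(FALSE, length(queries))
  if (length(q) > 0L) {
    qi <- match(q, queries)
    ok <- !is.na(qi)
    qi <- qi[ok]; nb <- nb[ok]; w <- w[ok]
    # weight matrix Q x train, then (Q x train) %*% (train x K)
    wm <- Matrix::sparseMatrix(i = qi, j = match(nb, train_table$proteins),
                               x = w, dims = c(length(queries),
                                               length(train_table$proteins)))
    num <- as.matrix(wm %*% train_table$matrix)
    den <- Matrix::rowSums(wm)
    covered <- den > 0
    out[covered, ] <- num[covered, , drop = FALSE] / den[covered]
  }
  structure(score_matrix(queries, train_table$terms, out),
            covered = covered)
}

#' Train per-term L2-regularized logistic regression on signature features
#'
#' One independent ridge-penalized logistic fit per GO term on the binary
#' signature features. Terms with fewer than one positive or one negative
#' training protein get a constant model at the positive rate.
#'
#' @param features A `signature_matrix` covering the training proteins.
#' @param train_table Propagated training `annotation_table`.
#' @param regularization L2 penalty strength (default 1.0); translated to a
#'   glmnet lambda of `regularization / n`.
#' @return An `lr_model`: list with `weights` (m x K), `intercept` (K),
#'   `constant` (K, NA where a fit exists), `terms`, `vocabulary`.
#' @export
lr_train <- function(features, train_table, regularization = 1.0) {
  labeled <- intersect(train_table$proteins, features$proteins)
  stopifnot(length(labeled) > 0L)
  x <- features$matrix[match(labeled, features$proteins), , drop = FALSE]
  y <- train_table$matrix[match(labeled, train_table$proteins), , drop = FALSE]
  m <- ncol(x); K <- ncol(y); n <- nrow(x)
  weights <- matrix(0, m, K)
  intercept <- numeric(K)
  constant <- rep(NA_real_, K)
  lam <- regularization / n
  xfit <- if (m >= 2L) x else cbind(x, 0)  # glmnet needs >= 2 columns
  for (j in seq_len(K)) {
    yj <- as.numeric(y[, j])
    npos <- sum(yj)
    if (npos == 0 || npos == n) {
      constant[j] <- npos / n
      next
    }
    # small positive classes are routine for rare GO terms; glmnet's
    # small-class warning is expected and benign, and a class too small to
    # fit at all degrades to the constant model like the one-class case
    fit <- tryCatch(
      suppressWarnings(
        glmnet::glmnet(xfit, yj, family = "binomial", alpha = 0,
                       lambda = lam, standardize = FALSE, thresh = 1e-10)),
      error = function(e) NULL)
    if (is.null(fit)) {
      constant[j] <- npos / n
      next
    }
    co <- as.numeric(stats::coef(fit))
    intercept[j] <- co[1L]
    weights[, j] <- co[2L:(m + 1L)]
  }
  structure(list(weights = weights, intercept = intercept, constant = constant,
                 terms = train_table$terms, vocabulary = features$vocabulary),
            class = "lr_model")
}

#' Predict with a per-term logistic regression model
#'
#' @param model An `lr_model`.
#' @param features A `signature_matrix` built with the model's vocabulary.
#' @param proteins Proteins to score (must have feature rows).
#' @return A `score_matrix`.
#' @export
lr_predict <- function(model, features, proteins) {
  if (!identical(features$vocabulary$signatures, model$vocabulary$signatures)) {
    stop("feature vocabulary does not match the fitted model")
  }
  idx <- match(proteins, features$proteins)
  if (anyNA(idx)) stop("proteins without feature rows: ",
                       paste(proteins[is.na(idx)], collapse = ", "))
  x <- features$matrix[idx, , drop = FALSE]
  s <- sigmoid(sweep(as.matrix(x %*% model$weights), 2, model$intercept, `+`))
  const <- !is.na(model$constant)
  if (any(const)) s[, const] <- matrix(model$constant[const], nrow(s),
                                       sum(const), byrow = TRUE)
  score_matrix(proteins, model$terms, s)
}
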