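# Residual graph convolutional network for multi-label GO prediction.
#
# Architecture: input FC layer on sparse binary signature features,
#   H0 = relu(X W0 + b0)
# M residual GCN layers over the symmetrically normalized adjacency Ahat,
#   Hl = relu(Ahat H(l-1) Wl + bl) + H(l-1)
# per-term sigmoid output,
#   yhat_ij = sigmoid(Wo[, j] . h_i + bo_j)
# trained with masked binary cross-entropy over labeled nodes only
# (semi-supervised: unlabeled network nodes still shape message passing).

relu <- function(x) pmax(x, 0)
sigmoid <- function(x) 1 / (1 + exp(-x))

#' Training configuration
#'
#' Defaults follow the reference setting for this architecture: two GCN
#' layers, mini-batches of 40 labeled nodes, 10 epochs, Adam with stepsize
#' 1e-3, dropout 0.5 after each GCN layer, top-30 edges per node, and a
#' three-seed ensemble.
#'
#' @param n_layers Number of GCN layers M (0 disables message passing).
#' @param hidden_dim Representation width d.
#' @param batch_size Labeled nodes per mini-batch.
#' @param epochs Training sweeps over the labeled nodes.
#' @param learning_rate Adam stepsize.
#' @param dropout Drop rate applied after each GCN layer during training.
#' @param k_edges Top-k edges kept per node before training.
#' @param seeds RNG seeds, one model per seed (ensembled by averaging).
#' @return A `gnn_config` list.
#' @export
gnn_config <- function(n_layers = 2L, hidden_dim = 512L, batch_size = 40L,
                       epochs = 10L, learning_rate = 1e-3, dropout = 0.5,
                       k_edges = 30L, seeds = c(101L, 102L, 103L)) {
  stopifnot(n_layers >= 0, hidden_dim >= 1, batch_size >= 1, epochs >= 0,
            learning_rate > 0, dropout >= 0, dropout < 1, k_edges >= 1,
            length(seeds) >= 1)
  structure(list(n_layers = as.integer(n_layers),
                 hidden_dim = as.integer(hidden_dim),
                 batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs),
                 learning_rate = learning_rate, dropout = dropout,
                 k_edges = as.integer(k_edges), seeds = as.integer(seeds)),
            class = "gnn_config")
}

# uniform fan-in initialization, U(-1/sqrt(fan_in), 1/sqrt(fan_in))
.init_mat <- function(nr, nc) {
  bound <- 1 / sqrt(nr)
  matrix(stats::runif(nr * nc, -bound, bound), nr, nc)
}

#' Initialize a GCN model
#'
#' @param m Feature (signature vocabulary) size.
#' @param k_terms Number of scored GO terms K.
#' @param config A [gnn_config()].
#' @param seed RNG seed for the initial weights.
#' @param hidden_fc Add one extra hidden fully connected layer between the
#'   input layer and the output layer (used by the graph-free ablation).
#' @return A `gnn_model`: list of parameter matrices `W0` (m x d), `b0`,
#'   `W`/`b` (per GCN layer), optional `Wh`/`bh`, `Wo` (d x K), `bo`.
#' @export
gnn_init <- function(m, k_terms, config = gnn_config(), seed = 1L,
                     hidden_fc = FALSE) {
  set.seed(seed)
  d <- config$hidden_dim
  model <- list(
    W0 = .init_mat(m, d), b0 = stats::runif(d, -1 / sqrt(m), 1 / sqrt(m)),
    W = lapply(seq_len(config$n_layers), function(l) .init_mat(d, d)),
    b = lapply(seq_len(config$n_layers), function(l)
      stats::runif(d, -1 / sqrt(d), 1 / sqrt(d))),
    Wo = .init_mat(d, k_terms), bo = stats::runif(k_terms, -1 / sqrt(d), 1 / sqrt(d)),
    m = m, d = d, k_terms = k_terms, n_layers = config$n_layers,
    hidden_fc = hidden_fc
  )
  if (hidden_fc) {
    model$Wh <- .init_mat(d, d)
    model$bh <- stats::runif(d, -1 / sqrt(d), 1 / sqrt(d))
  }
  class(model) <- "gnn_model"
  model
}

#' @export
print.gnn_model <- function(x, ...) {
  cat("gnn_model: m =", x$m, ", d =", x$d, ", M =", x$n_layers,
      ", K =", x$k_terms, if (isTRUE(x$hidden_fc)) "(graph-free ablation)" else "", "\n")
  invisible(x)
}

#' Input layer forward pass
#'
#' `H0 = f(X W0 + b0)` rowwise, with `f` the rectifier.
#'
#' @param x Sparse binary feature matrix (rows = proteins), or a
#'   `signature_matrix`.
#' @param model A `gnn_model`.
#' @return Dense representation matrix (N x d).
#' @export
input_forward <- function(x, model) {
  if (inherits(x, "signature_matrix")) x <- x$matrix
  if (ncol(x) != model$m) stop("feature width ", ncol(x), " != model m ", model$m)
  relu(sweep(as.matrix(x %*% model$W0), 2, model$b0, `+`))
}

#' One residual GCN layer forward pass
#'
#' `H(l) = f(Ahat H(l-1) W + b) + H(l-1)`: the residual is added outside the
#' nonlinearity.
#'
#' @param h_prev Previous representation matrix (N x d).
#' @param adjacency Normalized adjacency (a `normalized_adjacency`, a
#'   `batch_subgraph`, or a plain matrix).
#' @param w,b Layer weight (d x d) and bias (d).
#' @param f Activation (default rectifier).
#' @return Updated representation matrix.
#' @export
gcn_forward <- function(h_prev, adjacency, w, b, f = relu) {
  if (inherits(adjacency, c("normalized_adjacency", "batch_subgraph"))) {
    adjacency <- adjacency$matrix
  }
  if (nrow(h_prev) != nrow(adjacency)) stop("representation/adjacency size mismatch")
  if (any(!is.finite(h_prev))) stop("non-finite representation input")
  f(sweep(as.matrix(adjacency %*% h_prev %*% w), 2, b, `+`)) + h_prev
}

#' Output layer forward pass
#'
#' Per-term sigmoid scores `yhat_ij = sigmoid(Wo[, j] . h_i + bo_j)`.
#'
#' @param h Representation matrix (N x d).
#' @param model A `gnn_model`.
#' @return Dense score matrix (N x K), entries in (0, 1).
#' @export
output_forward <- function(h, model) {
  if (ncol(h) != model$d) stop("representation width mismatch")
  sigmoid(sweep(h %*% model$Wo, 2, model$bo, `+`))
}

#' Masked binary cross-entropy loss
#'
#' Mean over labeled proteins (mask) and all K terms of
#' `-[y log yhat + (1 - y) log(1 - yhat)]`, scores clipped to
#' `[eps, 1 - eps]`.
#'
#' @param scores Score matrix (N x K).
#' @param truth Binary matrix of the same shape.
#' @param mask Logical or integer vector of labeled rows.
#' @param eps Clipping constant (default 1e-12).
#' @return Scalar loss.
#' @export
bce_loss <- function(scores, truth, mask = seq_len(nrow(scores)), eps = 1e-12) {
  if (is.logical(mask)) mask <- which(mask)
  if (length(mask) == 0L) stop("empty labeled mask")
  s <- pmin(pmax(as.matrix(scores[mask, , drop = FALSE]), eps), 1 - eps)
  y <- as.matrix(truth[mask, , drop = FALSE])
  -mean(y * log(s) + (1 - y) * log(1 - s))
}

# full forward pass (no dropout); adjacency NULL for the graph-free ablation
.gnn_forward <- function(model, x, adjacency = NULL) {
  h <- input_forward(x, model)
  if (isTRUE(model$hidden_fc)) {
    h <- relu(sweep(h %*% model$Wh, 2, model$bh, `+`))
  }
  if (model$n_layers > 0) {
    for (l in seq_len(model$n_layers)) {
      h <- gcn_forward(h, adjacency, model$W[[l]], model$b[[l]])
    }
  }
  output_forward(h, model)
}

#' Graph-free feed-forward ablation forward pass
#'
#' Replaces the GCN layers with one hidden fully connected layer on the
#' signature features alone; consumes no graph input.
#'
#' @param x Feature matrix or `signature_matrix`.
#' @param model A `gnn_model` built with `hidden_fc = TRUE`, `n_layers = 0`.
#' @return Dense score matrix (N x K).
#' @export
dnn_interpro_forward <- function(x, model) {
  stopifnot(isTRUE(model$hidden_fc), model$n_layers == 0L)
  .gnn_forward(model, x, adjacency = NULL)
}

# ---- training ----------------------------------------------------------

.adam_new <- function(shapes) {
  lapply(shapes, function(s) list(m = array(0, dim = s), v = array(0, dim = s)))
}

.adam_step <- function(par, grad, state, lr, t, beta1 = 0.9, beta2 = 0.999,
                       eps = 1e-8) {
  state$m <- beta1 * state$m + (1 - beta1) * grad
  state$v <- beta2 * state$v + (1 - beta2) * grad^2
  mhat <- state$m / (1 - beta1^t)
  vhat <- state$v / (1 - beta2^t)
  list(par = par - lr * mhat / (sqrt(vhat) + eps), state = state)
}

# forward+backward on one batch; returns loss and parameter gradients.
# xb: sparse features for included nodes; ahat: local normalized adjacency
# (NULL for graph-free); y: truth for seed rows; seed_idx: rows with labels.
.gnn_batch_grad <- function(model, xb, ahat, y, seed_idx, dropout, training = TRUE) {
  n <- nrow(xb); d <- model$d; K <- model$k_terms
  z0 <- sweep(as.matrix(xb %*% model$W0), 2, model$b0, `+`)
  h <- relu(z0)
  cache <- list(h0 = h)
  if (isTRUE(model$hidden_fc)) {
    zh <- sweep(h %*% model$Wh, 2, model$bh, `+`)
    ah <- relu(zh)
    cache$zh <- zh; cache$h_pre_hidden <- h
    h <- ah
    if (training && dropout > 0) {
      mask_h <- matrix(stats::rbinom(n * d, 1, 1 - dropout) / (1 - dropout), n, d)
      h <- h * mask_h
      cache$mask_h <- mask_h
    }
  }
  layers <- list()
  if (model$n_layers > 0) {
    for (l in seq_len(model$n_layers)) {
      p <- as.matrix(ahat %*% h)
      z <- sweep(p %*% model$W[[l]], 2, model$b[[l]], `+`)
      a <- relu(z)
      h_new <- a + h
      mask <- NULL
      if (training && dropout > 0) {
        mask <- matrix(stats::rbinom(n * d, 1, 1 - dropout) / (1 - dropout), n, d)
        h_new <- h_new * mask
      }
      layers[[l]] <- list(p = p, z = z, h_in = h, mask = mask)
      h <- h_new
    }
  }
  s <- sweep(h %*% model$Wo, 2, model$bo, `+`)
  yhat <- sigmoid(s)
  eps <- 1e-12
  ys <- pmin(pmax(yhat[seed_idx, , drop = FALSE], eps), 1 - eps)
  loss <- -mean(y * log(ys) + (1 - y) * log(1 - ys))

  # backward
  ds <- matrix(0, n, K)
  ds[seed_idx, ] <- (yhat[seed_idx, , drop = FALSE] - y) / (length(seed_idx) * K)
  grads <- list(Wo = crossprod(h, ds), bo = colSums(ds))
  dh <- ds %*% t(model$Wo)
  if (model$n_layers > 0) {
    grads$W <- vector("list", model$n_layers)
    grads$b <- vector("list", model$n_layers)
    for (l in rev(seq_len(model$n_layers))) {
      lay <- layers[[l]]
      if (!is.null(lay$mask)) dh <- dh * lay$mask
      dz <- (dh * (lay$z > 0))
      grads$W[[l]] <- crossprod(lay$p, dz)
      grads$b[[l]] <- colSums(dz)
      dp <- dz %*% t(model$W[[l]])
      # residual carries dh through; message passing adds Ahat^T dp
      dh <- dh + as.matrix(Matrix::t(ahat) %*% dp)
    }
  }
  if (isTRUE(model$hidden_fc)) {
    if (!is.null(cache$mask_h)) dh <- dh * cache$mask_h
    dzh <- dh * (cache$zh > 0)
    grads$Wh <- crossprod(cache$h_pre_hidden, dzh)
    grads$bh <- colSums(dzh)
    dh <- dzh %*% t(model$Wh)
  }
  dz0 <- dh * (z0 > 0)
  grads$W0 <- as.matrix(Matrix::crossprod(xb, dz0))
  grads$b0 <- colSums(dz0)
  list(loss = loss, grads = grads)
}

#' Train the GCN on labeled nodes of a protein network
#'
#' Mini-batch semi-supervised training: each epoch shuffles the labeled
#' nodes into batches, extracts the M-hop neighborhood of each batch from
#' the pruned, normalized graph, and takes one Adam step on the masked
#' binary cross-entropy of the batch's labeled rows. The graph should
#' already be pruned with [top_k_prune()] at `config$k_edges`. Only labeled
#' proteins present in the graph are trained on.
#'
#' @param features A `signature_matrix` over the graph nodes (row order must
#'   match `graph$nodes`).
#' @param normalized A `normalized_adjacency` over the same nodes.
#' @param train_table An `annotation_table` of training annotations
#'   (propagated, root-free); proteins absent from the graph are ignored.
#' @param config A [gnn_config()].
#' @param seed RNG seed controlling initialization, shuffling and dropout.
#' @param verbose Print per-epoch mean loss.
#' @return A trained `gnn_model` with attribute `epoch_loss` (mean training
#'   loss per epoch).
#' @export
gnn_train <- function(features, normalized, train_table, config = gnn_config(),
                      seed = config$seeds[1L], verbose = FALSE) {
  stopifnot(identical(features$proteins, normalized$nodes))
  labeled <- intersect(train_table$proteins, normalized$nodes)
  if (length(labeled) == 0L) stop("no labeled proteins present in the graph")
  truth <- train_table$matrix[match(labeled, train_table$proteins), , drop = FALSE]
  node_idx <- match(labeled, normalized$nodes)

  model <- gnn_init(length(features$vocabulary$signatures),
                    length(train_table$terms), config, seed = seed)
  if (config$epochs == 0L) return(model)
  model$terms <- train_table$terms

  shapes <- c(list(W0 = dim(model$W0), b0 = length(model$b0),
                   Wo = dim(model$Wo), bo = length(model$bo)),
              stats::setNames(lapply(model$W, dim),
                              paste0("W", seq_len(config$n_layers))),
              stats::setNames(lapply(model$b, length),
                              paste0("b", seq_len(config$n_layers))))
  adam <- .adam_new(shapes)
  t_step <- 0L
  epoch_loss <- numeric(config$epochs)
  for (epoch in seq_len(config$epochs)) {
    order_ix <- sample(length(labeled))
    batches <- split(order_ix, ceiling(seq_along(order_ix) / config$batch_size))
    losses <- numeric(length(batches))
    for (bi in seq_along(batches)) {
      batch <- batches[[bi]]
      sub <- batch_neighborhood(normalized, labeled[batch], hops = config$n_layers)
      xb <- features$matrix[sub$global_index, , drop = FALSE]
      res <- .gnn_batch_grad(model, xb, sub$matrix,
                             as.matrix(truth[batch, , drop = FALSE]),
                             sub$seed_index, config$dropout)
      if (!is.finite(res$loss)) {
        stop("non-finite training loss at epoch ", epoch, ", batch ", bi)
      }
      losses[bi] <- res$loss
      t_step <- t_step + 1L
      g <- res$grads
      upd <- function(name, par, grad) {
        st <- .adam_step(par, grad, adam[[name]], config$learning_rate, t_step)
        adam[[name]] <<- st$state
        st$par
      }
      model$W0 <- upd("W0", model$W0, g$W0)
      model$b0 <- upd("b0", model$b0, g$b0)
      model$Wo <- upd("Wo", model$Wo, g$Wo)
      model$bo <- upd("bo", model$bo, g$bo)
      if (config$n_layers > 0) {
        for (l in seq_len(config$n_layers)) {
          model$W[[l]] <- upd(paste0("W", l), model$W[[l]], g$W[[l]])
          model$b[[l]] <- upd(paste0("b", l), model$b[[l]], g$b[[l]])
        }
      }
    }
    epoch_loss[epoch] <- mean(losses)
    if (verbose) message("epoch ", epoch, ": mean loss ", signif(epoch_loss[epoch], 4))
  }
  attr(model, "epoch_loss") <- epoch_loss
  model
}

#' Train the graph-free feed-forward ablation
#'
#' Same optimizer, loss and schedule as [gnn_train()], but the network input
#' is ignored: representations come from one extra hidden fully connected
#' layer on the signature features. All labeled proteins are used (the model
#' needs no graph membership).
#'
#' @inheritParams gnn_train
#' @param features A `signature_matrix` covering at least the training
#'   proteins.
#' @return A trained `gnn_model` (with `hidden_fc = TRUE`).
#' @export
dnn_train <- function(features, train_table, config = gnn_config(),
                      seed = config$seeds[1L], verbose = FALSE) {
  labeled <- intersect(train_table$proteins, features$proteins)
  if (length(labeled) == 0L) stop("no labeled proteins with features")
  truth <- train_table$matrix[match(labeled, train_table$proteins), , drop = FALSE]
  feat_idx <- match(labeled, features$proteins)

  cfg0 <- config; cfg0$n_layers <- 0L
  model <- gnn_init(length(features$vocabulary$signatures),
                    length(train_table$terms), cfg0, seed = seed, hidden_fc = TRUE)
  if (config$epochs == 0L) return(model)
  model$terms <- train_table$terms

  shapes <- list(W0 = dim(model$W0), b0 = length(model$b0),
                 Wh = dim(model$Wh), bh = length(model$bh),
                 Wo = dim(model$Wo), bo = length(model$bo))
  adam <- .adam_new(shapes)
  t_step <- 0L
  epoch_loss <- numeric(config$epochs)
  for (epoch in seq_len(config$epochs)) {
    order_ix <- sample(length(labeled))
    batches <- split(order_ix, ceiling(seq_along(order_ix) / config$batch_size))
    losses <- numeric(length(batches))
    for (bi in seq_along(batches)) {
      batch <- batches[[bi]]
      xb <- features$matrix[feat_idx[batch], , drop = FALSE]
      res <- .gnn_batch_grad(model, xb, NULL,
                             as.matrix(truth[batch, , drop = FALSE]),
                             seq_along(batch), config$dropout)
      if (!is.finite(res$loss)) {
        stop("non-finite training loss at epoch ", epoch, ", batch ", bi)
      }
      losses[bi] <- res$loss
      t_step <- t_step + 1L
      g <- res$grads
      for (name in names(shapes)) {
        st <- .adam_step(model[[name]], g[[name]], adam[[name]],
                         config$learning_rate, t_step)
        model[[name]] <- st$par
        adam[[name]] <- st$state
      }
    }
    epoch_loss[epoch] <- mean(losses)
    if (verbose) message("epoch ", epoch, ": mean loss ", signif(epoch_loss[epoch], 4))
  }
  attr(model, "epoch_loss") <- epoch_loss
  model
}

# ---- prediction --------------------------------------------------------

#' Score-matrix container
#' @param proteins,terms Axis identifiers.
#' @param scores Numeric matrix in [0, 1].
#' @param coverage Optional per-protein stratum (STRI / HOMO / NONE).
#' @return A `score_matrix`.
#' @export
score_matrix <- function(proteins, terms, scores, coverage = NULL) {
  stopifnot(nrow(scores) == length(proteins), ncol(scores) == length(terms))
  dimnames(scores) <- list(proteins, terms)
  structure(list(proteins = proteins, terms = terms,
                 scores = as.matrix(scores), coverage = coverage),
            class = "score_matrix")
}

#' @export
print.score_matrix <- function(x, ...) {
  cat("score_matrix:", length(x$proteins), "proteins x", length(x$terms), "terms\n")
  if (!is.null(x$coverage)) print(table(x$coverage))
  invisible(x)
}

#' Highest-bit-score in-graph homolog of each query
#'
#' @param queries Query protein identifiers.
#' @param homology data.frame with `query`, `subject`, `bitscore` columns.
#' @param universe Proteins eligible as homologs (e.g. graph nodes).
#' @return Named character vector (NA where no homolog exists).
#' @export
best_homolog <- function(queries, homology, universe) {
  hom <- homology[homology$subject %in% universe &
                    homology$query %in% queries, , drop = FALSE]
  out <- stats::setNames(rep(NA_character_, length(queries)), queries)
  if (nrow(hom) > 0L) {
    hom <- hom[order(hom$query, -hom$bitscore, hom$subject), , drop = FALSE]
    first <- hom[!duplicated(hom$query), , drop = FALSE]
    out[first$query] <- first$subject
  }
  out
}

#' Predict GO-term scores with homology fallback
#'
#' Proteins in the graph are scored by the forward pass. Proteins off the
#' graph with at least one in-graph homolog copy the score row of their
#' highest-bit-score homolog (stratum HOMO). Proteins with neither get an
#' all-zero row and stratum NONE — a documented outcome, not an error.
#'
#' @param model A trained `gnn_model`.
#' @param features A `signature_matrix` over the graph nodes.
#' @param normalized A `normalized_adjacency` (or `batch_subgraph`) over the
#'   same nodes; ignored by the graph-free ablation.
#' @param proteins Proteins to score.
#' @param homology Optional homology data.frame (query, subject, bitscore).
#' @return A `score_matrix` with per-protein `coverage` strata.
#' @export
gnn_predict <- function(model, features, normalized, proteins,
                        homology = NULL) {
  if (isTRUE(model$hidden_fc)) {
    # graph-free: every protein with a feature row is scorable directly
    idx <- match(proteins, features$proteins)
    scorable <- features$proteins
    full <- .gnn_forward(model, features$matrix, NULL)
  } else {
    scorable <- normalized$nodes
    full <- .gnn_forward(model, features$matrix, normalized)
    idx <- match(proteins, scorable)
  }
  terms <- if (!is.null(model$terms)) model$terms else
    paste0("term", seq_len(model$k_terms))
  out <- matrix(0, length(proteins), length(terms))
  coverage <- rep("NONE", length(proteins))
  hit <- !is.na(idx)
  out[hit, ] <- full[idx[hit], , drop = FALSE]
  coverage[hit] <- "STRI"
  if (!is.null(homology) && any(!hit)) {
    fb <- best_homolog(proteins[!hit], homology, scorable)
    has <- !is.na(fb)
    if (any(has)) {
      out[which(!hit)[has], ] <- full[match(fb[has], scorable), , drop = FALSE]
      coverage[which(!hit)[has]] <- "HOMO"
    }
  }
  score_matrix(proteins, terms, out, coverage = coverage)
}

#' Average an ensemble of score matrices
#'
#' @param matrices List of `score_matrix` objects over identical axes.
#' @return Their elementwise arithmetic mean (coverage from the first).
#' @export
ensemble_average <- function(matrices) {
  stopifnot(length(matrices) >= 1L)
  ref <- matrices[[1L]]
  for (m in matrices[-1L]) {
    if (!identical(m$proteins, ref$proteins) || !identical(m$terms, ref$terms)) {
      stop("score matrices have mismatched axes")
    }
  }
  avg <- Reduce(`+`, lapply(matrices, `[[`, "scores")) / length(matrices)
  score_matrix(ref$proteins, ref$terms, avg, coverage = ref$coverage)
}
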