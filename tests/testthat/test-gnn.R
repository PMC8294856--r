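# small random model/feature builders
rand_model <- function(m, d, K, M = 2, seed = 1, hidden_fc = FALSE) {
  gnn_init(m, K, gnn_config(n_layers = M, hidden_dim = d), seed = seed,
           hidden_fc = hidden_fc)
}
rand_features <- function(n, m, seed = 1, density = 0.3) {
  set.seed(seed)
  Matrix::Matrix(matrix(rbinom(n * m, 1, density), n, m), sparse = TRUE)
}

test_that("input layer matches a dense scalar oracle and trivial cases", {
  model <- rand_model(6, 4, 3)
  x <- rand_features(5, 6, seed = 2)
  h <- input_forward(x, model)
  # scalar-loop oracle
  oracle <- matrix(0, 5, 4)
  for (i in 1:5) for (j in 1:4) {
    oracle[i, j] <- max(0, sum(as.matrix(x)[i, ] * model$W0[, j]) + model$b0[j])
  }
  expect_equal(h, oracle, tolerance = 1e-12, ignore_attr = TRUE)
  # zero weights -> zero matrix
  z <- model; z$W0[] <- 0; z$b0[] <- 0
  expect_equal(input_forward(x, z), matrix(0, 5, 4), ignore_attr = TRUE)
  # zero row -> f(b0)
  x0 <- rand_features(1, 6, seed = 3) * 0
  expect_equal(as.vector(input_forward(x0, model)), pmax(model$b0, 0))
  expect_error(input_forward(rand_features(2, 5), model), "mismatch|!=")
})

test_that("GCN layer equals a dense propagation oracle; residual collapses at W=0", {
  for (seed in 1:20) {
    g <- random_graph(10, p = 0.3, seed = seed)
    nm <- normalized_adjacency(g)
    set.seed(seed)
    h0 <- matrix(rnorm(10 * 4), 10, 4)
    w <- matrix(rnorm(16, sd = 0.3), 4, 4); b <- rnorm(4, sd = 0.1)
    got <- gcn_forward(h0, nm, w, b)
    a <- as.matrix(nm$matrix)
    oracle <- pmax(a %*% h0 %*% w + matrix(b, 10, 4, byrow = TRUE), 0) + h0
    expect_equal(got, oracle, tolerance = 1e-9)
    # two stacked layers against the two-step oracle
    got2 <- gcn_forward(got, nm, w, b)
    oracle2 <- pmax(a %*% oracle %*% w + matrix(b, 10, 4, byrow = TRUE), 0) + oracle
    expect_equal(got2, oracle2, tolerance = 1e-9)
    # zero-weight collapse: residual identity for any graph
    expect_equal(gcn_forward(h0, nm, w * 0, b * 0), h0, ignore_attr = TRUE)
  }
  # single node with self-loop only: Ahat = 1
  g1 <- protein_graph("a", data.frame(from = character(0), to = character(0),
                                      weight = numeric(0)))
  nm1 <- normalized_adjacency(g1)
  h <- matrix(c(1, -2, 3), 1, 3)
  w <- diag(3); b <- c(0.5, 0, -1)
  expect_equal(gcn_forward(h, nm1, w, b), pmax(h %*% w + rep(b, each = 1), 0) + h,
               ignore_attr = TRUE)
  expect_error(gcn_forward(matrix(NaN, 1, 3), nm1, w, b), "non-finite")
})

test_that("output layer matches a per-entry sigmoid oracle and saturates", {
  model <- rand_model(6, 4, 3)
  set.seed(7)
  h <- matrix(rnorm(5 * 4), 5, 4)
  s <- output_forward(h, model)
  for (i in 1:5) for (j in 1:3) {
    expect_equal(s[i, j],
                 1 / (1 + exp(-(sum(h[i, ] * model$Wo[, j]) + model$bo[j]))),
                 tolerance = 1e-12)
  }
  z <- model; z$Wo[] <- 0; z$bo[] <- 0
  expect_equal(output_forward(h, z), matrix(0.5, 5, 3), ignore_attr = TRUE)
  z$bo[] <- 30
  expect_equal(output_forward(h, z), matrix(1, 5, 3), tolerance = 1e-9,
               ignore_attr = TRUE)
})

test_that("masked BCE matches closed forms and a scalar double-loop oracle", {
  y <- matrix(c(1, 0, 1, 0, 0, 1, 1, 1, 0, 1, 0, 0), 4, 3)
  expect_lt(bce_loss(y, y), 1e-10)                       # perfect prediction
  expect_equal(bce_loss(matrix(0.5, 4, 3), y), log(2), tolerance = 1e-12)
  set.seed(8)
  s <- matrix(runif(12, 0.01, 0.99), 4, 3)
  mask <- c(1, 3)
  oracle <- 0
  for (i in mask) for (j in 1:3) {
    oracle <- oracle - (y[i, j] * log(s[i, j]) + (1 - y[i, j]) * log(1 - s[i, j]))
  }
  expect_equal(bce_loss(s, y, mask), oracle / (2 * 3), tolerance = 1e-12)
  expect_error(bce_loss(s, y, integer(0)), "empty")
})

test_that("graph-free ablation ignores the graph and matches a dense oracle", {
  model <- rand_model(6, 4, 3, M = 0, hidden_fc = TRUE)
  x <- rand_features(5, 6, seed = 9)
  s <- dnn_interpro_forward(x, model)
  h0 <- pmax(as.matrix(x) %*% model$W0 + matrix(model$b0, 5, 4, byrow = TRUE), 0)
  h1 <- pmax(h0 %*% model$Wh + matrix(model$bh, 5, 4, byrow = TRUE), 0)
  oracle <- 1 / (1 + exp(-(h1 %*% model$Wo + matrix(model$bo, 5, 3, byrow = TRUE))))
  expect_equal(s, oracle, tolerance = 1e-9, ignore_attr = TRUE)
  z <- model
  z$W0[] <- 0; z$b0[] <- 0; z$Wh[] <- 0; z$bh[] <- 0; z$Wo[] <- 0; z$bo[] <- 0
  expect_equal(dnn_interpro_forward(x, z), matrix(0.5, 5, 3), ignore_attr = TRUE)
})

test_that("zero-weight GCN stack equals input+output composition on any graph", {
  for (seed in 1:5) {
    g <- random_graph(12, p = 0.4, seed = seed + 60)
    nm <- normalized_adjacency(g)
    model <- rand_model(8, 5, 4, M = 3, seed = seed)
    for (l in 1:3) { model$W[[l]][] <- 0; model$b[[l]][] <- 0 }
    x <- rand_features(12, 8, seed = seed)
    h0 <- input_forward(x, model)
    via_graph <- gognn:::.gnn_forward(model, x, nm)
    expect_equal(via_graph, output_forward(h0, model), tolerance = 1e-12,
                 ignore_attr = TRUE)
  }
})

test_that("node permutation of features and graph permutes score rows", {
  g <- random_graph(15, p = 0.3, seed = 5)
  nm <- normalized_adjacency(g)
  x <- rand_features(15, 10, seed = 5)
  model <- rand_model(10, 6, 4, seed = 5)
  base <- gognn:::.gnn_forward(model, x, nm)
  set.seed(6)
  perm <- sample(15)
  g2 <- g
  g2$nodes <- g$nodes[perm]
  g2$adjacency <- g$adjacency[perm, perm]
  nm2 <- normalized_adjacency(g2)
  out <- gognn:::.gnn_forward(model, x[perm, ], nm2)
  expect_equal(out, base[perm, ], tolerance = 1e-10, ignore_attr = TRUE)
})

test_that("vocabulary permutation with matching W0 rows leaves scores unchanged", {
  x <- rand_features(8, 10, seed = 11)
  model <- rand_model(10, 5, 3, seed = 11)
  base <- output_forward(input_forward(x, model), model)
  set.seed(12)
  perm <- sample(10)
  model2 <- model; model2$W0 <- model$W0[perm, ]
  out <- output_forward(input_forward(x[, perm], model2), model2)
  expect_equal(out, base, tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("training reduces loss on separable data, deterministically per seed", {
  bench <- synth_benchmark(synth_config(n_proteins = 60, n_terms = 20,
                                        n_signatures = 40, seed = 21,
                                        feature_signal = 0.9))
  cfg <- gnn_config(hidden_dim = 16, epochs = 10, batch_size = 16,
                    seeds = c(5L))
  tab <- bench$split$train
  pruned <- top_k_prune(bench$graph, cfg$k_edges)
  nm <- normalized_adjacency(pruned)
  m1 <- gnn_train(bench$features, nm, tab, cfg, seed = 5)
  loss <- attr(m1, "epoch_loss")
  expect_true(all(is.finite(loss)))
  expect_lt(loss[length(loss)], loss[1])
  # identical seed -> identical parameters
  m2 <- gnn_train(bench$features, nm, tab, cfg, seed = 5)
  expect_identical(m1$W0, m2$W0)
  expect_identical(m1$Wo, m2$Wo)
  # zero epochs -> initialized model unchanged
  cfg0 <- cfg; cfg0$epochs <- 0L
  m0 <- gnn_train(bench$features, nm, tab, cfg0, seed = 5)
  init <- gnn_init(length(bench$features$vocabulary$signatures),
                   length(tab$terms), cfg0, seed = 5)
  expect_identical(m0$W0, init$W0)
})

test_that("prediction composes forwards, falls back to homologs, flags NONE", {
  bench <- synth_benchmark(synth_config(n_proteins = 60, n_terms = 20,
                                        n_signatures = 40, seed = 22))
  cfg <- gnn_config(hidden_dim = 16, epochs = 2, batch_size = 16, seeds = 5L)
  nm <- normalized_adjacency(top_k_prune(bench$graph, cfg$k_edges))
  model <- gnn_train(bench$features, nm, bench$split$train, cfg)
  # in-graph protein equals the composed forward pass
  p <- bench$features$proteins[3]
  sc <- gnn_predict(model, bench$features, nm, p)
  full <- gognn:::.gnn_forward(model, bench$features$matrix, nm)
  expect_equal(sc$scores[1, ], full[3, ], tolerance = 1e-12, ignore_attr = TRUE)
  expect_equal(sc$coverage, "STRI")
  # off-graph protein: copies the row of its highest-bit-score homolog
  hom <- data.frame(query = c("ghost", "ghost"),
                    subject = bench$features$proteins[c(1, 2)],
                    bitscore = c(80, 120), evalue = 1e-9, pident = 50)
  sc2 <- gnn_predict(model, bench$features, nm, "ghost", homology = hom)
  expect_equal(sc2$scores[1, ], full[2, ], ignore_attr = TRUE)  # picks 120
  expect_equal(sc2$coverage, "HOMO")
  # no homolog: zero row, NONE stratum
  sc3 <- gnn_predict(model, bench$features, nm, "orphan", homology = hom)
  expect_equal(unname(sc3$scores[1, ]), rep(0, length(model$terms)))
  expect_equal(sc3$coverage, "NONE")
})

test_that("subgraph prediction equals full-graph prediction on seed rows", {
  for (seed in 1:5) {
    g <- random_graph(25, p = 0.2, seed = seed + 80)
    x <- rand_features(25, 12, seed = seed)
    features <- structure(list(
      proteins = g$nodes,
      vocabulary = structure(list(signatures = sprintf("s%d", 1:12),
                                  index = stats::setNames(1:12, sprintf("s%d", 1:12))),
                             class = "signature_vocabulary"),
      matrix = x), class = "signature_matrix")
    model <- rand_model(12, 6, 4, seed = seed)
    model$terms <- sprintf("GO:%07d", 1:4)
    nm <- normalized_adjacency(g)
    full <- gnn_predict(model, features, nm, g$nodes)
    seeds_n <- g$nodes[sample(25, 4)]
    sub <- batch_neighborhood(nm, seeds_n, hops = 2)
    sub_feat <- features
    sub_feat$proteins <- sub$nodes
    sub_feat$matrix <- x[sub$global_index, , drop = FALSE]
    local <- gnn_predict(model, sub_feat, sub, seeds_n)
    expect_equal(local$scores, full$scores[match(seeds_n, g$nodes), ],
                 tolerance = 1e-6, ignore_attr = TRUE)
  }
})

test_that("ensemble averaging is the elementwise mean and checks axes", {
  prot <- sprintf("p%d", 1:4); terms <- sprintf("t%d", 1:3)
  a <- score_matrix(prot, terms, matrix(0, 4, 3))
  b <- score_matrix(prot, terms, matrix(1, 4, 3))
  expect_equal(ensemble_average(list(a, b))$scores,
               matrix(0.5, 4, 3), ignore_attr = TRUE)
  expect_equal(ensemble_average(list(b, b, b))$scores, b$scores)
  set.seed(30)
  mats <- lapply(1:3, function(i) score_matrix(prot, terms, matrix(runif(12), 4, 3)))
  avg <- ensemble_average(mats)
  for (i in 1:4) for (j in 1:3) {
    expect_equal(avg$scores[i, j],
                 mean(c(mats[[1]]$scores[i, j], mats[[2]]$scores[i, j],
                        mats[[3]]$scores[i, j])))
  }
  bad <- score_matrix(rev(prot), terms, matrix(0, 4, 3))
  expect_error(ensemble_average(list(a, bad)), "mismatch")
})

test_that("checkpoints round-trip the model through JSON", {
  model <- rand_model(7, 5, 4, M = 2, seed = 31)
  model$terms <- sprintf("GO:%07d", 1:4)
  f <- tempfile(fileext = ".json")
  save_checkpoint(model, f)
  back <- load_checkpoint(f)
  expect_equal(back$W0, model$W0)
  expect_equal(back$W[[2]], model$W[[2]])
  expect_equal(back$bo, model$bo)
  expect_equal(back$terms, model$terms)
  x <- rand_features(6, 7, seed = 31)
  g <- random_graph(6, p = 0.5, seed = 31)
  nm <- normalized_adjacency(g)
  expect_equal(gognn:::.gnn_forward(back, x, nm),
               gognn:::.gnn_forward(model, x, nm), tolerance = 1e-12,
               ignore_attr = TRUE)
})
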