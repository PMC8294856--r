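# End-to-end orchestration: load standard-format inputs, train the seed
# ensemble, predict with any method, evaluate and compare.

#' Load a benchmark directory written in the standard formats
#'
#' Expects `ontology.obo`, `interproscan.tsv`, `network.tsv`,
#' `homology.tsv`, `annotations.tsv` (as written by [write_benchmark()] or
#' assembled from real data).
#'
#' @param dir Input directory.
#' @param domain GO domain to analyse.
#' @param t0,t1,t_valid Split boundaries (see [make_time_split()]).
#' @return List with `ontology`, `features`, `graph`, `homology`, `split`.
#' @export
load_benchmark_dir <- function(dir, domain = "BPO", t0 = "2018-01-01",
                               t1 = "2020-01-01", t_valid = "2019-01-01") {
  need <- c("ontology.obo", "interproscan.tsv", "network.tsv",
            "homology.tsv", "annotations.tsv")
  missing <- need[!file.exists(file.path(dir, need))]
  if (length(missing) > 0L) {
    stop("benchmark directory is missing: ", paste(missing, collapse = ", "))
  }
  ontology <- load_obo(file.path(dir, "ontology.obo"))
  hits <- read_interproscan_tsv(file.path(dir, "interproscan.tsv"))
  graph <- load_string_edges(file.path(dir, "network.tsv"))
  proteins <- sort(unique(c(names(hits), graph$nodes)))
  graph <- load_string_edges(file.path(dir, "network.tsv"), nodes = proteins)
  vocab <- build_vocabulary(hits, proteins)
  features <- vectorize_signatures(hits, vocab, proteins)
  homology <- read_homology_tsv(file.path(dir, "homology.tsv"))
  records <- read_annotation_tsv(file.path(dir, "annotations.tsv"))
  records <- filter_evidence(records)
  split <- make_time_split(records, ontology, domain, t0, t1, t_valid)
  list(ontology = ontology, features = features, graph = graph,
       homology = homology, split = split)
}

#' Train the seed ensemble on a benchmark
#'
#' Prunes the graph to `config$k_edges`, normalizes it, trains one model
#' per seed and (optionally) writes JSON checkpoints plus a manifest.
#'
#' @param bench List with `features`, `graph`, `split` (from
#'   [synth_benchmark()] or [load_benchmark_dir()]).
#' @param config A [gnn_config()].
#' @param min_train_count Minimum training annotations per scored term.
#' @param out_dir Optional directory for checkpoints and `manifest.json`.
#' @return List with `models` (one per seed), `train_table` (scored terms),
#'   `normalized` adjacency and `config`.
#' @export
run_train <- function(bench, config = gnn_config(), min_train_count = 0,
                      out_dir = NULL) {
  train_table <- select_scored_terms(bench$split$train, min_train_count)
  pruned <- top_k_prune(bench$graph, config$k_edges)
  normalized <- normalized_adjacency(pruned)
  models <- lapply(config$seeds, function(s) {
    gnn_train(bench$features, normalized, train_table, config, seed = s)
  })
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    paths <- file.path(out_dir, sprintf("model_seed%d.json", config$seeds))
    for (k in seq_along(models)) {
      save_checkpoint(models[[k]], paths[k], bench$features$vocabulary)
    }
    jsonlite::write_json(
      list(seeds = config$seeds, checkpoints = basename(paths),
           k_terms = length(train_table$terms),
           final_loss = vapply(models, function(m)
             utils::tail(attr(m, "epoch_loss"), 1L), numeric(1))),
      file.path(out_dir, "manifest.json"), auto_unbox = TRUE, digits = NA)
  }
  list(models = models, train_table = train_table, normalized = normalized,
       config = config)
}

#' Predict test scores with a named method
#'
#' @param bench Benchmark list (`features`, `graph`, `homology`, `split`).
#' @param method One of `"gcn"` (the ensemble GNN), `"blast-knn"`,
#'   `"net-knn"`, `"lr-interpro"`, `"dnn-interpro"`.
#' @param trained Result of [run_train()] (required for `"gcn"`).
#' @param proteins Proteins to score; defaults to the test split.
#' @param config A [gnn_config()] (used by `"dnn-interpro"`).
#' @param min_train_count Scored-term threshold for baseline methods.
#' @return A `score_matrix`.
#' @export
run_predict <- function(bench, method = c("gcn", "blast-knn", "net-knn",
                                          "lr-interpro", "dnn-interpro"),
                        trained = NULL, proteins = NULL,
                        config = gnn_config(), min_train_count = 0) {
  method <- match.arg(method)
  if (is.null(proteins)) proteins <- bench$split$test$proteins
  train_table <- if (!is.null(trained)) trained$train_table else
    select_scored_terms(bench$split$train, min_train_count)
  switch(method,
    "gcn" = {
      if (is.null(trained)) stop("method 'gcn' needs a run_train() result")
      ensemble_average(lapply(trained$models, function(m) {
        gnn_predict(m, bench$features, trained$normalized, proteins,
                    homology = bench$homology)
      }))
    },
    "blast-knn" = blast_knn(proteins, bench$homology, train_table),
    "net-knn" = net_knn(proteins, bench$graph, train_table,
                        homology = bench$homology),
    "lr-interpro" = {
      model <- lr_train(bench$features, train_table)
      lr_predict(model, bench$features, proteins)
    },
    "dnn-interpro" = {
      model <- dnn_train(bench$features, train_table, config,
                         seed = config$seeds[1L])
      gnn_predict(model, bench$features, NULL, proteins,
                  homology = bench$homology)
    }
  )
}

#' Evaluate one or more prediction sets against a truth table
#'
#' @param predictions Named list of `score_matrix` objects.
#' @param truth An `annotation_table` (typically the test split).
#' @param min_count M-AUPR term-frequency threshold.
#' @param compare Optional list of 2-element character vectors naming
#'   method pairs for bootstrap comparison.
#' @param n_resamples,seed Bootstrap settings.
#' @return Named list per method with `fmax`, `tau_star`, `aupr`, `m_aupr`,
#'   `n_benchmark`; plus `comparisons` when requested.
#' @export
run_evaluate <- function(predictions, truth, min_count = 3, compare = NULL,
                         n_resamples = 100, seed = 1L) {
  out <- lapply(predictions, function(p) {
    ev <- fmax_protein(p, truth)
    list(fmax = ev$fmax, tau_star = ev$tau_star,
         aupr = aupr_pairs(p, truth),
         m_aupr = tryCatch(m_aupr(p, truth, min_count), error = function(e) NA),
         n_benchmark = ev$n_benchmark)
  })
  if (!is.null(compare)) {
    out$comparisons <- lapply(compare, function(pair) {
      bc <- bootstrap_compare(predictions[[pair[1L]]], predictions[[pair[2L]]],
                              truth, n_resamples = n_resamples, seed = seed)
      list(pair = pair, mean_diff = bc$mean_diff, p_value = bc$p_value,
           degenerate = bc$degenerate)
    })
  }
  out
}
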