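# Self-contained synthetic benchmarks: a layered GO-like DAG, sparse binary
# signature features predictive of leaf terms, a homophilous weighted
# network, a bit-score homology table and time-stamped annotations with
# no-knowledge validation/test proteins.
#
# The generative chain mirrors how the real inputs relate: signatures carry
# a per-term log-odds effect (feature signal s_f); latent leaf labels induce
# the network (edge probability rises with shared terms, homophily beta);
# labels then partially diffuse over the network (each term of one random
# neighbour is copied with probability s_n, network signal); the true-path
# closure and the time-stamped split are applied exactly as for real data.

#' Synthetic benchmark configuration
#'
#' Defaults give a desk-scale benchmark: 300 proteins in 3 species, a
#' 60-term DAG of depth 4, 120 signatures, mean network degree 8.
#'
#' @param n_proteins,n_terms,n_signatures,n_species Sizes.
#' @param dag_depth Layers below the root.
#' @param mean_degree Expected node degree of the network at `homophily = 0`.
#' @param homophily Edge-probability boost per shared latent term (beta).
#' @param feature_signal Per-signature log-odds scale s_f in [0, 1] on its
#'   linked leaf term.
#' @param network_signal Probability s_n in [0, 1] of copying each of a
#'   random neighbour's leaf terms.
#' @param label_density Base rate of a leaf term before any signal.
#' @param domain GO domain label for the generated ontology.
#' @param seed RNG seed; regeneration from the same config is bit-identical.
#' @return A `synth_config` list.
#' @export
synth_config <- function(n_proteins = 300L, n_terms = 60L, n_signatures = 120L,
                         n_species = 3L, dag_depth = 4L, mean_degree = 8,
                         homophily = 0.6, feature_signal = 0.5,
                         network_signal = 0.3, label_density = 0.08,
                         domain = "BPO", seed = 1L) {
  stopifnot(n_proteins > 0, n_terms > 1, n_signatures > 0, n_species > 0,
            dag_depth >= 1, mean_degree > 0,
            homophily >= 0, homophily <= 1,
            network_signal >= 0, network_signal <= 1,
            feature_signal >= 0, label_density > 0, label_density < 1)
  structure(as.list(environment()), class = "synth_config")
}

.domain_namespace <- c(MFO = "molecular_function", BPO = "biological_process",
                       CCO = "cellular_component")

#' Generate a layered random DAG ontology
#'
#' One root; every non-root term has one or two parents drawn from the
#' layer above, so the graph is acyclic by construction and single-domain.
#'
#' @param n_terms Total term count (including the root).
#' @param depth Number of layers below the root (1 gives a star).
#' @param seed RNG seed.
#' @param domain GO domain label.
#' @return A `go_ontology`; attribute `layers` holds the layer assignment.
#' @export
generate_dag <- function(n_terms, depth = 3L, seed = 1L, domain = "BPO") {
  stopifnot(n_terms >= 2, depth >= 1)
  set.seed(seed)
  ids <- sprintf("GO:%07d", seq_len(n_terms))
  root <- ids[1L]
  rest <- ids[-1L]
  layer_of <- sort(rep_len(seq_len(depth), length(rest)))
  parents <- stats::setNames(vector("list", n_terms), ids)
  parents[[root]] <- character(0)
  for (k in seq_along(rest)) {
    above <- if (layer_of[k] == 1L) root else rest[layer_of == layer_of[k] - 1L]
    np <- min(length(above), sample(1:2, 1L))
    parents[[rest[k]]] <- sample(above, np)
  }
  dom <- stats::setNames(rep(domain, n_terms), ids)
  onto <- structure(
    list(terms = ids, parents = parents, domain = dom,
         roots = stats::setNames(root, domain)),
    class = "go_ontology"
  )
  attr(onto, "layers") <- stats::setNames(c(0L, layer_of), ids)
  .check_acyclic(onto)
  onto
}

#' Generate proteins: signatures, homology table, species map
#'
#' Each signature is linked to one leaf term of the ontology; each protein
#' draws a handful of signatures. Homology bit-scores exist only between
#' proteins sharing at least one signature and grow with the shared count,
#' as does percent identity.
#'
#' @param config A [synth_config()].
#' @param ontology The generated `go_ontology`.
#' @return List with `features` (a `signature_matrix`), `homology`
#'   (data.frame query, subject, bitscore, evalue, pident), `species`
#'   (named character), `sig_term` (named character, signature -> linked
#'   leaf term).
#' @export
generate_proteins <- function(config, ontology) {
  set.seed(config$seed + 1L)
  proteins <- sprintf("PROT%04d", seq_len(config$n_proteins))
  species <- stats::setNames(
    sprintf("sp%d", rep_len(seq_len(config$n_species), config$n_proteins)),
    proteins)

  layers <- attr(ontology, "layers")
  leaves <- names(layers)[layers == max(layers)]
  sigs <- sprintf("IPR%06d", seq_len(config$n_signatures))
  sig_term <- stats::setNames(sample(leaves, config$n_signatures, replace = TRUE),
                              sigs)

  hits <- lapply(proteins, function(p) {
    n <- 2L + stats::rpois(1L, 3)
    sample(sigs, min(n, length(sigs)))
  })
  names(hits) <- proteins
  vocab <- build_vocabulary(hits, proteins)
  features <- vectorize_signatures(hits, vocab, proteins)

  # homology from shared-signature counts
  shared <- Matrix::tcrossprod(features$matrix)
  trip <- Matrix::summary(methods::as(shared, "TsparseMatrix"))
  trip <- trip[trip$i < trip$j & trip$x >= 2, , drop = FALSE]
  n_pairs <- nrow(trip)
  if (n_pairs > 0L) {
    bits <- 30 * trip$x + stats::runif(n_pairs, 0, 10)
    pident <- pmin(99, 20 + 14 * trip$x + stats::rnorm(n_pairs, 0, 4))
    pident <- pmax(pident, 5)
    homology <- data.frame(
      query = c(proteins[trip$i], proteins[trip$j]),
      subject = c(proteins[trip$j], proteins[trip$i]),
      bitscore = rep(bits, 2),
      evalue = rep(10^(-bits / 8), 2),
      pident = rep(round(pident, 1), 2),
      stringsAsFactors = FALSE
    )
  } else {
    homology <- data.frame(query = character(0), subject = character(0),
                           bitscore = numeric(0), evalue = numeric(0),
                           pident = numeric(0))
  }
  list(features = features, homology = homology, species = species,
       sig_term = sig_term)
}

# latent leaf labels from signature effects + base rate
.latent_labels <- function(config, ontology, features, sig_term) {
  layers <- attr(ontology, "layers")
  leaves <- names(layers)[layers == max(layers)]
  base <- stats::qlogis(config$label_density)
  effect <- 6 * config$feature_signal
  # count of signatures linked to each leaf, per protein
  link <- Matrix::sparseMatrix(
    i = match(names(sig_term), features$vocabulary$signatures),
    j = match(unname(sig_term), leaves),
    x = 1, dims = c(length(features$vocabulary$signatures), length(leaves)))
  cnt <- as.matrix(features$matrix %*% link)
  p <- stats::plogis(base + effect * cnt)
  lab <- matrix(stats::rbinom(length(p), 1, p), nrow(p), ncol(p))
  dimnames(lab) <- list(features$proteins, leaves)
  # every protein gets at least one leaf term so all rows are benchmarkable
  none <- rowSums(lab) == 0
  if (any(none)) {
    lab[cbind(which(none), sample(ncol(lab), sum(none), replace = TRUE))] <- 1
  }
  lab
}

#' Generate a homophilous weighted protein network
#'
#' Within-species edge probability is `mean_degree / (n_sp - 1)` plus a
#' homophily boost per shared latent leaf term; edge weights increase with
#' the shared-term count.
#'
#' @param config A [synth_config()].
#' @param latent Binary protein x leaf-term matrix of latent labels.
#' @param species Named species map.
#' @return A `protein_graph`.
#' @export
generate_network <- function(config, latent, species) {
  set.seed(config$seed + 2L)
  proteins <- rownames(latent)
  shared <- tcrossprod(latent)
  from <- integer(0); to <- integer(0); w <- numeric(0)
  for (sp in unique(species)) {
    idx <- which(species[proteins] == sp)
    if (length(idx) < 2L) next
    base_p <- min(0.9, config$mean_degree / (length(idx) - 1))
    pairs <- utils::combn(idx, 2L)
    sh <- shared[t(pairs)]
    p_edge <- pmin(0.95, base_p + config$homophily * 0.08 * sh)
    draw <- stats::runif(ncol(pairs)) < p_edge
    if (!any(draw)) next
    wt <- pmin(1, pmax(0.05, 0.35 + 0.12 * sh[draw] +
                         stats::rnorm(sum(draw), 0, 0.05)))
    from <- c(from, pairs[1L, draw]); to <- c(to, pairs[2L, draw])
    w <- c(w, wt)
  }
  protein_graph(proteins,
                data.frame(from = proteins[from], to = proteins[to],
                           weight = w, stringsAsFactors = FALSE))
}

#' Generate time-stamped annotations and the benchmark split
#'
#' Latent leaf labels are augmented by network diffusion (each leaf term of
#' one random neighbour is copied with probability `network_signal`), dated
#' so that a held-out fraction of proteins becomes no-knowledge validation
#' (window 2018) and test (window 2019) proteins, and propagated up the DAG.
#'
#' @param config A [synth_config()].
#' @param ontology A `go_ontology`.
#' @param latent Binary latent label matrix (proteins x leaf terms).
#' @param graph A `protein_graph`.
#' @param frac_valid,frac_test Fractions of proteins held out.
#' @return List with `split` (a `benchmark_split`), `records` (the raw
#'   annotation data.frame) and `roles` (named character: train/valid/test).
#' @export
generate_annotations <- function(config, ontology, latent, graph,
                                 frac_valid = 0.1, frac_test = 0.2) {
  set.seed(config$seed + 3L)
  proteins <- rownames(latent)
  n <- length(proteins)
  labels <- latent
  if (config$network_signal > 0) {
    adj <- graph$adjacency
    for (i in seq_len(n)) {
      nb <- which(adj[i, ] > 0)
      if (length(nb) == 0L) next
      donor <- if (length(nb) == 1L) nb else sample(nb, 1L)
      donor_terms <- which(labels[donor, ] > 0)
      take <- donor_terms[stats::runif(length(donor_terms)) < config$network_signal]
      labels[i, take] <- 1
    }
  }

  roles <- rep("train", n)
  held <- sample(n, round((frac_valid + frac_test) * n))
  nv <- round(frac_valid * n)
  roles[held[seq_len(nv)]] <- "valid"
  roles[held[-seq_len(nv)]] <- "test"
  names(roles) <- proteins

  windows <- list(
    train = c(as.Date("2016-01-01"), as.Date("2018-01-01")),
    valid = c(as.Date("2018-01-01"), as.Date("2019-01-01")),
    test = c(as.Date("2019-01-01"), as.Date("2020-01-01"))
  )
  idx <- which(labels > 0, arr.ind = TRUE)
  prot <- proteins[idx[, 1L]]
  term <- colnames(labels)[idx[, 2L]]
  win <- windows[roles[prot]]
  span <- vapply(win, function(w) as.integer(w[2L] - w[1L]), integer(1))
  date <- as.Date(vapply(seq_along(win), function(k)
    as.integer(win[[k]][1L]) + sample.int(span[k], 1L) - 1L, integer(1)),
    origin = "1970-01-01")
  evidence <- sample(c("IDA", "IMP", "IGI", "EXP", "IEP", "IPI", "IC", "TAS"),
                     length(prot), replace = TRUE)
  records <- data.frame(protein = prot, term = term, evidence = evidence,
                        date = date, stringsAsFactors = FALSE)
  split <- make_time_split(records, ontology, config$domain,
                           t0 = "2018-01-01", t1 = "2020-01-01",
                           t_valid = "2019-01-01")
  list(split = split, records = records, roles = roles)
}

#' Generate a complete synthetic benchmark
#'
#' Runs the whole generative chain and returns every artifact the other
#' modules consume, with provenance for bit-identical regeneration.
#'
#' @param config A [synth_config()].
#' @return A `synth_benchmark`: list with `ontology`, `features`, `graph`,
#'   `homology`, `split`, `records`, `species`, `roles`, `config`.
#' @export
synth_benchmark <- function(config = synth_config()) {
  ontology <- generate_dag(config$n_terms, config$dag_depth, config$seed,
                           config$domain)
  prot <- generate_proteins(config, ontology)
  latent <- .latent_labels(config, ontology, prot$features, prot$sig_term)
  graph <- generate_network(config, latent, prot$species)
  ann <- generate_annotations(config, ontology, latent, graph)
  structure(
    list(ontology = ontology, features = prot$features, graph = graph,
         homology = prot$homology, split = ann$split, records = ann$records,
         species = prot$species, roles = ann$roles, config = config),
    class = "synth_benchmark"
  )
}

#' @export
print.synth_benchmark <- function(x, ...) {
  cat("synth_benchmark:", length(x$features$proteins), "proteins,",
      length(x$ontology$terms), "terms, seed", x$config$seed, "\n")
  print(x$split)
  invisible(x)
}

#' Write a synthetic benchmark as standard-format files
#'
#' Emits the same on-disk formats real inputs use, so downstream paths are
#' identical for real and synthetic data: `ontology.obo`,
#' `interproscan.tsv`, `network.tsv` (STRING-style), `homology.tsv`
#' (outfmt-6-like), `annotations.tsv` and `provenance.json`.
#'
#' @param bench A `synth_benchmark`.
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_benchmark <- function(bench, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_obo(bench$ontology, file.path(dir, "ontology.obo"))
  # InterProScan-style 13-column TSV
  hits <- Matrix::summary(bench$features$matrix)
  sig <- bench$features$vocabulary$signatures[hits$j]
  lines <- paste(bench$features$proteins[hits$i], "md5", "100", "SYNTH",
                 sig, "synthetic signature", "1", "100", "1e-10", "T",
                 "15/01/2020", sig, "synthetic entry", sep = "\t")
  writeLines(lines, file.path(dir, "interproscan.tsv"))
  write_string_edges(bench$graph, file.path(dir, "network.tsv"))
  utils::write.table(bench$homology, file.path(dir, "homology.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  rec <- bench$records
  rec$date <- format(rec$date)
  utils::write.table(rec, file.path(dir, "annotations.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  jsonlite::write_json(
    list(generator = "gognn::synth_benchmark",
         config = unclass(bench$config)),
    file.path(dir, "provenance.json"), auto_unbox = TRUE)
  invisible(dir)
}

#' Write a `go_ontology` as OBO 1.2 text
#' @param ontology A `go_ontology`.
#' @param path Output file.
#' @export
write_obo <- function(ontology, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("format-version: 1.2", ""), con)
  for (t in ontology$terms) {
    pars <- ontology$parents[[t]]
    writeLines(c(
      "[Term]",
      paste0("id: ", t),
      paste0("name: synthetic term ", t),
      paste0("namespace: ", .domain_namespace[[ontology$domain[[t]]]]),
      if (length(pars) > 0) paste0("is_a: ", pars),
      ""), con)
  }
}
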