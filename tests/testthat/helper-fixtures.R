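# Fixtures built in code: tiny ontologies, graphs and score/truth pairs.

# 6-term BPO chain-and-diamond ontology:
#   root <- b <- c ; root <- d ; e is_a b, e part_of d ; f is_a c
tiny_obo_lines <- function() {
  c("format-version: 1.2", "",
    "[Term]", "id: GO:0000001", "name: root", "namespace: biological_process", "",
    "[Term]", "id: GO:0000002", "name: b", "namespace: biological_process",
    "is_a: GO:0000001", "",
    "[Term]", "id: GO:0000003", "name: c", "namespace: biological_process",
    "is_a: GO:0000002", "",
    "[Term]", "id: GO:0000004", "name: d", "namespace: biological_process",
    "is_a: GO:0000001", "",
    "[Term]", "id: GO:0000005", "name: e", "namespace: biological_process",
    "is_a: GO:0000002", "relationship: part_of GO:0000004", "",
    "[Term]", "id: GO:0000006", "name: f", "namespace: biological_process",
    "is_a: GO:0000003", "",
    "[Term]", "id: GO:0000007", "name: gone", "namespace: biological_process",
    "is_a: GO:0000001", "is_obsolete: true", "")
}

tiny_ontology <- function() load_obo(tiny_obo_lines())

# random weighted graph on n nodes; every pair independently an edge
random_graph <- function(n, p = 0.3, seed = 1) {
  set.seed(seed)
  nodes <- sprintf("n%02d", seq_len(n))
  pairs <- utils::combn(n, 2)
  on <- stats::runif(ncol(pairs)) < p
  protein_graph(nodes, data.frame(
    from = nodes[pairs[1, on]], to = nodes[pairs[2, on]],
    weight = round(stats::runif(sum(on), 0.05, 1), 3)))
}

# random scores/truth pair as score_matrix + annotation_table
random_instance <- function(n_prot, n_term, seed, grid = FALSE) {
  set.seed(seed)
  prot <- sprintf("p%d", seq_len(n_prot))
  terms <- sprintf("GO:%07d", seq_len(n_term))
  s <- matrix(stats::runif(n_prot * n_term), n_prot, n_term)
  if (grid) s <- round(s, 2)
  y <- matrix(stats::rbinom(n_prot * n_term, 1, 0.4), n_prot, n_term)
  # ensure a benchmark exists
  if (all(rowSums(y) == 0)) y[1, 1] <- 1
  list(
    scores = score_matrix(prot, terms, s),
    truth = structure(list(proteins = prot, terms = terms,
                           matrix = Matrix::Matrix(y, sparse = TRUE,
                                                   dimnames = list(prot, terms))),
                      class = "annotation_table")
  )
}

# brute-force Fmax: every distinct positive score (plus 1) as threshold —
# the sweep domain is (0, 1], so a zero score is never a prediction
oracle_fmax <- function(s, y) {
  bench <- which(rowSums(y) > 0)
  taus <- sort(unique(c(as.vector(s)[as.vector(s) > 0], 1)))
  best <- 0
  for (tau in taus) {
    prs <- c(); rcs <- c()
    for (i in bench) {
      pred <- which(s[i, ] >= tau)
      tp <- length(intersect(pred, which(y[i, ] > 0)))
      if (length(pred) > 0) prs <- c(prs, tp / length(pred))
      rcs <- c(rcs, tp / sum(y[i, ]))
    }
    pr <- if (length(prs)) mean(prs) else 0
    rc <- mean(rcs)
    f <- if (pr + rc > 0) 2 * pr * rc / (pr + rc) else 0
    best <- max(best, f)
  }
  best
}

# brute-force pooled-pair AUPR by threshold enumeration with tie grouping
oracle_aupr <- function(s, y) {
  sv <- as.vector(s); yv <- as.vector(y) > 0
  taus <- sort(unique(sv), decreasing = TRUE)
  pos <- sum(yv)
  area <- 0; prev_tp <- 0
  for (tau in taus) {
    sel <- sv >= tau
    tp <- sum(yv[sel])
    prec <- tp / sum(sel)
    area <- area + prec * (tp - prev_tp)
    prev_tp <- tp
  }
  area / pos
}
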