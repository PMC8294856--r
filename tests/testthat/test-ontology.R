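test_that("load_obo keeps is_a/part_of structure and drops obsolete terms", {
  onto <- tiny_ontology()
  expect_s3_class(onto, "go_ontology")
  expect_false("GO:0000007" %in% onto$terms)            # obsolete dropped
  expect_equal(onto$parents[["GO:0000003"]], "GO:0000002")  # linear chain
  expect_equal(onto$parents[["GO:0000002"]], "GO:0000001")
  expect_setequal(onto$parents[["GO:0000005"]],
                  c("GO:0000002", "GO:0000004"))         # both parents kept
  expect_equal(unname(onto$roots[["BPO"]]), "GO:0000001")
})

test_that("load_obo rejects cycles and unknown parents", {
  cyc <- c("format-version: 1.2", "",
           "[Term]", "id: A", "namespace: biological_process", "is_a: B", "",
           "[Term]", "id: B", "namespace: biological_process", "is_a: A", "")
  expect_error(load_obo(cyc), "cycle")
  bad <- c("[Term]", "id: A", "namespace: biological_process", "is_a: NOPE", "")
  expect_error(load_obo(bad), "unknown parent")
})

test_that("evidence filtering keeps only accepted codes, order preserved", {
  rec <- data.frame(protein = c("p1", "p1", "p2"),
                    term = rep("GO:0000003", 3),
                    evidence = c("IDA", "IEA", "IMP"),
                    date = as.Date("2017-06-01"))
  out <- filter_evidence(rec)
  expect_equal(out$evidence, c("IDA", "IMP"))   # IEA is not experimental
  expect_equal(filter_evidence(rec, c("IDA", "IEA", "IMP")), rec)
  expect_equal(nrow(filter_evidence(rec, "TAS")), 0L)
})

test_that("true-path propagation closes under ancestors, excludes the root", {
  onto <- tiny_ontology()
  rec <- data.frame(protein = "p1", term = "GO:0000003",
                    evidence = "IDA", date = as.Date("2017-01-01"))
  tab <- propagate_true_path(rec, onto, "BPO")
  got <- tab$terms[as.vector(tab$matrix[1, ]) > 0]
  expect_setequal(got, c("GO:0000003", "GO:0000002"))  # root excluded

  # two leaves sharing an ancestor: counted once (binary matrix)
  rec2 <- data.frame(protein = "p1", term = c("GO:0000006", "GO:0000003"),
                     evidence = "IDA", date = as.Date("2017-01-01"))
  tab2 <- propagate_true_path(rec2, onto, "BPO")
  expect_true(all(as.matrix(tab2$matrix) %in% c(0, 1)))
  got2 <- tab2$terms[as.vector(tab2$matrix[1, ]) > 0]
  expect_setequal(got2, c("GO:0000006", "GO:0000003", "GO:0000002"))
})

test_that("propagation equals a transitive-closure reachability oracle", {
  # Floyd-Warshall reachability over random layered DAGs
  for (seed in 1:5) {
    onto <- generate_dag(20, depth = 3, seed = seed)
    n <- length(onto$terms)
    reach <- diag(n)  # reach[i, j] = 1 if term j is ancestor-or-self of i
    rownames(reach) <- colnames(reach) <- onto$terms
    for (t in onto$terms) for (p in onto$parents[[t]]) reach[t, p] <- 1
    for (k in seq_len(n)) for (i in seq_len(n)) {
      if (reach[i, k] > 0) reach[i, ] <- pmax(reach[i, ], reach[k, ])
    }
    set.seed(seed + 100)
    rec <- data.frame(protein = sample(sprintf("p%d", 1:5), 12, replace = TRUE),
                      term = sample(onto$terms[-1], 12, replace = TRUE),
                      evidence = "EXP", date = as.Date("2017-01-01"))
    tab <- propagate_true_path(rec, onto, "BPO")
    for (p in tab$proteins) {
      direct <- unique(rec$term[rec$protein == p])
      expected <- setdiff(
        onto$terms[colSums(reach[direct, , drop = FALSE]) > 0], onto$terms[1])
      got <- tab$terms[as.vector(tab$matrix[match(p, tab$proteins), ]) > 0]
      expect_setequal(got, expected)
    }
  }
})

test_that("propagation is idempotent and monotone", {
  onto <- generate_dag(25, depth = 3, seed = 3)
  set.seed(9)
  rec <- data.frame(protein = sample(sprintf("p%d", 1:6), 15, replace = TRUE),
                    term = sample(onto$terms[-1], 15, replace = TRUE),
                    evidence = "EXP", date = as.Date("2017-01-01"))
  tab1 <- propagate_true_path(rec, onto, "BPO")
  # feed the propagated pairs back in: nothing changes
  idx <- Matrix::summary(tab1$matrix)
  rec2 <- data.frame(protein = tab1$proteins[idx$i], term = tab1$terms[idx$j],
                     evidence = "EXP", date = as.Date("2017-01-01"))
  tab2 <- propagate_true_path(rec2, onto, "BPO")
  expect_equal(as.matrix(align_terms(tab2, tab1$terms)$matrix[tab1$proteins, ]),
               as.matrix(tab1$matrix))
  # adding a record never removes a 1
  extra <- rbind(rec, data.frame(protein = "p1", term = onto$terms[5],
                                 evidence = "EXP", date = as.Date("2017-01-01")))
  tab3 <- propagate_true_path(extra, onto, "BPO")
  m1 <- as.matrix(align_terms(tab1, tab3$terms)$matrix)
  m3 <- as.matrix(tab3$matrix)[tab1$proteins, , drop = FALSE]
  expect_true(all(m3 >= m1))
})

test_that("terms of the wrong domain are skipped with a warning count", {
  onto <- tiny_ontology()
  onto2 <- onto
  # graft an MFO term
  onto2$terms <- c(onto2$terms, "GO:0000099")
  onto2$parents[["GO:0000099"]] <- character(0)
  onto2$domain <- c(onto2$domain, stats::setNames("MFO", "GO:0000099"))
  onto2$roots <- c(onto2$roots, stats::setNames("GO:0000099", "MFO"))
  rec <- data.frame(protein = "p1", term = c("GO:0000003", "GO:0000099"),
                    evidence = "IDA", date = as.Date("2017-01-01"))
  expect_warning(tab <- propagate_true_path(rec, onto2, "BPO"), "skipped")
  expect_equal(attr(tab, "n_skipped"), 1L)
})

test_that("time split separates train and no-knowledge test proteins", {
  onto <- tiny_ontology()
  rec <- data.frame(
    protein = c("early", "early", "cross", "cross", "fresh", "fresh2"),
    term = "GO:0000003",
    evidence = "IDA",
    date = as.Date(c("2017-05-01", "2019-03-01",  # early: train (2017 anno)
                     "2017-02-01", "2019-06-01",  # cross: annotated pre-t0
                     "2019-04-01", "2018-05-01")),
    stringsAsFactors = FALSE)
  sp <- make_time_split(rec, onto, "BPO", t0 = "2018-01-01", t1 = "2020-01-01",
                        t_valid = "2019-01-01")
  expect_setequal(sp$train$proteins, c("early", "cross"))
  expect_setequal(sp$test$proteins, "fresh")       # cross has prior knowledge
  expect_setequal(sp$valid$proteins, "fresh2")
  # split soundness: no test protein annotated before the test window
  expect_true(all(!rec$protein[rec$date < as.Date("2019-01-01")] %in%
                    sp$test$proteins))
})

test_that("limited-knowledge proteins (annotated in another domain) are excluded", {
  onto <- tiny_ontology()
  onto$terms <- c(onto$terms, "GO:0000098")
  onto$parents[["GO:0000098"]] <- character(0)
  onto$domain <- c(onto$domain, stats::setNames("MFO", "GO:0000098"))
  onto$roots <- c(onto$roots, stats::setNames("GO:0000098", "MFO"))
  rec <- data.frame(
    protein = c("lim", "lim", "nk", "tr"),
    term = c("GO:0000098", "GO:0000003", "GO:0000003", "GO:0000003"),
    evidence = "IDA",
    date = as.Date(c("2017-03-01", "2019-05-01", "2019-05-01", "2016-01-01")),
    stringsAsFactors = FALSE)
  sp <- make_time_split(rec, onto, "BPO", t0 = "2018-01-01", t1 = "2020-01-01")
  expect_false("lim" %in% sp$test$proteins)  # MFO annotation before t0
  expect_true("nk" %in% sp$test$proteins)
  expect_error(
    make_time_split(rec[rec$protein == "tr", ], onto, "BPO",
                    "2018-01-01", "2020-01-01"),
    "empty test")
})

test_that("scored-term selection matches a column-sum oracle", {
  onto <- generate_dag(50, depth = 3, seed = 11)
  set.seed(12)
  rec <- data.frame(protein = sample(sprintf("p%d", 1:40), 200, replace = TRUE),
                    term = sample(onto$terms[-1], 200, replace = TRUE),
                    evidence = "EXP", date = as.Date("2017-01-01"))
  tab <- propagate_true_path(rec, onto, "BPO")
  expect_identical(select_scored_terms(tab, 0)$terms, tab$terms)  # identity
  thr <- select_scored_terms(tab, 10)
  expect_identical(thr$terms, tab$terms[Matrix::colSums(tab$matrix) >= 10])
  one <- select_scored_terms(tab, 2)
  expect_false(any(Matrix::colSums(one$matrix) < 2))
})

test_that("GAF reader maps columns 2/5/7/14", {
  gaf <- c("!gaf-version: 2.1",
           paste("UniProtKB", "P12345", "GENE", "", "GO:0000003", "PMID:1",
                 "IDA", "", "P", "", "", "protein", "taxon:9606", "20170215",
                 "UniProt", sep = "\t"))
  f <- tempfile(); writeLines(gaf, f)
  df <- read_gaf(f)
  expect_equal(df$protein, "P12345")
  expect_equal(df$term, "GO:0000003")
  expect_equal(df$evidence, "IDA")
  expect_equal(df$date, as.Date("2017-02-15"))
})
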