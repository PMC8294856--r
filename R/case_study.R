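# Published case-study term sets for the no-knowledge protein Q9BQD7.

#' Case-study BPO term sets for protein Q9BQD7
#'
#' The predicted BPO term sets of several function-prediction methods for
#' the no-knowledge human protein Q9BQD7, together with its 22 true BPO
#' terms (the domain root GO:0008150 omitted throughout), as published in
#' the case study this package's set-level F1 is validated against.
#' Q9BQD7 is a *difficult* protein with no training-set homolog at the
#' 0.001 e-value cutoff, so the homology-transfer method predicts nothing.
#'
#' @return Named list of character vectors: `truth` plus one entry per
#'   method (`gcn` is the graph convolutional model; `blast-knn` is empty).
#' @export
case_study_q9bqd7 <- function() {
  path <- system.file("extdata", "case_study_Q9BQD7_bpo.tsv",
                      package = "gognn", mustWork = TRUE)
  lines <- readLines(path, warn = FALSE)
  parts <- strsplit(lines, "\t", fixed = TRUE)
  sets <- lapply(parts, function(p) {
    if (length(p) < 2L) character(0) else strsplit(p[2L], ",", fixed = TRUE)[[1L]]
  })
  names(sets) <- vapply(parts, `[[`, character(1), 1L)
  sets
}
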