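# Serialization: CAFA prediction TSV, model checkpoints, metrics reports.

#' Write a score matrix in CAFA prediction format
#'
#' One `protein<TAB>GO term<TAB>score` line per pair with score above the
#' floor. Scores may optionally be rounded to 2 decimals (the CAFA
#' submission convention).
#'
#' @param scores A `score_matrix`.
#' @param path Output file.
#' @param floor Minimum score emitted (default 0: emit every pair).
#' @param round2 Round scores to 2 decimals.
#' @export
write_cafa_predictions <- function(scores, path, floor = 0, round2 = FALSE) {
  s <- scores$scores
  if (round2) s <- round(s, 2)
  idx <- which(s > floor | (floor == 0 & s >= 0), arr.ind = TRUE)
  if (floor > 0) idx <- which(s > floor, arr.ind = TRUE)
  df <- data.frame(protein = scores$proteins[idx[, 1L]],
                   term = scores$terms[idx[, 2L]],
                   score = s[idx])
  df <- df[order(df$protein, -df$score, df$term), ]
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
}

#' Read CAFA-format predictions into a score matrix
#' @param path Prediction TSV (protein, term, score).
#' @param proteins,terms Optional axes; defaults to those present.
#' @return A `score_matrix` (absent pairs score 0).
#' @export
read_cafa_predictions <- function(path, proteins = NULL, terms = NULL) {
  df <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE,
                          col.names = c("protein", "term", "score"))
  if (is.null(proteins)) proteins <- sort(unique(df$protein))
  if (is.null(terms)) terms <- sort(unique(df$term))
  s <- matrix(0, length(proteins), length(terms))
  keep <- df$protein %in% proteins & df$term %in% terms
  s[cbind(match(df$protein[keep], proteins), match(df$term[keep], terms))] <-
    df$score[keep]
  score_matrix(proteins, terms, s)
}

#' Save a trained model as a self-describing JSON checkpoint
#'
#' Stores shapes, the scored term list, a vocabulary hash and all parameter
#' arrays (column-major) in plain JSON.
#'
#' @param model A `gnn_model`.
#' @param path Output file.
#' @param vocabulary Optional `signature_vocabulary` to hash into the
#'   checkpoint for compatibility checking.
#' @export
save_checkpoint <- function(model, path, vocabulary = NULL) {
  payload <- list(
    class = "gnn_model",
    m = model$m, d = model$d, k_terms = model$k_terms,
    n_layers = model$n_layers, hidden_fc = isTRUE(model$hidden_fc),
    terms = model$terms,
    vocab_hash = if (is.null(vocabulary)) NULL else
      sum(utf8ToInt(paste(vocabulary$signatures, collapse = ""))),
    W0 = as.vector(model$W0), b0 = model$b0,
    W = lapply(model$W, as.vector), b = model$b,
    Wo = as.vector(model$Wo), bo = model$bo,
    Wh = if (isTRUE(model$hidden_fc)) as.vector(model$Wh) else NULL,
    bh = if (isTRUE(model$hidden_fc)) model$bh else NULL
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
}

#' Load a model checkpoint written by [save_checkpoint()]
#' @param path Checkpoint file.
#' @return A `gnn_model`.
#' @export
load_checkpoint <- function(path) {
  p <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  # fromJSON simplifies a list of equal-length vectors to a row-matrix
  relist <- function(v) {
    if (is.matrix(v)) lapply(seq_len(nrow(v)), function(i) v[i, ]) else
      as.list(v)
  }
  model <- list(
    W0 = matrix(p$W0, p$m, p$d), b0 = p$b0,
    W = lapply(relist(p$W), function(w) matrix(w, p$d, p$d)),
    b = relist(p$b),
    Wo = matrix(p$Wo, p$d, p$k_terms), bo = p$bo,
    m = p$m, d = p$d, k_terms = p$k_terms, n_layers = p$n_layers,
    hidden_fc = isTRUE(p$hidden_fc), terms = p$terms
  )
  if (model$hidden_fc) {
    model$Wh <- matrix(p$Wh, p$d, p$d)
    model$bh <- p$bh
  }
  class(model) <- "gnn_model"
  model
}

#' Write a metrics report as JSON plus a readable table
#' @param results Named list: method -> list of metric values.
#' @param path Output JSON path; a `.txt` table is written alongside.
#' @export
write_metrics_report <- function(results, path) {
  jsonlite::write_json(results, path, auto_unbox = TRUE, digits = NA)
  tab <- do.call(rbind, lapply(names(results), function(m) {
    data.frame(method = m,
               fmax = results[[m]]$fmax %||% NA,
               aupr = results[[m]]$aupr %||% NA,
               m_aupr = results[[m]]$m_aupr %||% NA)
  }))
  utils::write.table(format(tab, digits = 4), sub("\\.json$", ".txt", path),
                     sep = "\t", quote = FALSE, row.names = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
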