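# CAFA-style evaluation: protein-centric Fmax, pair-centric AUPR,
# term-centric M-AUPR, set-level F1, difficulty stratification and
# bootstrap significance comparison.

.align_scores_truth <- function(scores, truth) {
  stopifnot(inherits(scores, "score_matrix"), inherits(truth, "annotation_table"))
  p <- intersect(scores$proteins, truth$proteins)
  if (length(p) == 0L) stop("no shared proteins between scores and truth")
  terms <- truth$terms
  s <- matrix(0, length(p), length(terms))
  shared <- intersect(terms, scores$terms)
  s[, match(shared, terms)] <-
    scores$scores[match(p, scores$proteins), match(shared, scores$terms), drop = FALSE]
  y <- as.matrix(truth$matrix[match(p, truth$proteins), , drop = FALSE])
  list(proteins = p, s = s, y = y)
}

#' Protein-centric Fmax
#'
#' Sweeps a score threshold tau; at each tau, precision is averaged over the
#' h(tau) proteins predicting at least one term at or above tau, recall over
#' all N_T benchmark proteins. Fmax is the maximum harmonic mean (0/0 -> 0).
#' Truth must be propagated with the root excluded; only benchmark proteins
#' (rows with at least one true term) enter.
#'
#' @param scores A `score_matrix`.
#' @param truth An `annotation_table`.
#' @param step Threshold grid step over (0, 1] (default 0.01, the CAFA
#'   convention); ignored when `thresholds = "scores"`.
#' @param thresholds `"grid"` for the regular grid, `"scores"` to sweep
#'   every distinct positive score, or a numeric vector.
#' @return An `eval_result`: list with `fmax`, `tau_star`, `pr_curve`
#'   (data.frame tau, pr, rc, h), `n_benchmark`.
#' @export
fmax_protein <- function(scores, truth, step = 0.01, thresholds = "grid") {
  al <- .align_scores_truth(scores, truth)
  bench <- rowSums(al$y) > 0
  if (!any(bench)) stop("empty benchmark: no protein has a true term")
  s <- al$s[bench, , drop = FALSE]
  y <- al$y[bench, , drop = FALSE]
  n_t <- nrow(s)
  taus <- if (is.numeric(thresholds)) sort(unique(thresholds)) else
    if (identical(thresholds, "scores")) sort(unique(s[s > 0])) else
      seq(step, 1, by = step)

  npos <- rowSums(y)
  pr <- rc <- h <- numeric(length(taus))
  for (t in seq_along(taus)) {
    # tiny slack so grid thresholds built by seq() match equal scores exactly
    pred <- s >= taus[t] - 1e-9
    np <- rowSums(pred)
    tp <- rowSums(pred & (y > 0))
    has <- np > 0
    h[t] <- sum(has)
    pr[t] <- if (h[t] > 0) mean(tp[has] / np[has]) else 0
    rc[t] <- mean(tp / npos)
  }
  f <- ifelse(pr + rc > 0, 2 * pr * rc / (pr + rc), 0)
  best <- which.max(f)
  structure(
    list(fmax = f[best], tau_star = taus[best],
         pr_curve = data.frame(tau = taus, pr = pr, rc = rc, h = h),
         n_benchmark = n_t),
    class = "eval_result"
  )
}

#' @export
print.eval_result <- function(x, ...) {
  cat(sprintf("Fmax = %.4f at tau = %.3g (N_T = %d)\n",
              x$fmax, x$tau_star, x$n_benchmark))
  invisible(x)
}

# area under the PR step curve of a scored binary vector, ties grouped:
# pairs sharing a score enter the ranking together.
.aupr_vector <- function(score, label) {
  pos_total <- sum(label)
  if (pos_total == 0) stop("no positive pairs")
  o <- order(score, decreasing = TRUE)
  score <- score[o]; label <- label[o]
  grp <- cumsum(!duplicated(score))
  tp_g <- tapply(label, grp, sum)
  n_g <- tapply(rep(1, length(label)), grp, sum)
  tp <- cumsum(tp_g)
  n <- cumsum(n_g)
  prec <- tp / n
  dtp <- diff(c(0, tp))
  sum(prec * dtp) / pos_total
}

#' Pair-centric AUPR
#'
#' Pools every protein-term pair, ranks by score (ties grouped) and returns
#' the area under the precision-recall step curve.
#'
#' @inheritParams fmax_protein
#' @return Scalar AUPR.
#' @export
aupr_pairs <- function(scores, truth) {
  al <- .align_scores_truth(scores, truth)
  .aupr_vector(as.vector(al$s), as.vector(al$y) > 0)
}

#' Term-centric M-AUPR
#'
#' Mean per-term AUPR over terms annotated to at least `min_count` benchmark
#' proteins ("appearing more than twice" read as count >= 3); each term
#' ranks the test proteins by its column of scores.
#'
#' @inheritParams fmax_protein
#' @param min_count Minimum positives per scored term (default 3).
#' @return Scalar M-AUPR.
#' @export
m_aupr <- function(scores, truth, min_count = 3) {
  al <- .align_scores_truth(scores, truth)
  counts <- colSums(al$y)
  qual <- which(counts >= min_count)
  if (length(qual) == 0L) stop("no term with >= ", min_count, " annotations")
  mean(vapply(qual, function(j) .aupr_vector(al$s[, j], al$y[, j] > 0),
              numeric(1)))
}

#' Set-level F1 between a predicted and a true term set
#'
#' `precision = |intersection| / |predicted|`, `recall = |intersection| /
#' |truth|`, F1 their harmonic mean; an empty prediction scores 0. The
#' domain root is expected to be excluded from both sets.
#'
#' @param predicted Character vector of predicted terms.
#' @param truth Character vector of true terms (non-empty).
#' @return Scalar F1.
#' @export
f1_set <- function(predicted, truth) {
  truth <- unique(truth)
  if (length(truth) == 0L) stop("empty truth set")
  predicted <- unique(predicted)
  if (length(predicted) == 0L) return(0)
  tp <- length(intersect(predicted, truth))
  pr <- tp / length(predicted)
  rc <- tp / length(truth)
  if (pr + rc == 0) return(0)
  2 * pr * rc / (pr + rc)
}

#' Stratify test proteins by best training-set sequence identity
#'
#' A protein is *difficult* when the percent identity of its most similar
#' training protein is strictly below the threshold (no hit at all is also
#' difficult).
#'
#' @param proteins Test protein identifiers.
#' @param homology data.frame with `query`, `subject`, `pident` columns.
#' @param train_proteins Training-set identifiers.
#' @param threshold Identity threshold in percent (default 60).
#' @return Named character vector, "difficult" or "easy" per protein.
#' @export
stratify_difficult <- function(proteins, homology, train_proteins,
                               threshold = 60) {
  hom <- homology[homology$query %in% proteins &
                    homology$subject %in% train_proteins, , drop = FALSE]
  best <- tapply(hom$pident, hom$query, max)
  out <- stats::setNames(rep("difficult", length(proteins)), proteins)
  hit <- intersect(names(best), proteins)
  out[hit][best[hit] >= threshold] <- "easy"
  out
}

#' Bootstrap comparison of two score matrices
#'
#' Resamples the benchmark proteins with replacement `n_resamples` times,
#' computes the metric for both methods on each resample, and runs a paired
#' t-test on the differences. Zero-variance differences are flagged
#' degenerate: the p-value is 0 when the mean difference is nonzero
#' (maximal, perfectly consistent separation) and NaN when it is zero.
#'
#' @param scores_a,scores_b `score_matrix` objects over the same benchmark.
#' @param truth An `annotation_table`.
#' @param n_resamples Number of bootstrap resamples (default 100).
#' @param metric Function(scores, truth) -> scalar; default Fmax.
#' @param seed RNG seed.
#' @return List with `mean_diff`, `p_value`, `differences`, `degenerate`.
#' @export
bootstrap_compare <- function(scores_a, scores_b, truth, n_resamples = 100,
                              metric = function(s, t) fmax_protein(s, t)$fmax,
                              seed = 1L) {
  stopifnot(n_resamples >= 2)
  proteins <- intersect(intersect(scores_a$proteins, scores_b$proteins),
                        truth$proteins)
  bench <- proteins[Matrix::rowSums(
    truth$matrix[match(proteins, truth$proteins), , drop = FALSE]) > 0]
  set.seed(seed)
  diffs <- numeric(n_resamples)
  for (r in seq_len(n_resamples)) {
    pick <- sample(bench, length(bench), replace = TRUE)
    # resampled proteins get unique row names so duplicates count separately
    uid <- make.unique(pick)
    tr <- structure(list(
      proteins = uid, terms = truth$terms,
      matrix = truth$matrix[match(pick, truth$proteins), , drop = FALSE]),
      class = "annotation_table")
    rownames(tr$matrix) <- uid
    sa <- score_matrix(uid, scores_a$terms,
                       scores_a$scores[match(pick, scores_a$proteins), , drop = FALSE])
    sb <- score_matrix(uid, scores_b$terms,
                       scores_b$scores[match(pick, scores_b$proteins), , drop = FALSE])
    diffs[r] <- metric(sa, tr) - metric(sb, tr)
  }
  sdd <- stats::sd(diffs)
  if (sdd == 0) {
    p <- if (mean(diffs) == 0) NaN else 0
    degenerate <- TRUE
  } else {
    p <- stats::t.test(diffs)$p.value
    degenerate <- FALSE
  }
  list(mean_diff = mean(diffs), p_value = p, differences = diffs,
       degenerate = degenerate)
}
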