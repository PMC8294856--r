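# GO DAG handling: OBO parsing, true-path propagation, benchmark splits.

#' Default experimental evidence codes
#'
#' The accept-list used for building benchmarks: annotations supported by
#' direct experimental evidence or curator statements. `TAS` is accepted
#' under both its standard spelling and the abbreviation `TA`.
#'
#' @return Character vector of evidence codes.
#' @export
experimental_evidence_codes <- function() {
  c("IDA", "IPI", "EXP", "IGI", "IMP", "IEP", "IC", "TAS", "TA")
}

go_domain_labels <- c(
  molecular_function = "MFO",
  biological_process = "BPO",
  cellular_component = "CCO"
)

#' Parse a Gene Ontology OBO file
#'
#' Reads the OBO 1.2 dialect: `[Term]` stanzas with `id`, `name`,
#' `namespace`, `is_a` and `relationship: part_of` lines. Obsolete terms are
#' dropped. Only `is_a` and `part_of` edges are kept (the true-path rule is
#' defined over these), and a parent link that crosses GO domains is severed
#' so each domain forms its own DAG.
#'
#' @param path Path to an OBO file, or a character vector of its lines.
#' @return An object of class `go_ontology`: a list with `terms` (character
#'   vector), `parents` (named list, term -> character vector of direct
#'   parents), `domain` (named character, one of MFO/BPO/CCO) and `roots`
#'   (named character, domain -> root term).
#' @export
load_obo <- function(path) {
  lines <- if (length(path) == 1L && file.exists(path)) readLines(path, warn = FALSE) else path
  lines <- trimws(lines)

  # split into stanzas
  starts <- which(lines == "[Term]")
  if (length(starts) == 0L) stop("no [Term] stanzas found in OBO input")
  ends <- c(which(grepl("^\\[", lines))[-1L] - 1L, length(lines))
  ends <- vapply(starts, function(s) min(ends[ends >= s]), integer(1))

  ids <- character(0); dom <- character(0)
  parents <- list()
  for (k in seq_along(starts)) {
    chunk <- lines[starts[k]:ends[k]]
    get1 <- function(key) {
      v <- chunk[startsWith(chunk, paste0(key, ":"))]
      if (length(v) == 0L) return(NA_character_)
      trimws(sub(paste0("^", key, ":"), "", v[1L]))
    }
    if (identical(get1("is_obsolete"), "true")) next
    id <- get1("id")
    if (is.na(id)) next
    ns <- get1("namespace")
    isa <- chunk[startsWith(chunk, "is_a:")]
    isa <- sub("^is_a:\\s*", "", isa)
    isa <- trimws(sub("!.*$", "", isa))
    rel <- chunk[startsWith(chunk, "relationship:")]
    rel <- trimws(sub("^relationship:\\s*", "", rel))
    po <- rel[startsWith(rel, "part_of")]
    po <- trimws(sub("!.*$", "", sub("^part_of\\s*", "", po)))
    isa <- isa[nzchar(isa)]
    po <- po[nzchar(po)]
    ids <- c(ids, id)
    dom <- c(dom, if (is.na(ns)) NA_character_ else unname(go_domain_labels[ns]))
    parents[[id]] <- unique(c(isa, po))
  }
  names(dom) <- ids

  unknown <- setdiff(unlist(parents), ids)
  if (length(unknown) > 0L) {
    stop("unknown parent reference(s) in OBO input: ", paste(unknown, collapse = ", "))
  }
  # sever cross-domain parent links
  for (id in ids) {
    p <- parents[[id]]
    parents[[id]] <- p[!is.na(dom[p]) & dom[p] == dom[id]]
  }
  roots <- ids[vapply(parents[ids], length, integer(1)) == 0L]
  root_map <- stats::setNames(roots, dom[roots])

  onto <- structure(
    list(terms = ids, parents = parents, domain = dom, roots = root_map),
    class = "go_ontology"
  )
  .check_acyclic(onto)
  onto
}

# depth-first cycle check; reports one offending edge
.check_acyclic <- function(ontology) {
  color <- stats::setNames(integer(length(ontology$terms)), ontology$terms)
  visit <- function(v) {
    color[[v]] <<- 1L
    for (p in ontology$parents[[v]]) {
      if (color[[p]] == 1L) stop("cycle detected in ontology at edge ", v, " -> ", p)
      if (color[[p]] == 0L) visit(p)
    }
    color[[v]] <<- 2L
  }
  for (t in ontology$terms) if (color[[t]] == 0L) visit(t)
  invisible(TRUE)
}

#' @export
print.go_ontology <- function(x, ...) {
  cat("go_ontology:", length(x$terms), "terms;",
      paste(sprintf("%s (root %s)", names(x$roots), x$roots), collapse = ", "), "\n")
  invisible(x)
}

#' All ancestors of each term (true-path closure)
#'
#' @param ontology A `go_ontology`.
#' @param include_self Include the term itself in its closure.
#' @return Named list: term -> character vector of ancestors.
#' @export
term_ancestors <- function(ontology, include_self = TRUE) {
  memo <- new.env(parent = emptyenv())
  anc <- function(t) {
    if (!is.null(memo[[t]])) return(memo[[t]])
    out <- unique(unlist(c(
      list(ontology$parents[[t]]),
      lapply(ontology$parents[[t]], anc)
    )))
    if (is.null(out)) out <- character(0)
    memo[[t]] <- out
    out
  }
  res <- lapply(ontology$terms, function(t) {
    a <- anc(t)
    if (include_self) unique(c(t, a)) else a
  })
  names(res) <- ontology$terms
  res
}

#' Read annotation records from TSV
#'
#' Columns: protein, GO term, evidence code, ISO-8601 date.
#'
#' @param path TSV path (no header).
#' @return data.frame with columns protein, term, evidence, date (Date).
#' @export
read_annotation_tsv <- function(path) {
  df <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE,
                          col.names = c("protein", "term", "evidence", "date"))
  df$date <- as.Date(df$date)
  df
}

#' Read annotation records from a GAF 2.x file
#'
#' Maps GAF columns 2 (DB object id), 5 (GO id), 7 (evidence code) and
#' 14 (date, YYYYMMDD). Comment lines and qualifier semantics are ignored.
#'
#' @param path GAF path.
#' @return data.frame as [read_annotation_tsv()].
#' @export
read_gaf <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!startsWith(lines, "!") & nzchar(lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  ok <- vapply(fields, length, integer(1)) >= 14L
  fields <- fields[ok]
  data.frame(
    protein = vapply(fields, `[[`, character(1), 2L),
    term = vapply(fields, `[[`, character(1), 5L),
    evidence = vapply(fields, `[[`, character(1), 7L),
    date = as.Date(vapply(fields, `[[`, character(1), 14L), format = "%Y%m%d"),
    stringsAsFactors = FALSE
  )
}

#' Filter annotation records by evidence code
#'
#' @param records data.frame with an `evidence` column.
#' @param accepted Character vector of accepted codes; defaults to the
#'   experimental accept-list.
#' @return The surviving rows, original order preserved.
#' @export
filter_evidence <- function(records, accepted = experimental_evidence_codes()) {
  stopifnot(length(accepted) > 0L)
  records[records$evidence %in% accepted, , drop = FALSE]
}

#' Propagate annotations up the GO DAG (true-path rule)
#'
#' Each protein's term set becomes the union of ancestor closures of its
#' directly annotated terms, restricted to one GO domain. The domain root is
#' excluded from the scored term set by default (every annotated protein
#' would trivially carry it).
#'
#' @param records data.frame with `protein` and `term` columns.
#' @param ontology A `go_ontology`.
#' @param domain One of "MFO", "BPO", "CCO".
#' @param keep_root Keep the domain root as a scored column (default FALSE).
#' @return An `annotation_table`: list with `proteins`, `terms` and a sparse
#'   binary `matrix` (proteins x terms). Records whose term is missing from
#'   the ontology or belongs to another domain are skipped; the number
#'   skipped is attached as attribute `n_skipped` (with a warning).
#' @export
propagate_true_path <- function(records, ontology, domain, keep_root = FALSE) {
  stopifnot(domain %in% c("MFO", "BPO", "CCO"))
  in_onto <- records$term %in% ontology$terms
  in_dom <- in_onto & ontology$domain[records$term] == domain
  n_skipped <- sum(!in_dom)
  if (n_skipped > 0L) {
    warning(n_skipped, " record(s) outside ontology/domain skipped")
  }
  rec <- records[in_dom, , drop = FALSE]

  anc <- term_ancestors(ontology, include_self = TRUE)
  proteins <- unique(rec$protein)
  dom_terms <- ontology$terms[ontology$domain == domain]
  root <- unname(ontology$roots[[domain]])
  terms <- if (keep_root) dom_terms else setdiff(dom_terms, root)

  per_protein <- split(rec$term, factor(rec$protein, levels = proteins))
  closure <- lapply(per_protein, function(ts) intersect(terms, unique(unlist(anc[ts]))))

  i <- rep.int(seq_along(proteins), vapply(closure, length, integer(1)))
  j <- match(unlist(closure), terms)
  mat <- Matrix::sparseMatrix(i = i, j = j, x = 1,
                              dims = c(length(proteins), length(terms)),
                              dimnames = list(proteins, terms))
  structure(
    list(proteins = proteins, terms = terms, matrix = mat),
    n_skipped = n_skipped, domain = domain, class = "annotation_table"
  )
}

#' @export
print.annotation_table <- function(x, ...) {
  cat("annotation_table:", length(x$proteins), "proteins x", length(x$terms),
      "terms;", Matrix::nnzero(x$matrix), "annotations\n")
  invisible(x)
}

#' Restrict an annotation table to a protein set (kept order)
#' @param table An `annotation_table`.
#' @param proteins Proteins to keep; those absent from the table get all-zero
#'   rows.
#' @return An `annotation_table` over `proteins`.
#' @export
subset_annotation <- function(table, proteins) {
  mat <- Matrix::sparseMatrix(i = integer(0), j = integer(0), x = numeric(0),
                              dims = c(length(proteins), length(table$terms)),
                              dimnames = list(proteins, table$terms))
  hit <- proteins %in% table$proteins
  mat[hit, ] <- table$matrix[match(proteins[hit], table$proteins), , drop = FALSE]
  structure(list(proteins = proteins, terms = table$terms, matrix = mat),
            domain = attr(table, "domain"), class = "annotation_table")
}

#' Time-stamped no-knowledge benchmark split
#'
#' Training proteins carry at least one accepted in-domain annotation dated
#' before `t0`. Test proteins are *no-knowledge*: no accepted annotation in
#' ANY domain before the test window opens, and at least one in-domain
#' annotation inside it. When `t_valid` is supplied the validation set holds
#' no-knowledge proteins (relative to `t0`) first annotated in `[t0,
#' t_valid)` and the test window becomes `[t_valid, t1)`; otherwise the test
#' window is `[t0, t1)` and the validation set is empty. Windows are
#' half-open at day granularity.
#'
#' @param records Evidence-filtered annotation data.frame (protein, term,
#'   evidence, date).
#' @param ontology A `go_ontology`.
#' @param domain Target GO domain.
#' @param t0,t1 Window boundaries (coerced with `as.Date`), `t0 < t1`.
#' @param t_valid Optional boundary between validation and test windows.
#' @return A `benchmark_split`: list with `train`, `valid`, `test`
#'   annotation tables (propagated), plus `t0`, `t1`.
#' @export
make_time_split <- function(records, ontology, domain, t0, t1, t_valid = NULL) {
  t0 <- as.Date(t0); t1 <- as.Date(t1)
  stopifnot(t0 < t1)
  if (!is.null(t_valid)) {
    t_valid <- as.Date(t_valid)
    stopifnot(t0 < t_valid, t_valid < t1)
  }
  dom_of <- function(term) ontology$domain[term]
  in_dom <- records$term %in% ontology$terms & dom_of(records$term) == domain

  first_any <- tapply(records$date, records$protein, min)
  first_any <- as.Date(first_any, origin = "1970-01-01")

  train_prot <- unique(records$protein[in_dom & records$date < t0])

  window_set <- function(w0, w1) {
    nk <- names(first_any)[first_any >= w0]   # no accepted annotation in any domain before w0
    gain <- unique(records$protein[in_dom & records$date >= w0 & records$date < w1])
    intersect(gain, nk)
  }
  if (is.null(t_valid)) {
    valid_prot <- character(0)
    test_prot <- window_set(t0, t1)
  } else {
    valid_prot <- window_set(t0, t_valid)
    test_prot <- window_set(t_valid, t1)
  }
  if (length(train_prot) == 0L) {
    stop("empty training set for window before ", format(t0))
  }
  if (length(test_prot) == 0L) {
    stop("empty test set for window [", format(if (is.null(t_valid)) t0 else t_valid),
         ", ", format(t1), ")")
  }
  tab_for <- function(prot) {
    rec <- records[records$protein %in% prot, , drop = FALSE]
    tab <- propagate_true_path(rec, ontology, domain)
    subset_annotation(tab, prot)
  }
  structure(
    list(train = tab_for(train_prot),
         valid = if (length(valid_prot)) tab_for(valid_prot) else NULL,
         test = tab_for(test_prot),
         t0 = t0, t1 = t1),
    class = "benchmark_split"
  )
}

#' @export
print.benchmark_split <- function(x, ...) {
  cat("benchmark_split: train", length(x$train$proteins),
      "/ valid", if (is.null(x$valid)) 0L else length(x$valid$proteins),
      "/ test", length(x$test$proteins), "proteins\n")
  invisible(x)
}

#' Restrict scored terms to those with enough training support
#'
#' @param table An `annotation_table` (training set).
#' @param min_train_count Keep terms annotated to at least this many
#'   training proteins (default 0 = keep all). Column order is preserved.
#' @return The filtered `annotation_table`.
#' @export
select_scored_terms <- function(table, min_train_count = 0) {
  stopifnot(min_train_count >= 0)
  keep <- Matrix::colSums(table$matrix) >= min_train_count
  structure(
    list(proteins = table$proteins, terms = table$terms[keep],
         matrix = table$matrix[, keep, drop = FALSE]),
    domain = attr(table, "domain"), class = "annotation_table"
  )
}

#' Align an annotation table to a fixed term list
#' @param table An `annotation_table`.
#' @param terms Target column order; missing terms become zero columns.
#' @return An `annotation_table` with columns `terms`.
#' @export
align_terms <- function(table, terms) {
  mat <- Matrix::sparseMatrix(i = integer(0), j = integer(0), x = numeric(0),
                              dims = c(length(table$proteins), length(terms)),
                              dimnames = list(table$proteins, terms))
  hit <- terms %in% table$terms
  mat[, hit] <- table$matrix[, match(terms[hit], table$terms), drop = FALSE]
  structure(list(proteins = table$proteins, terms = terms, matrix = mat),
            domain = attr(table, "domain"), class = "annotation_table")
}
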