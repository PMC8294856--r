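# InterPro signature features: the N x m sparse binary node-feature matrix.

#' Read InterProScan tabular output
#'
#' The InterProScan TSV has 11-15 tab-separated columns; column 1 is the
#' protein accession, column 5 the member-database signature and column 12
#' the integrated InterPro entry accession (may be "-"). By default the
#' InterPro entry is used as the signature identity, since it integrates the
#' member databases into one vocabulary.
#'
#' @param path TSV path or character vector of lines.
#' @param use_entry Use column 12 (InterPro entry) if TRUE, column 5
#'   (member-database signature) otherwise.
#' @return Named list: protein -> character vector of signature accessions.
#'   Malformed lines (fewer than 12 columns) are skipped; their count is in
#'   attribute `n_skipped`. All lines malformed is an error.
#' @export
read_interproscan_tsv <- function(path, use_entry = TRUE) {
  lines <- if (length(path) == 1L && file.exists(path)) readLines(path, warn = FALSE) else path
  lines <- lines[nzchar(lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  need <- if (use_entry) 12L else 5L
  ok <- vapply(fields, length, integer(1)) >= need
  if (length(lines) > 0L && !any(ok)) stop("all InterProScan lines malformed")
  n_skipped <- sum(!ok)
  if (n_skipped > 0L) message(n_skipped, " malformed InterProScan line(s) skipped")
  fields <- fields[ok]
  prot <- vapply(fields, `[[`, character(1), 1L)
  acc <- vapply(fields, `[[`, character(1), need)
  keep <- !is.na(acc) & nzchar(acc) & acc != "-"
  hits <- lapply(split(acc[keep], prot[keep]), unique)
  attr(hits, "n_skipped") <- n_skipped
  hits
}

#' Build the signature vocabulary
#'
#' The vocabulary is the set of signatures hitting at least one of the given
#' proteins, in lexicographic column order (frozen before any test-time
#' vectorization).
#'
#' @param hits Named list protein -> signature accessions.
#' @param proteins Proteins defining the vocabulary (training plus network
#'   proteins, typically).
#' @return A `signature_vocabulary`: list with `signatures` (ordered) and
#'   `index` (named integer map).
#' @export
build_vocabulary <- function(hits, proteins) {
  stopifnot(length(proteins) > 0L)
  sigs <- sort(unique(unlist(hits[intersect(names(hits), proteins)])))
  if (length(sigs) == 0L) stop("empty signature vocabulary")
  structure(
    list(signatures = sigs,
         index = stats::setNames(seq_along(sigs), sigs)),
    class = "signature_vocabulary"
  )
}

#' Vectorize signature hits against a frozen vocabulary
#'
#' Out-of-vocabulary accessions (signatures first seen at test time) are
#' silently dropped; proteins without hits get all-zero rows.
#'
#' @param hits Named list protein -> signature accessions.
#' @param vocabulary A `signature_vocabulary`.
#' @param proteins Row order of the result.
#' @return A `signature_matrix`: list with `proteins`, `vocabulary` and
#'   sparse binary `matrix` (N x m).
#' @export
vectorize_signatures <- function(hits, vocabulary, proteins) {
  per <- lapply(proteins, function(p) {
    v <- vocabulary$index[intersect(hits[[p]], vocabulary$signatures)]
    as.integer(v)
  })
  i <- rep.int(seq_along(proteins), vapply(per, length, integer(1)))
  j <- unlist(per)
  if (is.null(j)) j <- integer(0)
  mat <- Matrix::sparseMatrix(i = i, j = j, x = 1,
                              dims = c(length(proteins), length(vocabulary$signatures)),
                              dimnames = list(proteins, vocabulary$signatures))
  structure(list(proteins = proteins, vocabulary = vocabulary, matrix = mat),
            class = "signature_matrix")
}

#' @export
print.signature_matrix <- function(x, ...) {
  cat("signature_matrix:", length(x$proteins), "proteins x",
      length(x$vocabulary$signatures), "signatures;",
      Matrix::nnzero(x$matrix), "hits\n")
  invisible(x)
}

#' Write a signature matrix as coordinate text with a JSON header
#' @param x A `signature_matrix`.
#' @param path Output file.
#' @export
write_signature_matrix <- function(x, path) {
  header <- jsonlite::toJSON(list(proteins = x$proteins,
                                  signatures = x$vocabulary$signatures),
                             auto_unbox = FALSE)
  coo <- Matrix::summary(x$matrix)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("#", header), con)
  utils::write.table(coo[, c("i", "j")], con, sep = "\t",
                     row.names = FALSE, col.names = FALSE)
}

#' Read a signature matrix written by [write_signature_matrix()]
#' @param path Input file.
#' @return A `signature_matrix`.
#' @export
read_signature_matrix <- function(path) {
  lines <- readLines(path, warn = FALSE)
  header <- jsonlite::fromJSON(sub("^#", "", lines[1L]))
  vocab <- structure(
    list(signatures = header$signatures,
         index = stats::setNames(seq_along(header$signatures), header$signatures)),
    class = "signature_vocabulary"
  )
  body <- lines[-1L][nzchar(lines[-1L])]
  ij <- if (length(body)) do.call(rbind, lapply(strsplit(body, "\t"), as.integer)) else
    matrix(integer(0), 0, 2)
  mat <- Matrix::sparseMatrix(i = ij[, 1], j = ij[, 2], x = 1,
                              dims = c(length(header$proteins), length(header$signatures)),
                              dimnames = list(header$proteins, header$signatures))
  structure(list(proteins = header$proteins, vocabulary = vocab, matrix = mat),
            class = "signature_matrix")
}
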