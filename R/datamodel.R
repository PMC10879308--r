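# Labeled-matrix containers and on-disk formats.
#
# Both container types are plain base matrices with row/column names
# carrying the entity identifiers; the as_* validators enforce the
# type invariants and are called at every module boundary that accepts
# user input.

#' Validate a similarity matrix
#'
#' A similarity matrix is square, symmetric (within `tol`), has unit
#' diagonal and all values in \[0, 1\].  Row and column names carry the
#' entity identifiers and must match.
#'
#' @param m numeric matrix with row and column names.
#' @param tol symmetry tolerance (default `1e-8`).
#' @param check_diag require a unit diagonal (default `TRUE`).
#' @return the validated matrix, unchanged.
#' @examples
#' s <- diag(2); dimnames(s) <- list(c("a", "b"), c("a", "b"))
#' as_similarity_matrix(s)
#' @export
as_similarity_matrix <- function(m, tol = 1e-8, check_diag = TRUE) {
  if (!is.matrix(m) || !is.numeric(m)) abort("similarity input must be a numeric matrix")
  if (nrow(m) != ncol(m)) abort("similarity matrix must be square, got %dx%d", nrow(m), ncol(m))
  ids <- rownames(m)
  if (is.null(ids) || is.null(colnames(m))) abort("similarity matrix must carry row and column names")
  if (!identical(ids, colnames(m))) abort("similarity matrix row and column names differ")
  if (anyDuplicated(ids)) abort("duplicate entity identifiers: %s",
                                paste(unique(ids[duplicated(ids)]), collapse = ", "))
  if (anyNA(m)) abort("similarity matrix contains missing values")
  asym <- max(abs(m - t(m)))
  if (asym > tol) abort("similarity matrix is asymmetric beyond tolerance (max |S - t(S)| = %g)", asym)
  if (min(m) < -tol || max(m) > 1 + tol) {
    abort("similarity values must lie in [0, 1]; observed range [%g, %g]", min(m), max(m))
  }
  if (check_diag && any(abs(diag(m) - 1) > tol)) {
    bad <- ids[which(abs(diag(m) - 1) > tol)[1]]
    abort("similarity diagonal must equal 1 (entity '%s')", bad)
  }
  m
}

#' Validate a drug x disease association matrix
#'
#' Raw association matrices are strictly binary; matrices produced by
#' the completion stage (`completed = TRUE`) may hold any non-negative
#' real scores.
#'
#' @param m numeric matrix, rows = drugs, columns = diseases, with
#'   row/column names.
#' @param completed allow non-negative reals instead of \{0, 1\}.
#' @return the validated matrix, unchanged.
#' @export
as_association_matrix <- function(m, completed = FALSE) {
  if (!is.matrix(m) || !is.numeric(m)) abort("association input must be a numeric matrix")
  if (is.null(rownames(m)) || is.null(colnames(m))) {
    abort("association matrix must carry drug (row) and disease (column) names")
  }
  if (anyDuplicated(rownames(m))) abort("duplicate drug identifiers")
  if (anyDuplicated(colnames(m))) abort("duplicate disease identifiers")
  if (anyNA(m)) abort("association matrix contains missing values")
  if (completed) {
    if (min(m) < 0) abort("completed association scores must be non-negative")
  } else if (!all(m == 0 | m == 1)) {
    bad <- which(m != 0 & m != 1, arr.ind = TRUE)[1, ]
    abort("raw association values must be 0 or 1; found %g at (%s, %s)",
          m[bad[1], bad[2]], rownames(m)[bad[1]], colnames(m)[bad[2]])
  }
  m
}

#' Read a labeled matrix from TSV (or CSV)
#'
#' The canonical on-disk format is a delimited table with one header
#' row of column identifiers and a first column of row identifiers.
#'
#' @param path file path.
#' @param kind one of `"similarity"`, `"association"`, `"numeric"`
#'   (no validation beyond numeric parsing).
#' @param completed for `kind = "association"`, accept completed
#'   (real-valued) matrices.
#' @param sep field delimiter; `"\t"` by default, `","` for CSV.
#' @return a validated labeled matrix.
#' @export
read_labeled_matrix <- function(path, kind = c("similarity", "association", "numeric"),
                                completed = FALSE, sep = "\t") {
  kind <- match.arg(kind)
  if (!file.exists(path)) abort("no such file: '%s'", path)
  raw <- utils::read.table(path, header = TRUE, sep = sep, check.names = FALSE,
                           colClasses = "character", quote = "", comment.char = "")
  if (ncol(raw) < 2) abort("'%s': expected row-label column plus numeric columns", path)
  row_ids <- raw[[1]]
  body <- as.matrix(raw[, -1, drop = FALSE])
  vals <- suppressWarnings(array(as.numeric(body), dim = dim(body)))
  if (anyNA(vals)) {
    bad <- which(is.na(vals), arr.ind = TRUE)[1, ]
    abort("'%s': non-numeric cell '%s' at row '%s', column '%s'",
          path, body[bad[1], bad[2]], row_ids[bad[1]], colnames(body)[bad[2]])
  }
  dimnames(vals) <- list(row_ids, colnames(body))
  switch(kind,
         similarity = as_similarity_matrix(vals),
         association = as_association_matrix(vals, completed = completed),
         numeric = {
           if (anyDuplicated(row_ids)) abort("'%s': duplicate row identifiers", path)
           vals
         })
}

#' Write a labeled matrix as TSV (or CSV)
#'
#' Inverse of [read_labeled_matrix()]; written atomically.
#'
#' @param m labeled numeric matrix.
#' @param path destination path.
#' @param sep field delimiter.
#' @return `path`, invisibly.
#' @export
write_labeled_matrix <- function(m, path, sep = "\t") {
  if (is.null(rownames(m)) || is.null(colnames(m))) abort("matrix must carry dimnames")
  atomic_write(path, function(tmp) {
    df <- data.frame(id = rownames(m), m, check.names = FALSE, stringsAsFactors = FALSE)
    utils::write.table(df, tmp, sep = sep, quote = FALSE, row.names = FALSE, col.names = TRUE)
  })
}

#' Write ranked predictions as TSV
#'
#' @param predictions data.frame with columns `drug_id`, `disease_id`,
#'   `distance`, `rank` (as produced by [rank_candidates()]); distances
#'   must be non-negative and ranks start at 1 within each drug.  Ties
#'   in distance are expected to be already broken by partner id.
#' @param path destination path.
#' @return `path`, invisibly.
#' @export
write_ranked_predictions <- function(predictions, path) {
  needed <- c("drug_id", "disease_id", "distance", "rank")
  if (!all(needed %in% names(predictions))) {
    abort("predictions must have columns %s", paste(needed, collapse = ", "))
  }
  if (nrow(predictions) > 0) {
    if (any(predictions$distance < 0)) abort("prediction distances must be non-negative")
    if (any(predictions$rank < 1)) abort("ranks must start at 1")
    predictions <- predictions[order(predictions$drug_id, predictions$rank), needed]
  } else {
    predictions <- predictions[, needed]
  }
  atomic_write(path, function(tmp) {
    utils::write.table(predictions, tmp, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = TRUE)
  })
}
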