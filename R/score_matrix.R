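#' Construct a rater-attributed score matrix
#'
#' A score matrix is the universal currency of the pipeline: an integer
#' matrix of criterion scores (1--5, higher = greater unmet need) with
#' disease ids as row names, criterion names as column names, and the
#' rater's identity attached as an attribute. Missing cells are `NA`;
#' downstream statistics refuse missing values rather than imputing.
#'
#' @param scores Numeric matrix with disease-id row names and
#'   criterion-name column names.
#' @param rater_id Identifier of the rater that produced the scores.
#' @return A `score_matrix` object.
#' @examples
#' m <- score_matrix(matrix(3L, 2, 11,
#'   dimnames = list(c("MONDO:0000001", "MONDO:0000002"),
#'                   default_criteria()$name)), rater_id = "expert1")
#' @export
score_matrix <- function(scores, rater_id = NA_character_) {
  stopifnot(is.matrix(scores))
  if (is.null(rownames(scores)) || is.null(colnames(scores))) {
    stop_umni("score matrix needs disease-id row names and criterion column names")
  }
  storage.mode(scores) <- "double"
  structure(scores, rater_id = rater_id, class = c("score_matrix", "matrix"))
}

#' @export
print.score_matrix <- function(x, ...) {
  cat("<score_matrix> rater:", attr(x, "rater_id"), "-",
      nrow(x), "diseases x", ncol(x), "criteria\n")
  print(utils::head(unclass(x), 6L))
  if (nrow(x) > 6L) cat("... (", nrow(x) - 6L, " more rows)\n", sep = "")
  invisible(x)
}

#' Rater attached to a score matrix
#' @param m A `score_matrix`.
#' @return The rater id string.
#' @export
rater_id <- function(m) attr(m, "rater_id")

#' Audit a score matrix for invalid cells
#'
#' Enumerates every present (non-`NA`) cell that is not an integer in
#' \[1, 5\]. Violations are data, not exceptions: an empty report means the
#' matrix is clean. This mirrors the output-auditing step of the scoring
#' workflow, which checks generated scores for inappropriate values such as
#' non-integers before any downstream analysis.
#'
#' @param m A `score_matrix` (or plain named matrix).
#' @return Data frame with one row per violation: `disease_id`,
#'   `criterion`, `value`, `reason` (`"noninteger"` or `"out of range"`).
#' @export
validate_scores <- function(m) {
  stopifnot(is.matrix(m))
  idx <- which(!is.na(m))
  v <- m[idx]
  nonint <- !is_wholenumber(v)
  oor <- !nonint & (v < 1 | v > 5)
  bad <- idx[nonint | oor]
  reason <- c(rep("noninteger", sum(nonint)), rep("out of range", sum(oor)))
  ord <- order(c(idx[nonint], idx[oor]))
  bad_all <- c(idx[nonint], idx[oor])[ord]
  data.frame(
    disease_id = rownames(m)[(bad_all - 1L) %% nrow(m) + 1L],
    criterion = colnames(m)[(bad_all - 1L) %/% nrow(m) + 1L],
    value = m[bad_all],
    reason = reason[ord],
    stringsAsFactors = FALSE
  )
}

#' Read and write score matrices as CSV
#'
#' The frozen score-file dialect: UTF-8 CSV whose header row is
#' `disease_id` followed by the criterion names, one row per disease,
#' integer cells (empty for missing). Writing then reading reproduces the
#' matrix cell-for-cell.
#'
#' @param path File path.
#' @param m A `score_matrix`.
#' @param rater_id Rater identity to attach on read (not stored in the CSV).
#' @return `read_score_csv()` returns a `score_matrix`; `write_score_csv()`
#'   returns `path` invisibly.
#' @export
read_score_csv <- function(path, rater_id = NA_character_) {
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE,
                        fileEncoding = "UTF-8")
  if (!ncol(df) || names(df)[1L] != "disease_id") {
    stop_umni("score CSV must have 'disease_id' as its first column: ", path)
  }
  ids <- as.character(df[[1L]])
  mat <- as.matrix(df[, -1L, drop = FALSE])
  storage.mode(mat) <- "double"
  rownames(mat) <- ids
  score_matrix(mat, rater_id = rater_id)
}

#' @rdname read_score_csv
#' @export
write_score_csv <- function(m, path) {
  df <- data.frame(disease_id = rownames(m), unclass(m),
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE,
                   fileEncoding = "UTF-8", na = "")
  invisible(path)
}

# Check two matrices share an identical disease x criterion grid.
check_aligned <- function(a, b, what = c("a", "b")) {
  row_miss <- c(setdiff(rownames(a), rownames(b)), setdiff(rownames(b), rownames(a)))
  col_miss <- c(setdiff(colnames(a), colnames(b)), setdiff(colnames(b), colnames(a)))
  if (length(row_miss) || length(col_miss)) {
    stop_umni(
      "score matrices are not aligned; offending keys: ",
      paste(unique(c(row_miss, col_miss)), collapse = ", ")
    )
  }
  b[rownames(a), colnames(a), drop = FALSE]
}
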