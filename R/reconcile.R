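#' Tabulate disagreements between two raters
#'
#' Counts cells by absolute score difference band (0, 1, 2, >=3) over an
#' identical disease x criterion grid, with percentages of the total cell
#' count rounded to two decimals. The tabulation is symmetric in the two
#' raters and invariant under cell permutation.
#'
#' @param a,b Complete [score_matrix()] objects over the same grid.
#' @return A `disagreement_table` list: `counts` (named by band), `total`,
#'   `percent` (named by band, two decimals).
#' @examples
#' cn <- default_criteria()$name
#' m <- score_matrix(matrix(3, 4, 11, dimnames = list(paste0("MONDO:000000", 1:4), cn)))
#' diff_histogram(m, m)$counts
#' @export
diff_histogram <- function(a, b) {
  b <- check_aligned(a, b)
  if (anyNA(a) || anyNA(b)) {
    stop_umni("diff_histogram requires complete matrices")
  }
  d <- abs(as.numeric(a) - as.numeric(b))
  band <- cut(d, breaks = c(-0.5, 0.5, 1.5, 2.5, Inf),
              labels = c("0", "1", "2", ">=3"))
  counts <- table(band)
  total <- length(d)
  structure(list(
    counts = stats::setNames(as.integer(counts), names(counts)),
    total = total,
    percent = stats::setNames(round(100 * as.integer(counts) / total, 2), names(counts))
  ), class = "disagreement_table")
}

#' @export
print.disagreement_table <- function(x, ...) {
  cat("<disagreement_table>", x$total, "cells\n")
  df <- data.frame(`|diff|` = names(x$counts), count = x$counts,
                   percent = x$percent, check.names = FALSE)
  print(df, row.names = FALSE)
  invisible(x)
}

#' Reconcile two raters with a third-rater mediator
#'
#' Implements the two-expert reconciliation rule: one-point differences are
#' accepted as a reasonable margin of uncertainty and the consensus is the
#' arithmetic mean of the two scores (half-integers permitted in consensus
#' space); differences greater than one point are mediated — the
#' mediator's score is taken verbatim and the triple is logged. After
#' mediation every consensus cell lies within one point of at least one of
#' the two original raters.
#'
#' @param a,b Complete [score_matrix()] objects over the same grid.
#' @param mediator A [score_matrix()] providing a value for every cell
#'   with `|a - b| > 1` (other cells may be missing).
#' @return List: `consensus` (numeric matrix, same grid), `log` (data
#'   frame `disease_id`, `criterion`, `a`, `b`, `mediator`, `consensus`,
#'   one row per mediated cell).
#' @export
mediate <- function(a, b, mediator = NULL) {
  b <- check_aligned(a, b)
  if (anyNA(a) || anyNA(b)) stop_umni("mediate requires complete matrices")
  d <- abs(unclass(a) - unclass(b))
  consensus <- (unclass(a) + unclass(b)) / 2
  need <- which(d > 1)
  log <- data.frame(
    disease_id = character(0), criterion = character(0),
    a = numeric(0), b = numeric(0), mediator = numeric(0),
    consensus = numeric(0), stringsAsFactors = FALSE
  )
  if (length(need)) {
    if (is.null(mediator)) {
      stop_umni("differences greater than one point present but no mediator given")
    }
    med <- check_aligned(a, mediator)
    mv <- med[need]
    if (anyNA(mv)) {
      i <- need[which(is.na(mv))[1L]]
      stop_umni(
        "mediator missing a required cell: ",
        rownames(a)[(i - 1L) %% nrow(a) + 1L], " / ",
        colnames(a)[(i - 1L) %/% nrow(a) + 1L]
      )
    }
    consensus[need] <- mv
    log <- data.frame(
      disease_id = rownames(a)[(need - 1L) %% nrow(a) + 1L],
      criterion = colnames(a)[(need - 1L) %/% nrow(a) + 1L],
      a = unclass(a)[need], b = unclass(b)[need], mediator = mv,
      consensus = mv, stringsAsFactors = FALSE
    )
  }
  dimnames(consensus) <- dimnames(a)
  list(consensus = consensus, log = log)
}
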