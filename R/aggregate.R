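#' Weighted composite unmet-need total for one disease
#'
#' The composite is the exact dot product of the eleven criterion scores
#' with their weights — `total = score_1 * weight_1 + ... + score_11 *
#' weight_11` — with no normalization. Under the default weights a valid
#' score vector always yields a multiple of 0.25 in \[5.75, 28.75\].
#'
#' @param scores Named integer vector of criterion scores in 1--5.
#' @param weights Named weight vector covering exactly the same criteria.
#' @return The weighted total (numeric scalar).
#' @examples
#' weighted_total(setNames(rep(1L, 11), default_criteria()$name)) # 5.75
#' @export
weighted_total <- function(scores, weights = default_weights()) {
  if (is.null(names(scores)) || is.null(names(weights))) {
    stop_umni("scores and weights must be named by criterion")
  }
  if (length(scores) != length(weights) ||
      !setequal(names(scores), names(weights))) {
    stop_umni("scores and weights must cover the same criteria")
  }
  if (anyNA(scores)) stop_umni("scores contain missing values")
  sum(scores * weights[names(scores)])
}

#' Composite scores for a score matrix
#'
#' Applies [weighted_total()] row-wise, then ranks (see
#' [rank_and_percent()]).
#'
#' @param m A complete [score_matrix()].
#' @param weights Named weight vector.
#' @return Data frame: `disease_id`, `total_score`, `rank`, `top_percent`.
#' @export
composite_scores <- function(m, weights = default_weights()) {
  if (anyNA(m)) {
    stop_umni("score matrix has missing cells; refusing to aggregate")
  }
  w <- weights[colnames(m)]
  if (anyNA(w)) {
    stop_umni("weights missing for: ",
              paste(colnames(m)[is.na(w)], collapse = ", "))
  }
  totals <- as.numeric(unclass(m) %*% w)
  rank_and_percent(data.frame(
    disease_id = rownames(m), total_score = totals, stringsAsFactors = FALSE
  ))
}

#' Rank diseases and express rank as a top percentage
#'
#' Competition ranking: rank 1 is the highest total and ties share the
#' smallest applicable rank. `top_percent` is `100 * rank / N` rounded to
#' one decimal (so rank 959 of 22,701 is "top 4.2%").
#'
#' @param totals Data frame with columns `disease_id` and `total_score`.
#' @return The input with `rank` and `top_percent` columns added, original
#'   row order preserved.
#' @export
rank_and_percent <- function(totals) {
  stopifnot(is.data.frame(totals), all(c("disease_id", "total_score") %in% names(totals)))
  n <- nrow(totals)
  if (!n) stop_umni("rank_and_percent requires at least one disease")
  r <- rank(-totals$total_score, ties.method = "min")
  totals$rank <- as.integer(r)
  totals$top_percent <- round(100 * r / n, 1)
  totals
}

#' Histogram and skewness of composite totals
#'
#' Summarises a score distribution with equal-width histogram bins spanning
#' \[min, max\] and the Fisher–Pearson moment coefficient of skewness
#' `g1 = m3 / m2^(3/2)` (population moments). With zero variance the
#' skewness is undefined and flagged.
#'
#' @param totals Numeric vector of composite totals (length >= 3 for
#'   skewness).
#' @param bins Number of equal-width bins.
#' @return List: `breaks`, `counts` (summing to `length(totals)`), `mids`,
#'   `skewness`, `skewness_defined`, `n`.
#' @export
distribution_summary <- function(totals, bins = 30L) {
  stopifnot(is.numeric(totals), length(totals) >= 3L, bins >= 1L)
  rng <- range(totals)
  if (rng[1L] == rng[2L]) {
    breaks <- seq(rng[1L] - 0.5, rng[2L] + 0.5, length.out = bins + 1L)
  } else {
    breaks <- seq(rng[1L], rng[2L], length.out = bins + 1L)
  }
  h <- graphics::hist(totals, breaks = breaks, plot = FALSE,
                      include.lowest = TRUE, right = FALSE)
  n <- length(totals)
  m <- mean(totals)
  m2 <- mean((totals - m)^2)
  m3 <- mean((totals - m)^3)
  defined <- m2 > 0
  list(
    breaks = h$breaks,
    counts = h$counts,
    mids = h$mids,
    skewness = if (defined) m3 / m2^1.5 else NA_real_,
    skewness_defined = defined,
    n = n
  )
}

#' Write composite results and histograms as CSV
#'
#' @param composite Data frame from [composite_scores()].
#' @param summary List from [distribution_summary()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_composite_csv <- function(composite, path) {
  utils::write.csv(composite, path, row.names = FALSE, quote = FALSE,
                   fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname write_composite_csv
#' @export
write_histogram_csv <- function(summary, path) {
  k <- length(summary$counts)
  df <- data.frame(
    bin_left = summary$breaks[seq_len(k)],
    bin_right = summary$breaks[seq_len(k) + 1L],
    count = summary$counts
  )
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE,
                   fileEncoding = "UTF-8")
  invisible(path)
}
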