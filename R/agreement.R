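#' Per-criterion score moments
#'
#' Mean and sample standard deviation (n-1 denominator) of a criterion's
#' scores across diseases.
#'
#' @param x Numeric vector, length >= 2.
#' @return Named numeric vector `c(mean = , sd = )`.
#' @export
criterion_moments <- function(x) {
  if (length(x) < 2L) stop_umni("criterion_moments requires at least two scores")
  if (anyNA(x)) stop_umni("criterion_moments refuses missing values")
  c(mean = mean(x), sd = stats::sd(x))
}

#' Rater performance gates
#'
#' The acceptance thresholds a candidate rater must meet against expert
#' scores, applied per criterion: mean difference within +-1 point and
#' standard-deviation difference within +-0.5 points. Boundaries are
#' inclusive ("within").
#'
#' @param mean_diff Expert mean minus rater mean.
#' @param sd_diff Expert SD minus rater SD.
#' @return Named character vector `c(gate_mean = , gate_sd = )`, each
#'   `"pass"` or `"fail"`. Vectorised over inputs (returns a data frame
#'   when length > 1).
#' @export
gate_check <- function(mean_diff, sd_diff) {
  mean_diff <- unname(mean_diff)
  sd_diff <- unname(sd_diff)
  gm <- ifelse(abs(mean_diff) <= 1, "pass", "fail")
  gs <- ifelse(abs(sd_diff) <= 0.5, "pass", "fail")
  if (length(mean_diff) == 1L && length(sd_diff) == 1L) {
    return(c(gate_mean = gm, gate_sd = gs))
  }
  data.frame(gate_mean = gm, gate_sd = gs, stringsAsFactors = FALSE)
}

#' Spearman rank correlation
#'
#' Ranks both vectors (average ranks for ties) and returns the Pearson
#' correlation of the rank vectors.
#'
#' @param x,y Paired numeric vectors, length >= 3, neither constant.
#' @return Correlation in \[-1, 1\]; `NA` with a warning when an input is
#'   constant (undefined).
#' @export
spearman_rho <- function(x, y) {
  stopifnot(length(x) == length(y))
  if (length(x) < 3L) stop_umni("spearman_rho requires n >= 3")
  if (anyNA(x) || anyNA(y)) stop_umni("spearman_rho refuses missing values")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    warn_umni("spearman_rho undefined for constant input")
    return(NA_real_)
  }
  stats::cor(x, y, method = "spearman")
}

#' Percentile bootstrap confidence interval for Spearman's rho
#'
#' Resamples index pairs with replacement, recomputes the rank correlation
#' on each resample, and returns the percentile interval of the resampled
#' distribution. Degenerate resamples (either vector constant, where the
#' correlation is undefined) are redrawn. Seed-reproducible.
#'
#' @param x,y Paired numeric vectors, length >= 5.
#' @param resamples Number of bootstrap resamples (default 1,000).
#' @param level Confidence level in percent (default 95).
#' @param seed Integer seed.
#' @return Named numeric `c(low = , high = )`.
#' @export
bootstrap_rho_ci <- function(x, y, resamples = 1000L, level = 95, seed = NULL) {
  stopifnot(length(x) == length(y), length(x) >= 5L)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop_umni("bootstrap_rho_ci undefined for constant input")
  }
  n <- length(x)
  with_seed(seed, {
    rhos <- numeric(resamples)
    for (b in seq_len(resamples)) {
      repeat {
        idx <- sample.int(n, n, replace = TRUE)
        xb <- x[idx]; yb <- y[idx]
        if (stats::sd(xb) > 0 && stats::sd(yb) > 0) break
      }
      rhos[b] <- stats::cor(xb, yb, method = "spearman")
    }
    alpha <- (100 - level) / 200
    q <- stats::quantile(rhos, c(alpha, 1 - alpha), names = FALSE)
    c(low = q[1L], high = q[2L])
  })
}

#' Paired Wilcoxon signed-rank test
#'
#' Tests the null of zero median paired difference. Zero differences are
#' dropped (Wilcoxon convention). The exact null distribution is used when
#' the effective sample size is at most 25 and the absolute differences
#' are untied; otherwise a normal approximation with tie correction and
#' continuity correction. When all differences are zero the test is
#' degenerate and `p = 1` is returned with a flag.
#'
#' @param x,y Paired numeric vectors (or `y = NULL` to treat `x` as the
#'   differences).
#' @return List: `statistic` (V, sum of positive-difference ranks),
#'   `p_value` (two-sided), `method` (`"exact"`,
#'   `"normal-approximation"`, or `"degenerate"`), `degenerate`,
#'   `n_effective`.
#' @export
wilcoxon_signed_rank <- function(x, y = NULL) {
  d <- if (is.null(y)) x else {
    stopifnot(length(x) == length(y))
    x - y
  }
  if (!length(d)) stop_umni("wilcoxon_signed_rank requires n >= 1")
  if (anyNA(d)) stop_umni("wilcoxon_signed_rank refuses missing values")
  nz <- d[d != 0]
  n <- length(nz)
  if (n == 0L) {
    return(list(statistic = 0, p_value = 1, method = "degenerate",
                degenerate = TRUE, n_effective = 0L))
  }
  r <- rank(abs(nz))
  v <- sum(r[nz > 0])
  tied <- anyDuplicated(r) > 0L
  if (n <= 25L && !tied) {
    p_le <- stats::psignrank(v, n)
    p_ge <- stats::psignrank(v - 1, n, lower.tail = FALSE)
    p <- min(1, 2 * min(p_le, p_ge))
    method <- "exact"
  } else {
    mu <- n * (n + 1) / 4
    nties <- table(r)
    sigma2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(nties^3 - nties) / 48
    z <- v - mu
    z <- (z - sign(z) * 0.5) / sqrt(sigma2)
    p <- min(1, 2 * stats::pnorm(-abs(z)))
    method <- "normal-approximation"
  }
  list(statistic = v, p_value = p, method = method, degenerate = FALSE,
       n_effective = n)
}

#' Mean absolute and root-mean-square error between paired raters
#'
#' @param x,y Paired numeric vectors.
#' @return Named numeric `c(mae = , rmse = )`; always `rmse >= mae >=
#'   |mean difference|`.
#' @export
mae_rmse <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 1L)
  d <- x - y
  c(mae = mean(abs(d)), rmse = sqrt(mean(d^2)))
}

#' Pooled agreement battery for one paired score set
#'
#' Spearman rank correlation with a 95% percentile bootstrap interval
#' (1,000 resamples), mean absolute error, root-mean-square error, and a
#' paired Wilcoxon signed-rank test for systematic over- or under-rating.
#'
#' @param x,y Paired numeric vectors (expert, rater).
#' @param resamples Bootstrap resamples.
#' @param seed Seed for the bootstrap.
#' @return List: `spearman_rho`, `rho_ci_low`, `rho_ci_high`, `mae`,
#'   `rmse`, `wilcoxon_p`, `wilcoxon_statistic`.
#' @export
pooled_agreement <- function(x, y, resamples = 1000L, seed = NULL) {
  constant <- stats::sd(x) == 0 || stats::sd(y) == 0
  rho <- if (constant) {
    warn_umni("rank correlation undefined for a constant score vector")
    NA_real_
  } else {
    spearman_rho(x, y)
  }
  ci <- if (constant || resamples < 1L) {
    c(low = NA_real_, high = NA_real_)
  } else {
    bootstrap_rho_ci(x, y, resamples = resamples, seed = seed)
  }
  err <- mae_rmse(x, y)
  w <- wilcoxon_signed_rank(x, y)
  list(
    spearman_rho = rho, rho_ci_low = unname(ci["low"]),
    rho_ci_high = unname(ci["high"]),
    mae = unname(err["mae"]), rmse = unname(err["rmse"]),
    wilcoxon_p = w$p_value, wilcoxon_statistic = w$statistic
  )
}

#' Per-criterion agreement report between an expert and a candidate rater
#'
#' For every criterion: both raters' mean and sample SD across diseases,
#' the mean and SD differences (expert minus rater), the performance gates
#' of [gate_check()], and the pooled battery of [pooled_agreement()]
#' computed on that criterion's paired scores.
#'
#' @param expert,rater Complete [score_matrix()] objects over the same
#'   grid.
#' @param resamples Bootstrap resamples per criterion.
#' @param seed Base seed; criterion `i` uses `seed + i` so the report is
#'   reproducible as a whole.
#' @return An `agreement_report` data frame, one row per criterion.
#' @export
agreement_report <- function(expert, rater, resamples = 1000L, seed = NULL) {
  rater <- check_aligned(expert, rater)
  if (anyNA(expert) || anyNA(rater)) {
    stop_umni("agreement_report requires complete matrices")
  }
  rows <- lapply(seq_len(ncol(expert)), function(j) {
    e <- expert[, j]; l <- rater[, j]
    em <- criterion_moments(e); lm <- criterion_moments(l)
    mean_diff <- em["mean"] - lm["mean"]
    sd_diff <- em["sd"] - lm["sd"]
    gates <- gate_check(mean_diff, sd_diff)
    pooled <- pooled_agreement(e, l, resamples = resamples,
                               seed = if (is.null(seed)) NULL else seed + j)
    data.frame(
      criterion = colnames(expert)[j],
      expert_mean = unname(em["mean"]), expert_sd = unname(em["sd"]),
      rater_mean = unname(lm["mean"]), rater_sd = unname(lm["sd"]),
      mean_diff = unname(mean_diff), sd_diff = unname(sd_diff),
      gate_mean = unname(gates["gate_mean"]), gate_sd = unname(gates["gate_sd"]),
      spearman_rho = pooled$spearman_rho,
      rho_ci_low = pooled$rho_ci_low, rho_ci_high = pooled$rho_ci_high,
      mae = pooled$mae, rmse = pooled$rmse, wilcoxon_p = pooled$wilcoxon_p,
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  class(out) <- c("agreement_report", "data.frame")
  out
}
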