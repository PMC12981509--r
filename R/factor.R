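#' Bartlett's test of sphericity
#'
#' Tests whether a correlation matrix is the identity (variables
#' uncorrelated), a prerequisite check before factor analysis:
#' `chi2 = -(n - 1 - (2p + 5)/6) * ln det(R)` on `p(p-1)/2` degrees of
#' freedom, with the p-value from the upper chi-square tail.
#'
#' @param R Symmetric positive-definite correlation matrix with unit
#'   diagonal.
#' @param n Sample size used to estimate `R` (must exceed `p`).
#' @return List: `chi2`, `df`, `p_value`.
#' @examples
#' bartlett_sphericity(diag(11), n = 40)$chi2 # 0
#' @export
bartlett_sphericity <- function(R, n) {
  p <- check_corr_matrix(R)
  stopifnot(n > p)
  detR <- det(R)
  if (detR <= 0) stop_umni("correlation matrix is not positive-definite")
  chi2 <- -(n - 1 - (2 * p + 5) / 6) * log(detR)
  df <- p * (p - 1) / 2
  list(chi2 = chi2, df = df,
       p_value = stats::pchisq(chi2, df, lower.tail = FALSE))
}

check_corr_matrix <- function(R) {
  stopifnot(is.matrix(R), nrow(R) == ncol(R))
  p <- nrow(R)
  if (p < 2L) stop_umni("need at least two variables")
  if (max(abs(R - t(R))) > 1e-8) stop_umni("correlation matrix must be symmetric")
  if (max(abs(diag(R) - 1)) > 1e-8) stop_umni("correlation matrix must have unit diagonal")
  p
}

#' Kaiser-Meyer-Olkin measure of sampling adequacy
#'
#' For each variable `j`, the MSA is the ratio of summed squared raw
#' correlations to summed squared raw plus squared anti-image partial
#' correlations over the other variables; the overall MSA pools all
#' off-diagonal pairs. Partial correlations come from the scaled inverse of
#' `R`. Values near 1 indicate factorable data; the conventional adequacy
#' threshold is 0.6 per item and 0.5 overall. For an identity matrix the
#' measure is 0/0 and returned as `NaN` with a flag.
#'
#' @param R Invertible correlation matrix, `p >= 2`.
#' @return List: `msa_per_item` (named), `msa_overall`, `defined`.
#' @export
kmo <- function(R) {
  p <- check_corr_matrix(R)
  Rinv <- tryCatch(solve(R), error = function(e) {
    stop_umni("correlation matrix is singular")
  })
  s <- 1 / sqrt(diag(Rinv))
  Q <- -Rinv * tcrossprod(s) # anti-image partial correlations
  diag(Q) <- 0
  R0 <- R
  diag(R0) <- 0
  r2 <- R0^2
  q2 <- Q^2
  denom_item <- colSums(r2) + colSums(q2)
  msa_item <- ifelse(denom_item > 0, colSums(r2) / denom_item, NaN)
  names(msa_item) <- colnames(R) %||% paste0("V", seq_len(p))
  denom_all <- sum(r2) + sum(q2)
  msa_all <- if (denom_all > 0) sum(r2) / denom_all else NaN
  list(msa_per_item = msa_item, msa_overall = msa_all,
       defined = is.finite(msa_all))
}

# Squared multiple correlations: communality estimates for the reduced
# correlation matrix used in principal-factor eigenvalue traces.
smc <- function(R) {
  1 - 1 / diag(solve(R))
}

reduced_eigenvalues <- function(R) {
  Rr <- R
  diag(Rr) <- smc(R)
  sort(eigen(Rr, symmetric = TRUE, only.values = TRUE)$values,
       decreasing = TRUE)
}

#' Parallel analysis for factor retention
#'
#' Compares the principal-factor eigenvalues of the observed reduced
#' (communality-adjusted) correlation matrix against eigenvalues from
#' simulated uncorrelated data sets of identical shape. The suggested
#' factor count is the number of leading observed eigenvalues exceeding the
#' simulated comparison curve (mean by default, 95th percentile
#' optionally).
#'
#' @param data Numeric matrix, diseases x criteria (`nrow >= ncol + 1`),
#'   no constant column.
#' @param n_sim Number of simulated data sets.
#' @param seed Integer seed (the simulation is seed-reproducible).
#' @param criterion Comparison curve: `"mean"` of the simulated
#'   eigenvalues, or `"p95"` for their 95th percentile.
#' @return List: `n_factors`, `eigenvalues_observed`, `eigenvalues_sim`
#'   (the comparison curve), `criterion`.
#' @export
parallel_analysis <- function(data, n_sim = 1000L, seed = NULL,
                              criterion = c("mean", "p95")) {
  criterion <- match.arg(criterion)
  data <- as.matrix(data)
  n <- nrow(data); p <- ncol(data)
  if (n < p + 1L) stop_umni("parallel analysis needs more rows than columns")
  sds <- apply(data, 2L, stats::sd)
  if (any(sds == 0)) {
    stop_umni("degenerate data: constant column '",
              (colnames(data) %||% seq_len(p))[which(sds == 0)[1L]], "'")
  }
  obs <- reduced_eigenvalues(stats::cor(data))
  with_seed(seed, {
    sim <- matrix(0, n_sim, p)
    for (s in seq_len(n_sim)) {
      x <- matrix(stats::rnorm(n * p), n, p)
      sim[s, ] <- reduced_eigenvalues(stats::cor(x))
    }
    curve <- if (criterion == "mean") {
      colMeans(sim)
    } else {
      apply(sim, 2L, stats::quantile, probs = 0.95, names = FALSE)
    }
    exceed <- obs > curve
    k <- if (exceed[1L]) {
      run <- rle(exceed)
      run$lengths[1L]
    } else 0L
    list(n_factors = as.integer(k), eigenvalues_observed = obs,
         eigenvalues_sim = curve, criterion = criterion)
  })
}

#' Maximum-likelihood exploratory factor analysis
#'
#' Extracts `k` factors by maximum likelihood and applies the requested
#' rotation (oblique promax by default, so factors may correlate; varimax
#' and unrotated solutions are available). Factors are labelled `ML1..MLk`.
#' Non-convergence raises an error; solutions with a near-zero uniqueness
#' (Heywood case) are flagged with a warning.
#'
#' @param data Numeric matrix, diseases x criteria, `nrow > ncol`.
#' @param k Number of factors, `k < ncol(data)`.
#' @param rotation `"promax"`, `"varimax"`, or `"none"`.
#' @return List: `loadings` (p x k matrix), `uniquenesses`, `k`,
#'   `rotation`, `heywood` (logical).
#' @export
efa <- function(data, k, rotation = c("promax", "varimax", "none")) {
  rotation <- match.arg(rotation)
  data <- as.matrix(data)
  if (nrow(data) <= ncol(data)) stop_umni("efa needs more rows than columns")
  if (k >= ncol(data)) stop_umni("factor count must be below the number of criteria")
  fit <- tryCatch(
    stats::factanal(data, factors = k,
                    rotation = switch(rotation, none = "none", rotation),
                    scores = "none"),
    error = function(e) stop_umni("factor extraction failed: ", conditionMessage(e))
  )
  L <- unclass(fit$loadings)[, seq_len(k), drop = FALSE]
  colnames(L) <- paste0("ML", seq_len(k))
  heywood <- any(fit$uniquenesses < 0.005 + 1e-9)
  if (heywood) warn_umni("Heywood case: uniqueness at its lower bound")
  list(loadings = L, uniquenesses = fit$uniquenesses, k = k,
       rotation = rotation, heywood = heywood)
}

#' Group criteria by their dominant factor loading
#'
#' Assigns each criterion to the factor on which it has the largest
#' absolute loading (so strong negative loadings group with their factor);
#' ties are broken towards the lowest factor index with a warning.
#'
#' @param loadings Criterion x factor loading matrix.
#' @return List: `assignment` (data frame `criterion`, `factor`,
#'   `loading`), `groups` (factor name -> character vector of criteria).
#' @export
group_by_loading <- function(loadings) {
  L <- as.matrix(loadings)
  a <- abs(L)
  idx <- integer(nrow(L))
  for (i in seq_len(nrow(L))) {
    best <- which(a[i, ] == max(a[i, ]))
    if (length(best) > 1L) {
      warn_umni("tied loadings for '", rownames(L)[i] %||% i,
                "'; assigned to the lowest factor index")
    }
    idx[i] <- best[1L]
  }
  fnames <- colnames(L) %||% paste0("ML", seq_len(ncol(L)))
  assignment <- data.frame(
    criterion = rownames(L) %||% paste0("V", seq_len(nrow(L))),
    factor = fnames[idx],
    loading = L[cbind(seq_len(nrow(L)), idx)],
    stringsAsFactors = FALSE
  )
  groups <- split(assignment$criterion, factor(assignment$factor, levels = fnames))
  list(assignment = assignment, groups = groups[lengths(groups) > 0])
}

#' Full factorability-and-structure report for a score matrix
#'
#' Runs the factor suite end to end: Bartlett sphericity, KMO sampling
#' adequacy, parallel analysis for the factor count, maximum-likelihood
#' extraction at the suggested count, and dominant-loading grouping. EFA is
#' refused (with a warning, configurable) when the overall MSA falls below
#' `min_msa` or when Bartlett's test cannot reject sphericity at
#' `alpha` — diagnostics are still reported.
#'
#' @param data Numeric score matrix, diseases x criteria.
#' @param n_sim Parallel-analysis simulations.
#' @param seed Integer seed.
#' @param rotation Rotation passed to [efa()].
#' @param min_msa Minimum overall MSA required to run EFA (default 0.5).
#' @param alpha Bartlett significance level required to run EFA.
#' @param pa_criterion Parallel-analysis comparison curve.
#' @return A `factor_report` list: `n`, `bartlett`, `kmo`,
#'   `parallel` fields always present; `efa_run`, `loadings`, `groupings`
#'   when EFA ran.
#' @export
factor_report <- function(data, n_sim = 1000L, seed = NULL,
                          rotation = "promax", min_msa = 0.5, alpha = 0.05,
                          pa_criterion = "mean") {
  data <- as.matrix(data)
  if (anyNA(data)) stop_umni("factor_report requires complete rows")
  R <- stats::cor(data)
  bart <- bartlett_sphericity(R, n = nrow(data))
  adequacy <- kmo(R)
  pa <- parallel_analysis(data, n_sim = n_sim, seed = seed,
                          criterion = pa_criterion)
  out <- list(
    n = nrow(data), p = ncol(data),
    bartlett = bart, kmo = adequacy, parallel = pa,
    efa_run = FALSE, loadings = NULL, groupings = NULL
  )
  factorable <- is.finite(adequacy$msa_overall) &&
    adequacy$msa_overall >= min_msa && bart$p_value < alpha
  if (!factorable) {
    warn_umni("data not factorable (overall MSA ",
              round(adequacy$msa_overall, 3), ", Bartlett p ",
              signif(bart$p_value, 3), "); EFA skipped")
  } else if (pa$n_factors >= 1L) {
    fit <- efa(data, k = pa$n_factors, rotation = rotation)
    out$efa_run <- TRUE
    out$loadings <- fit$loadings
    out$groupings <- group_by_loading(fit$loadings)
    out$heywood <- fit$heywood
  } else {
    warn_umni("parallel analysis suggested zero factors; EFA skipped")
  }
  class(out) <- "factor_report"
  out
}

#' Write a factor report to disk
#'
#' Emits `factor_report.json` (diagnostics and groupings),
#' `loadings.csv`, and `eigenvalues.csv` (observed and simulated traces
#' for the scree comparison).
#'
#' @param report A `factor_report`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_factor_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  json <- list(
    n = report$n, p = report$p,
    bartlett = report$bartlett,
    kmo = list(
      msa_per_item = as.list(report$kmo$msa_per_item),
      msa_overall = report$kmo$msa_overall
    ),
    n_factors_suggested = report$parallel$n_factors,
    efa_run = report$efa_run
  )
  if (report$efa_run) {
    json$groupings <- lapply(report$groupings$groups, as.list)
    utils::write.csv(
      data.frame(criterion = rownames(report$loadings), report$loadings,
                 check.names = FALSE),
      file.path(dir, "loadings.csv"), row.names = FALSE, quote = FALSE
    )
  }
  jsonlite::write_json(json, file.path(dir, "factor_report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  utils::write.csv(
    data.frame(
      component = seq_along(report$parallel$eigenvalues_observed),
      observed = report$parallel$eigenvalues_observed,
      simulated = report$parallel$eigenvalues_sim
    ),
    file.path(dir, "eigenvalues.csv"), row.names = FALSE, quote = FALSE
  )
  invisible(dir)
}
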