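#' Target score distributions per criterion
#'
#' A spectrum plan fixes, for every criterion, the target marginal
#' distribution of scores 1--5 that a generated disease set should
#' realize. The default is uniform coverage so each score level appears —
#' emulating a calibration set deliberately chosen to span the full
#' spectrum of expected scores for each criterion.
#'
#' @param criteria Criterion set.
#' @param probs Either a single probability vector of length 5 applied to
#'   every criterion, or a criteria x 5 matrix.
#' @return An 11 x 5 row-stochastic matrix of class `spectrum_plan`, rows
#'   named by criterion.
#' @export
spectrum_plan <- function(criteria = default_criteria(),
                          probs = rep(0.2, 5)) {
  if (is.matrix(probs)) {
    plan <- probs
  } else {
    stopifnot(length(probs) == 5L)
    plan <- matrix(probs, nrow(criteria), 5L, byrow = TRUE)
  }
  rownames(plan) <- criteria$name
  colnames(plan) <- as.character(1:5)
  if (any(plan < 0) || any(abs(rowSums(plan) - 1) > 1e-8)) {
    stop_umni("each criterion's score distribution must be non-negative and sum to 1")
  }
  structure(plan, class = c("spectrum_plan", "matrix"))
}

# Draw one attribute value landing in the rubric band for `score`.
draw_attribute <- function(entry, score, criterion) {
  if (identical(entry$type, "numeric")) {
    band <- if (identical(entry$direction, "decreasing")) 6L - score else score
    edges <- c(entry$domain[1L], entry$cuts, entry$domain[2L])
    lo <- edges[band]; hi <- edges[band + 1L]
    if (!is.finite(lo) || !is.finite(hi) || hi <= lo) {
      stop_umni("empty rubric band for criterion '", criterion,
                "' at score ", score)
    }
    stats::runif(1L, lo, hi)
  } else {
    lv <- names(entry$map)[entry$map == score]
    if (!length(lv)) {
      stop_umni("empty rubric band for criterion '", criterion,
                "' at score ", score)
    }
    if (length(lv) == 1L) lv else sample(lv, 1L)
  }
}

#' Generate disease profiles realizing a spectrum plan
#'
#' Inverse construction: for each synthetic disease and criterion a target
#' score is sampled from the plan, then an attribute value is drawn
#' uniformly from that score's rubric band — so the rubric scores of the
#' generated profiles realize the plan's marginal distributions exactly up
#' to sampling of the plan itself. Seed-reproducible.
#'
#' @param n Number of diseases.
#' @param plan A [spectrum_plan()].
#' @param rubric A total [default_rubric()]-style rubric.
#' @param seed Integer seed.
#' @param criteria Criterion set.
#' @param id_start First numeric part of the synthetic MONDO-style ids.
#' @return A `disease_profile` data frame of `n` rows with synthetic ids
#'   `MONDO:9xxxxxx` and labels marking them as synthetic.
#' @export
gen_profiles <- function(n, plan = spectrum_plan(), rubric = default_rubric(),
                         seed = NULL, criteria = default_criteria(),
                         id_start = 9000001L) {
  cov <- rubric_coverage_check(rubric, criteria)
  if (nrow(cov)) {
    stop_umni("rubric fails coverage check; first issue: ",
              cov$criterion[1L], " (", cov$detail[1L], ")")
  }
  with_seed(seed, {
    rows <- vector("list", n)
    for (i in seq_len(n)) {
      rec <- list(disease_id = sprintf("MONDO:%07d", id_start + i - 1L))
      for (cn in criteria$name) {
        entry <- rubric[[cn]]
        score <- sample.int(5L, 1L, prob = plan[cn, ])
        val <- draw_attribute(entry, score, cn)
        if (entry$attribute == "typical_duration_years") {
          rec$typical_duration_value <- val
          rec$typical_duration_unit <- "years"
        } else {
          rec[[entry$attribute]] <- val
        }
      }
      rows[[i]] <- as.data.frame(rec, stringsAsFactors = FALSE)
    }
    validate_profiles(do.call(rbind, rows))
  })
}

#' Generate a paired expert/second-rater score set
#'
#' Draws an expert score matrix from the spectrum plan, then produces the
#' second rater by perturbing it with [mock_rate()] under the given
#' disagreement rates — emulating two independent raters whose
#' disagreement histogram converges to the configured rates.
#'
#' @param n_diseases Number of diseases.
#' @param plan A [spectrum_plan()].
#' @param rates Disagreement rates as in [mock_rate()].
#' @param seed Integer seed (expert draw and perturbation both derive from
#'   it).
#' @param criteria Criterion set.
#' @param id_start First numeric part of the synthetic ids.
#' @return List with `expert` and `second` [score_matrix()] objects.
#' @export
gen_rater_pair <- function(n_diseases, plan = spectrum_plan(),
                           rates = c("1" = 0.2045, "2" = 0.0545),
                           seed = NULL, criteria = default_criteria(),
                           id_start = 9000001L) {
  expert <- with_seed(seed, {
    m <- vapply(criteria$name, function(cn) {
      sample.int(5L, n_diseases, replace = TRUE, prob = plan[cn, ])
    }, integer(n_diseases))
    if (n_diseases == 1L) m <- matrix(m, nrow = 1L,
                                      dimnames = list(NULL, criteria$name))
    rownames(m) <- sprintf("MONDO:%07d", id_start + seq_len(n_diseases) - 1L)
    score_matrix(m + 0, rater_id = "expert")
  })
  second <- mock_rate(expert, rates = rates,
                      seed = if (is.null(seed)) NULL else seed + 1L,
                      rater = "second")
  list(expert = expert, second = second)
}

#' Specify a planted latent-factor model for score generation
#'
#' Defines the population structure used to generate score matrices with a
#' known factor structure: a p x k loading matrix, a factor correlation
#' matrix, implied uniquenesses (`1 - diag(L Phi L')`), and the latent
#' cut-points that discretize standardized continuous scores onto the 1--5
#' scale.
#'
#' @param loadings p x k numeric loading matrix (rownames = criteria).
#' @param phi k x k factor correlation matrix (default identity).
#' @param cuts Four increasing latent cut-points (default
#'   `c(-1.5, -0.5, 0.5, 1.5)`, giving roughly the observed 1--5 usage).
#' @return A `planted_factor_model` list; errors if the implied
#'   correlation matrix is not positive definite or a communality reaches
#'   1.
#' @export
planted_factor_model <- function(loadings, phi = NULL,
                                 cuts = c(-1.5, -0.5, 0.5, 1.5)) {
  L <- as.matrix(loadings)
  k <- ncol(L)
  phi <- phi %||% diag(k)
  stopifnot(nrow(phi) == k, ncol(phi) == k, length(cuts) == 4L,
            all(diff(cuts) > 0))
  common <- rowSums((L %*% phi) * L)
  if (any(common >= 1)) {
    stop_umni("communality at or above 1; reduce loadings")
  }
  psi <- 1 - common
  sigma <- L %*% phi %*% t(L) + diag(psi)
  ev <- eigen(sigma, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 1e-10) {
    stop_umni("implied correlation matrix is not positive definite")
  }
  structure(list(loadings = L, phi = phi, psi = psi, cuts = cuts,
                 sigma = sigma), class = "planted_factor_model")
}

#' The default four-factor planted structure
#'
#' An 11-criterion, four-factor structure mirroring the empirically
#' observed grouping of the criteria: a disease-burden factor (QALYs lost
#' 0.841, frequency of administration 0.732, adverse events 0.348), a
#' structural/access factor (robust supply 0.873, commonality 0.740,
#' regulatory barriers 0.674), a modifiability/chronicity factor (disease
#' modification -0.776, cost to patients 0.531, duration 0.403), and a
#' treatment-complexity factor (route of administration 0.854, mortality
#' 0.754, adverse events 0.713).
#'
#' @param criteria Criterion set fixing row order.
#' @return A [planted_factor_model()] with 4 orthogonal factors.
#' @export
four_factor_model <- function(criteria = default_criteria()) {
  L <- matrix(0, 11, 4, dimnames = list(criteria$name, paste0("F", 1:4)))
  L["QALYs lost", 1] <- 0.841
  L["Frequency of administration", 1] <- 0.732
  L["Adverse events", 1] <- 0.348
  L["Commonality", 2] <- 0.740
  L["Robust supply", 2] <- 0.873
  L["Regulatory barriers", 2] <- 0.674
  L["Disease modification", 3] <- -0.776
  L["Cost to patients", 3] <- 0.531
  L["Duration", 3] <- 0.403
  L["Route of administration", 4] <- 0.854
  L["Adverse events", 4] <- 0.713
  L["Mortality", 4] <- 0.754
  planted_factor_model(L)
}

#' Generate a score matrix from a planted factor model
#'
#' Latent factors are drawn from `N(0, Phi)`, observed continuous scores
#' from the loading model plus unique noise, and the standardized
#' continuous scores are discretized onto 1--5 by the model's cut-points.
#' The empirical correlation matrix converges to the model-implied one as
#' `n` grows (attenuated slightly by discretization).
#'
#' @param n Number of diseases (rows).
#' @param model A [planted_factor_model()].
#' @param seed Integer seed.
#' @param id_start First numeric part of the synthetic ids.
#' @return A [score_matrix()] with rater id `"synthetic"`.
#' @export
gen_factor_scores <- function(n, model, seed = NULL, id_start = 9000001L) {
  stopifnot(inherits(model, "planted_factor_model"))
  L <- model$loadings
  p <- nrow(L); k <- ncol(L)
  with_seed(seed, {
    eta <- matrix(stats::rnorm(n * k), n, k) %*% chol(model$phi)
    eps <- matrix(stats::rnorm(n * p), n, p) %*% diag(sqrt(model$psi), p)
    x <- eta %*% t(L) + eps
    scores <- matrix(findInterval(x, model$cuts) + 1, n, p)
    dimnames(scores) <- list(
      sprintf("MONDO:%07d", id_start + seq_len(n) - 1L),
      rownames(L)
    )
    score_matrix(scores, rater_id = "synthetic")
  })
}

#' Build a synthetic disease registry
#'
#' Companion to the generators: registry records for `n` synthetic
#' diseases with MONDO-style ids, labels flagged as synthetic, and a
#' synonym each (so synonym-handling code paths are exercised).
#'
#' @param n Number of diseases.
#' @param id_start First numeric part of the ids.
#' @return A `disease_registry` data frame.
#' @export
gen_registry <- function(n, id_start = 9000001L) {
  ids <- sprintf("MONDO:%07d", id_start + seq_len(n) - 1L)
  labels <- sprintf("synthetic disease %03d", seq_len(n))
  syns <- lapply(seq_len(n), function(i) sprintf("synthetic condition %03d", i))
  make_registry(ids, labels, syns)
}
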