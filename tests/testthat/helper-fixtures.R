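# Shared fixture builders for the test suite. Everything is generated in
# code; the only on-disk fixtures are the small pinned synthetic files in
# inst/extdata.

criteria_names <- default_criteria()$name

# A complete integer score matrix with every cell set to `fill`.
flat_scores <- function(n = 40L, fill = 3, rater = "expert",
                        ids = sprintf("MONDO:%07d", 9000000L + seq_len(n))) {
  score_matrix(
    matrix(fill, n, 11L, dimnames = list(ids, criteria_names)),
    rater_id = rater
  )
}

# A profile whose default-rubric scores are all 3 (mid-band values).
mid_band_profile <- function(id = "MONDO:9000001") {
  disease_profile(
    disease_id = id,
    prevalence_per_100k = 20,
    typical_duration_value = 2, typical_duration_unit = "years",
    qaly_loss_fraction = 0.4,
    five_year_mortality_pct = 20,
    soc_disease_modification = "moderate",
    soc_adverse_event_burden = "moderate",
    admin_route = "self_injection",
    admin_doses_per_week = 3,
    annual_cost_band = "moderate",
    supply_robustness = "occasional_shortage",
    regulatory_barrier = "moderate"
  )
}

extdata <- function(name) {
  path <- system.file("extdata", name, package = "umni")
  if (!nzchar(path)) path <- file.path("../../inst/extdata", name)
  path
}

# Exhaustive sign-enumeration oracle for the paired signed-rank test on
# non-zero, untied differences.
enumerate_signrank_p <- function(d) {
  stopifnot(all(d != 0), !anyDuplicated(abs(d)))
  n <- length(d)
  r <- rank(abs(d))
  v_obs <- sum(r[d > 0])
  signs <- expand.grid(rep(list(c(0L, 1L)), n))
  v_all <- as.matrix(signs) %*% r
  p_le <- mean(v_all <= v_obs)
  p_ge <- mean(v_all >= v_obs)
  min(1, 2 * min(p_le, p_ge))
}

# Classic closed-form Spearman for untied data.
spearman_closed_form <- function(x, y) {
  d <- rank(x) - rank(y)
  n <- length(x)
  1 - 6 * sum(d^2) / (n * (n^2 - 1))
}

# Single-factor planted model with varied loadings (for recovery tests).
varied_1f_model <- function(loads = c(0.5, 0.6, 0.7, 0.8, 0.85, 0.9)) {
  planted_factor_model(matrix(loads, ncol = 1,
                              dimnames = list(paste0("C", seq_along(loads)), "F1")))
}

uniform_1f_model <- function(p = 6, loading = 0.8) {
  planted_factor_model(matrix(loading, p, 1,
                              dimnames = list(paste0("C", seq_len(p)), "F1")))
}

two_block_model <- function() {
  L <- matrix(0, 6, 2, dimnames = list(paste0("C", 1:6), c("F1", "F2")))
  L[1:3, 1] <- c(0.8, 0.75, 0.7)
  L[4:6, 2] <- c(0.8, 0.75, 0.7)
  planted_factor_model(L)
}
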