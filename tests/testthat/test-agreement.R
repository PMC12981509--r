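test_that("criterion moments use the sample standard deviation", {
  expect_equal(unname(criterion_moments(c(3, 3, 3))), c(3, 0))
  m <- criterion_moments(c(1, 5))
  expect_equal(unname(m["mean"]), 3)
  expect_equal(unname(m["sd"]), 2 * sqrt(2), tolerance = 1e-12)
  expect_error(criterion_moments(3), "at least two")
})

test_that("performance gates are inclusive at the published thresholds", {
  expect_equal(gate_check(-1.40, -0.19), c(gate_mean = "fail", gate_sd = "pass"))
  expect_equal(gate_check(0, 0), c(gate_mean = "pass", gate_sd = "pass"))
  expect_equal(gate_check(1.0, 0.5), c(gate_mean = "pass", gate_sd = "pass"))
  expect_equal(gate_check(-1.001, 0.501), c(gate_mean = "fail", gate_sd = "fail"))
})

test_that("spearman rho handles perfect order, reversal, and ties", {
  expect_equal(spearman_rho(1:3, 1:3), 1)
  expect_equal(spearman_rho(1:3, 3:1), -1)
  expect_equal(spearman_rho(c(1, 2, 2, 4), c(1, 3, 2, 4)),
               4.5 / sqrt(22.5), tolerance = 1e-12)
  expect_warning(r <- spearman_rho(c(2, 2, 2), 1:3), "constant")
  expect_true(is.na(r))
})

test_that("spearman rho equals the closed-form rank statistic on all small permutations", {
  for (n in 3:5) {
    x <- seq_len(n)
    perms <- as.matrix(expand.grid(rep(list(x), n)))
    perms <- perms[apply(perms, 1, function(r) !anyDuplicated(r)), , drop = FALSE]
    for (i in seq_len(nrow(perms))) {
      y <- perms[i, ]
      expect_equal(spearman_rho(x, y), spearman_closed_form(x, y),
                   tolerance = 1e-12)
    }
  }
})

test_that("signed-rank test: degenerate, exact, and approximate branches", {
  w <- wilcoxon_signed_rank(c(2, 3, 4), c(2, 3, 4))
  expect_true(w$degenerate)
  expect_equal(w$p_value, 1)

  w2 <- wilcoxon_signed_rank(c(1, 2, 3))
  expect_equal(w2$method, "exact")
  expect_equal(w2$p_value, 0.25)
  expect_equal(w2$statistic, 6)

  # zero differences are dropped before ranking
  w3 <- wilcoxon_signed_rank(c(0, 1, 2, 3))
  expect_equal(w3$n_effective, 3L)
  expect_equal(w3$p_value, 0.25)

  # tied absolute differences force the corrected normal approximation
  w4 <- wilcoxon_signed_rank(c(1, 1, 2, -2, 3))
  expect_equal(w4$method, "normal-approximation")
  ref <- suppressWarnings(stats::wilcox.test(c(1, 1, 2, -2, 3), correct = TRUE))
  expect_equal(w4$p_value, ref$p.value, tolerance = 1e-10)
  expect_true(w4$p_value >= 0 && w4$p_value <= 1)
})

test_that("the exact branch reproduces full sign enumeration up to n = 10", {
  set.seed(42)
  for (rep in 1:20) {
    n <- sample(3:10, 1)
    d <- sample(c(-1, 1), n, replace = TRUE) * sample(seq(0.5, 20, by = 0.5), n)
    d <- d[!duplicated(abs(d))]
    if (length(d) < 3) next
    w <- wilcoxon_signed_rank(d)
    expect_equal(w$method, "exact")
    expect_equal(w$p_value, enumerate_signrank_p(d), tolerance = 1e-12)
    ref <- stats::wilcox.test(d, exact = TRUE)
    expect_equal(w$p_value, ref$p.value, tolerance = 1e-12)
  }
})

test_that("error metrics satisfy their definitions and ordering", {
  expect_equal(unname(mae_rmse(1:5, 1:5)), c(0, 0))
  expect_equal(unname(mae_rmse(c(2, 1), c(1, 2))), c(1, 1))
  expect_equal(unname(mae_rmse(c(1, 5), c(1, 3))), c(1, sqrt(2)),
               tolerance = 1e-12)

  set.seed(9)
  for (rep in 1:50) {
    x <- sample.int(5, 40, replace = TRUE)
    y <- sample.int(5, 40, replace = TRUE)
    e <- mae_rmse(x, y)
    expect_gte(e["rmse"], e["mae"])
    expect_gte(e["mae"], abs(mean(x - y)))
  }
})

test_that("the published per-criterion differences respect the error ordering", {
  # development-set and pooled rows: rmse >= mae in every printed pairing
  mae <- c(0.825, 0.475, 0.850, 0.775, 1.375, 1.400, 0.750, 0.838, 0.850, 1.163, 1.000)
  rmse <- c(1.129, 0.798, 1.031, 1.090, 1.677, 1.585, 1.124, 1.170, 1.146, 1.490, 1.396)
  expect_true(all(rmse >= mae))
})

test_that("bootstrap intervals are degenerate-proof, ordered, and reproducible", {
  x <- c(1, 2, 3, 4, 5, 6, 7, 8)
  ci <- bootstrap_rho_ci(x, x, resamples = 50, seed = 1)
  expect_equal(unname(ci), c(1, 1))

  pair <- gen_rater_pair(40, seed = 3)
  e <- pair$expert[, "Mortality"]; l <- pair$second[, "Mortality"]
  ci1 <- bootstrap_rho_ci(e, l, resamples = 200, seed = 7)
  ci2 <- bootstrap_rho_ci(e, l, resamples = 200, seed = 7)
  expect_identical(ci1, ci2)
  expect_lte(ci1["low"], ci1["high"])
  expect_true(ci1["low"] >= -1 && ci1["high"] <= 1)
  rho <- spearman_rho(e, l)
  expect_true(ci1["low"] <= rho && rho <= ci1["high"])

  expect_error(bootstrap_rho_ci(rep(3, 10), 1:10), "constant")
})

test_that("a perfectly agreeing rater passes every gate with zero error", {
  pair <- gen_rater_pair(40, seed = 19, rates = c("1" = 0, "2" = 0))
  rep <- agreement_report(pair$expert, pair$second, resamples = 100, seed = 2)
  expect_equal(nrow(rep), 11L)
  expect_true(all(rep$gate_mean == "pass"))
  expect_true(all(rep$gate_sd == "pass"))
  expect_true(all(rep$mae == 0))
  expect_true(all(rep$rmse == 0))
  expect_equal(rep$spearman_rho, rep(1, 11), tolerance = 1e-12)
  expect_true(all(rep$rmse >= rep$mae))
  expect_true(all(rep$mae >= abs(rep$mean_diff)))
})

test_that("the difference sign convention is expert minus rater", {
  e <- flat_scores(10, fill = 3, rater = "expert")
  l <- flat_scores(10, fill = 3)
  l[, ] <- 3
  l[1:4, "Commonality"] <- 4 # rater scores higher -> negative difference
  e2 <- unclass(e); e2[1, "Commonality"] <- 2; e2[2, "Commonality"] <- 4
  rep <- suppressWarnings(agreement_report(score_matrix(e2, "expert"), l,
                                           resamples = 0L, seed = 1))
  expect_lt(rep$mean_diff[rep$criterion == "Commonality"], 0)
})
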