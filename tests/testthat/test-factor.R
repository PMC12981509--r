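# Recursive partial-correlation oracle (conditions one variable at a time),
# independent of the matrix-inverse route used by kmo().
partial_cor_rec <- function(R, i, j, given) {
  if (!length(given)) return(R[i, j])
  k <- given[1]; rest <- given[-1]
  num <- partial_cor_rec(R, i, j, rest) -
    partial_cor_rec(R, i, k, rest) * partial_cor_rec(R, j, k, rest)
  den <- sqrt((1 - partial_cor_rec(R, i, k, rest)^2) *
                (1 - partial_cor_rec(R, j, k, rest)^2))
  num / den
}

block_R <- function(r = 0.6) {
  R <- diag(6)
  R[1:3, 1:3] <- r; R[4:6, 4:6] <- r
  diag(R) <- 1
  R
}

test_that("Bartlett sphericity matches its closed form and degrees of freedom", {
  b0 <- bartlett_sphericity(diag(11), n = 40)
  expect_equal(b0$chi2, 0)
  expect_equal(b0$df, 55)
  expect_equal(b0$p_value, 1)

  R <- matrix(c(1, 0.5, 0.5, 1), 2)
  b <- bartlett_sphericity(R, n = 10)
  expect_equal(b$chi2, 2.1576155, tolerance = 1e-6)
  expect_equal(b$df, 1)

  # invariant under permutation of the variables
  R6 <- block_R()
  perm <- c(4, 1, 6, 2, 5, 3)
  expect_equal(bartlett_sphericity(R6, 100)$chi2,
               bartlett_sphericity(R6[perm, perm], 100)$chi2,
               tolerance = 1e-12)

  bad <- matrix(c(1, 1.2, 1.2, 1), 2)
  expect_error(bartlett_sphericity(bad, 10), "positive-definite")
})

test_that("KMO reduces to 0.5 for two variables and is NaN for identity", {
  for (r in c(0.2, 0.5, -0.7)) {
    R <- matrix(c(1, r, r, 1), 2)
    k <- kmo(R)
    expect_equal(unname(k$msa_per_item), c(0.5, 0.5), tolerance = 1e-12)
    expect_equal(k$msa_overall, 0.5, tolerance = 1e-12)
  }
  k0 <- kmo(diag(3))
  expect_false(k0$defined)
  expect_true(is.nan(k0$msa_overall))
})

test_that("KMO anti-image partials agree with the recursive conditioning oracle", {
  R <- block_R()
  k <- kmo(R)
  # rebuild each item MSA from recursively computed full partial correlations
  for (j in 1:6) {
    others <- setdiff(1:6, j)
    r2 <- sum(R[j, others]^2)
    q2 <- sum(vapply(others, function(i) {
      partial_cor_rec(R, i, j, setdiff(1:6, c(i, j)))^2
    }, numeric(1)))
    expect_equal(unname(k$msa_per_item[j]), r2 / (r2 + q2), tolerance = 1e-10)
  }
  # two strong within-block correlations per item: comfortably factorable
  expect_true(all(k$msa_per_item > 0.6))
  expect_gt(k$msa_overall, 0.6)
})

test_that("parallel analysis recovers planted structure and rejects noise", {
  f1 <- gen_factor_scores(500, uniform_1f_model(), seed = 2)
  expect_equal(parallel_analysis(f1, n_sim = 150, seed = 3)$n_factors, 1L)

  f4 <- gen_factor_scores(500, four_factor_model(), seed = 4)
  expect_equal(parallel_analysis(f4, n_sim = 150, seed = 5)$n_factors, 4L)

  noise <- matrix(rnorm(500 * 11), 500, 11)
  set.seed(60); noise <- matrix(rnorm(500 * 11), 500, 11)
  pa0 <- parallel_analysis(noise, n_sim = 150, seed = 6, criterion = "p95")
  expect_equal(pa0$n_factors, 0L)

  pa_a <- parallel_analysis(f4, n_sim = 100, seed = 9)
  pa_b <- parallel_analysis(f4, n_sim = 100, seed = 9)
  expect_identical(pa_a$eigenvalues_sim, pa_b$eigenvalues_sim)

  degenerate <- cbind(f1[, 1:3], Const = 2)
  expect_error(parallel_analysis(degenerate, n_sim = 10), "Const")
})

test_that("maximum-likelihood extraction recovers planted loadings", {
  gen <- c(0.5, 0.6, 0.7, 0.8, 0.85, 0.9)
  fs <- gen_factor_scores(500, varied_1f_model(gen), seed = 12)
  fit <- efa(fs, k = 1)
  expect_gt(abs(cor(abs(fit$loadings[, 1]), gen)), 0.95)

  f2 <- gen_factor_scores(500, two_block_model(), seed = 13)
  fit2 <- efa(f2, k = 2)
  L <- abs(fit2$loadings)
  within1 <- rowMeans(L[1:3, , drop = FALSE])
  # each block loads dominantly on a single (its own) factor
  dominant <- apply(L, 1, which.max)
  expect_equal(length(unique(dominant[1:3])), 1L)
  expect_equal(length(unique(dominant[4:6])), 1L)
  expect_false(dominant[1] == dominant[4])
  expect_true(all(apply(L, 1, max) > 0.4))

  expect_error(efa(f2, k = 6), "below the number")
})

test_that("criteria group by largest absolute loading with index tie-breaks", {
  L <- rbind(
    "QALYs lost" = c(0.841, 0.1, 0.0, 0.05),
    "Disease modification" = c(-0.776, 0.2, 0.1, 0.0),
    "Flat" = c(0, 0, 0, 0)
  )
  colnames(L) <- paste0("ML", 1:4)
  expect_warning(g <- group_by_loading(L), "tied")
  expect_equal(g$assignment$factor, c("ML1", "ML1", "ML1"))
  expect_equal(g$assignment$loading[2], -0.776)
  expect_true(all(c("QALYs lost", "Disease modification", "Flat") %in%
                    g$groups$ML1))

  # flipping the sign of a whole factor leaves the grouping unchanged
  fs <- gen_factor_scores(400, two_block_model(), seed = 21)
  fit <- efa(fs, k = 2)
  flipped <- fit$loadings
  flipped[, 2] <- -flipped[, 2]
  expect_equal(group_by_loading(fit$loadings)$assignment$factor,
               group_by_loading(flipped)$assignment$factor)
})

test_that("the factor report gates EFA on factorability diagnostics", {
  fs <- gen_factor_scores(500, four_factor_model(), seed = 31)
  rep <- factor_report(fs, n_sim = 100, seed = 32)
  expect_equal(rep$bartlett$df, 55)
  expect_lt(rep$bartlett$p_value, 0.05)
  expect_gt(rep$kmo$msa_overall, 0.6)
  expect_equal(rep$parallel$n_factors, 4L)
  expect_true(rep$efa_run)
  expect_equal(ncol(rep$loadings), 4L)
  expect_equal(sort(unlist(rep$groupings$groups, use.names = FALSE)),
               sort(default_criteria()$name))

  # an unreachable adequacy bar deterministically takes the refusal path
  expect_warning(rep2 <- factor_report(fs, n_sim = 50, seed = 33, min_msa = 0.99),
                 "EFA skipped")
  expect_false(rep2$efa_run)
  expect_null(rep2$loadings)
})
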