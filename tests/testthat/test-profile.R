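# Crosstabs, Pearson chi-square, cluster-membership logistic regression,
# Moran's I.

test_that("crosstab reproduces the published quartile shares from raw counts", {
  cases <- expand_counts(table2_quartile_counts, "nd_quartile")
  ct <- crosstab_raap(cases, "nd_quartile")
  expect_equal(ct$N, 19477L)
  expect_equal(unname(ct$row_totals), c(4870L, 4869L, 4869L, 4869L))
  expect_equal(round(ct$row_pct["Q4", "below"], 1), 17.1)
  expect_equal(round(ct$row_pct["Q1", "below"], 1), 14.2)
  expect_equal(ct$row_pct["Q2", "median"], 38.16)
  expect_equal(unname(ct$col_totals),
               unname(colSums(table2_quartile_counts)))
  # row percentages sum to 100 within rounding
  expect_true(all(abs(rowSums(ct$row_pct) - 100) < 0.02))
  # single case: 100% in one column
  one <- data.frame(g = "only", raap = factor("median",
                                              levels = c("below", "median", "above")))
  ct1 <- crosstab_raap(one, "g")
  expect_equal(unname(ct1$row_pct[1, ]), c(0, 100, 0))
  expect_error(crosstab_raap(one, "nope"), "unknown grouping")
})

test_that("crosstab counts re-aggregate to the cohort RAAP partition", {
  run <- small_labeled_cohort(seed = 91, grid = 5, n = 2000)
  ct <- crosstab_raap(run$cases, "nd_quartile")
  expect_equal(unname(ct$col_totals["below"]), sum(run$cases$raap == "below"))
  expect_equal(ct$N, nrow(run$cases))
})

test_that("Pearson chi-square matches closed forms and a summation oracle", {
  expect_equal(pearson_chi2(matrix(10, 2, 2))$statistic, 0)
  expect_equal(pearson_chi2(matrix(10, 2, 2))$df, 1)
  # 2x2 closed form n(ad - bc)^2 / (r1 r2 c1 c2)
  m <- matrix(c(20, 10, 10, 20), 2, byrow = TRUE)
  expect_equal(pearson_chi2(m)$statistic, 60 * (20 * 20 - 10 * 10)^2 /
                 (30 * 30 * 30 * 30), tolerance = 1e-12)
  expect_equal(round(pearson_chi2(m)$statistic, 4), 6.6667)
  # random 2x3 tables against direct summation, and permutation invariance
  set.seed(5)
  for (i in 1:10) {
    O <- matrix(rpois(6, 30) + 1, 2, 3)
    res <- pearson_chi2(O)
    expect_equal(res$statistic, oracle_chi2(O), tolerance = 1e-10)
    expect_equal(res$df, 2)
    Operm <- O[sample(2), sample(3)]
    expect_equal(pearson_chi2(Operm)$statistic, res$statistic, tolerance = 1e-10)
  }
  expect_error(pearson_chi2(matrix(c(0, 0, 5, 5), 2)), "margin")
})

test_that("pairwise race comparisons run one 2x3 test per pair", {
  counts <- matrix(c(50, 30, 20, 40, 40, 20, 30, 30, 40), 3, byrow = TRUE,
                   dimnames = list(c("White", "non-White", "unknown"),
                                   c("above", "median", "below")))
  cases <- expand_counts(counts, "race")
  pw <- pairwise_race_chi2(cases)
  expect_equal(nrow(pw), 3L)
  expect_true(all(pw$df == 2))
  i <- which(pw$group1 == "White" & pw$group2 == "unknown" |
               pw$group1 == "unknown" & pw$group2 == "White")
  expect_equal(pw$statistic[i],
               oracle_chi2(counts[c("White", "unknown"), ]), tolerance = 1e-10)
})

test_that("logistic fit reproduces saturated 2x2 log-odds and flags degeneracy", {
  x <- rep(c(1, 0), each = 100)
  y <- c(rep(1, 30), rep(0, 70), rep(1, 10), rep(0, 90))
  fit <- fit_cluster_logistic(data.frame(x = x), y)
  expect_true(fit$converged)
  expect_equal(fit$coefficients$estimate[1], log(10 / 90), tolerance = 1e-6)
  expect_equal(fit$coefficients$estimate[2],
               log((30 / 70) / (10 / 90)), tolerance = 1e-6)
  expect_equal(round(fit$coefficients$estimate[2], 4), 1.3499)
  expect_true(all(fit$coefficients$se > 0))
  # all-zero outcome: degenerate, no coefficients
  fit0 <- fit_cluster_logistic(data.frame(x = x), rep(0, 200))
  expect_false(fit0$converged)
  expect_null(fit0$coefficients)
  # perfect separation flagged
  xs <- c(rep(0, 20), rep(10, 20))
  ys <- c(rep(0, 20), rep(1, 20))
  fsep <- fit_cluster_logistic(data.frame(x = xs), ys)
  expect_false(fsep$converged)
})

test_that("logistic fit recovers known coefficients within 2 SE", {
  beta <- c(`(Intercept)` = -1, x1 = 1.5, x2 = -0.8)
  for (n in c(400, 4000)) {
    set.seed(n)
    X <- data.frame(x1 = rnorm(n), x2 = rnorm(n))
    eta <- beta[1] + beta[2] * X$x1 + beta[3] * X$x2
    y <- rbinom(n, 1, plogis(eta))
    fit <- fit_cluster_logistic(X, y)
    expect_true(fit$converged)
    for (k in 1:3) {
      expect_lt(abs(fit$coefficients$estimate[k] - beta[k]),
                2 * fit$coefficients$se[k])
    }
    # univariate mode fits each covariate separately
    uni <- fit_cluster_logistic(X, y, univariate = TRUE)
    expect_named(uni, c("x1", "x2"))
    expect_equal(nrow(uni$x1$coefficients), 2L)
  }
})

test_that("Moran's I matches the double-sum oracle and known signs", {
  # 4-node path graph, values 1..4, row-standardized weights
  W <- path_weights(4)
  x <- 1:4
  res <- morans_i(x, W, permutations = 99, seed = 1)
  expect_equal(res$I, oracle_moran(x, W), tolerance = 1e-12)
  expect_equal(res$expected, -1 / 3)
  # checkerboard on a rook grid: negative autocorrelation by construction
  k <- 4
  Wg <- matrix(0, k * k, k * k)
  for (r in 1:k) for (cc in 1:k) {
    i <- (r - 1) * k + cc
    if (cc < k) { Wg[i, i + 1] <- 1; Wg[i + 1, i] <- 1 }
    if (r < k) { Wg[i, i + k] <- 1; Wg[i + k, i] <- 1 }
  }
  board <- as.vector(outer(1:k, 1:k, function(a, b) (a + b) %% 2))
  expect_lt(morans_i(board, Wg, permutations = 99, seed = 2)$I, 0)
  # agreement with an independent implementation
  skip_if_not_installed("ape")
  set.seed(9)
  v <- rnorm(16)
  Wr <- Wg / rowSums(Wg)
  got <- morans_i(v, Wr, permutations = 49, seed = 3)$I
  expect_equal(got, ape::Moran.I(v, Wr)$observed, tolerance = 1e-10)
})

test_that("the permutation-null mean of Moran's I is exactly -1/(n-1)", {
  # enumerate all 24 permutations of 4 values on a path graph
  W <- path_weights(4)
  vals <- c(0.3, 1.1, 2.5, 4.0)
  perms <- rbind(
    c(1,2,3,4), c(1,2,4,3), c(1,3,2,4), c(1,3,4,2), c(1,4,2,3), c(1,4,3,2),
    c(2,1,3,4), c(2,1,4,3), c(2,3,1,4), c(2,3,4,1), c(2,4,1,3), c(2,4,3,1),
    c(3,1,2,4), c(3,1,4,2), c(3,2,1,4), c(3,2,4,1), c(3,4,1,2), c(3,4,2,1),
    c(4,1,2,3), c(4,1,3,2), c(4,2,1,3), c(4,2,3,1), c(4,3,1,2), c(4,3,2,1)
  )
  Is <- apply(perms, 1, function(p) oracle_moran(vals[p], W))
  expect_equal(mean(Is), -1 / 3, tolerance = 1e-12)
})

test_that("Moran's I is invariant to location and positive scale", {
  W <- path_weights(6)
  set.seed(12)
  x <- rnorm(6)
  base <- morans_i(x, W, permutations = 9, seed = 5)$I
  expect_equal(morans_i(x + 100, W, permutations = 9, seed = 5)$I, base,
               tolerance = 1e-10)
  expect_equal(morans_i(3.7 * x, W, permutations = 9, seed = 5)$I, base,
               tolerance = 1e-10)
  expect_error(morans_i(rep(1, 6), W), "constant")
  expect_error(suppressWarnings(morans_i(x, abs(W) * 0)), "connected")
})

test_that("queen weights connect grid neighbors including diagonals", {
  cfg <- synthetic_config(grid_rows = 3, grid_cols = 3, n_patients = 0, seed = 4)
  geo <- generate_geography(cfg)
  W <- queen_weights(geo, row_standardize = FALSE)
  nbrs <- rowSums(W)
  # 3x3 grid: center has 8 neighbors, corners 3, edges 5
  expect_equal(sort(unname(nbrs)), c(3, 3, 3, 3, 5, 5, 5, 5, 8))
  expect_true(all(diag(W) == 0))
  expect_true(isSymmetric(W))
  Wr <- queen_weights(geo)
  expect_true(all(abs(rowSums(Wr) - 1) < 1e-12))
})
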