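# Poisson spatial scan statistic: windows, LLR, relative risk, Monte Carlo
# inference and cluster detection.

test_that("window system enumerates capped distance prefixes", {
  # a single CBG yields exactly one (singleton) window
  si1 <- scan_input("A", 3, 10, 0, 0)
  w1 <- build_windows(si1)
  expect_equal(w1$len, 1L)
  expect_equal(w1$order, matrix(1L, 1, 1))

  # every emitted window respects the cap (singletons exempt)
  run <- small_labeled_cohort(seed = 51, grid = 5, n = 2000)
  si <- make_scan_input(run$cases, run$geo)
  N <- sum(si$n)
  w <- build_windows(si, max_fraction = 0.5)
  for (j in seq_along(w$len)) {
    if (w$len[j] > 1) expect_lte(w$cum_n[w$len[j], j], 0.5 * N)
    if (w$len[j] < nrow(si)) expect_gt(w$cum_n[w$len[j] + 1, j], 0.5 * N)
  }

  # 3 collinear equidistant centroids: prefixes match brute-force enumeration
  si3 <- scan_input(c("A", "B", "C"), c(1, 1, 1), c(10, 10, 10),
                    x = c(0, 1, 2), y = c(0, 0, 0))
  w3 <- build_windows(si3, max_fraction = 0.5)
  for (j in 1:3) {
    sets <- oracle_prefix_sets(j, si3$cbg_id, si3$x, si3$y)
    for (l in seq_len(w3$len[j])) {
      expect_equal(sort(si3$cbg_id[w3$order[seq_len(l), j]]), sets[[l]])
    }
  }
  expect_error(build_windows(si3, max_fraction = 0.6), "max_fraction")
  expect_error(build_windows(scan_input(c("A", "B"), c(1, 1), c(5, 5),
                                        c(0, 0), c(0, 0))),
               "duplicate centroids")
})

test_that("the LLR closed form evaluates correctly and is one-sided", {
  expect_equal(poisson_llr(5, 5, 100), 0)          # c = E
  expect_equal(poisson_llr(3, 5, 100), 0)          # c < E: high-rate scan
  expect_equal(poisson_llr(10, 5, 100),
               10 * log(2) + 90 * log(90 / 95), tolerance = 1e-12)
  expect_equal(round(poisson_llr(10, 5, 100), 4), 2.0654)
  expect_equal(poisson_llr(0, 5, 100), 0)          # 0*log(0) convention
  expect_error(poisson_llr(10, 0, 100), "between 0 and C")
  expect_error(poisson_llr(10, 100, 100), "between 0 and C")
  # nonnegativity on a random grid
  set.seed(2)
  C <- 50
  c <- sample(0:C, 30, replace = TRUE)
  E <- runif(30, 0.1, C - 0.1)
  expect_true(all(poisson_llr(c, E, C) >= 0))
})

test_that("relative risk matches its closed form with sane boundary cases", {
  expect_equal(window_relative_risk(5, 5, 100), 1)
  expect_equal(window_relative_risk(0, 5, 100), 0)
  expect_equal(window_relative_risk(10, 5, 100), 2 * (95 / 90), tolerance = 1e-12)
  expect_equal(round(window_relative_risk(10, 5, 100), 4), 2.1111)
  expect_warning(rr <- window_relative_risk(100, 5, 100), "infinite")
  expect_identical(rr, Inf)
})

test_that("expected counts are additive over any partition", {
  run <- small_labeled_cohort(seed = 61, grid = 4, n = 1500)
  si <- make_scan_input(run$cases, run$geo)
  C <- sum(si$c); N <- sum(si$n)
  E_i <- C * si$n / N
  expect_equal(sum(E_i), C)
  set.seed(3)
  grp <- sample(1:3, nrow(si), replace = TRUE)
  expect_equal(sum(tapply(E_i, grp, sum)), C)
})

test_that("Monte Carlo p-values respect their rank bounds", {
  si <- scan_input(sprintf("C%d", 1:4), c(20, 1, 1, 1), c(25, 25, 25, 25),
                   x = c(0, 1, 0, 1), y = c(0, 0, 1, 1))
  w <- build_windows(si)
  mc <- monte_carlo_pvalue(si, w, R = 99, seed = 1)
  # extreme concentration: observed beats every null replicate
  expect_equal(mc$p_value, 1 / 100)
  expect_length(mc$null_llr, 99)
  # R = 1 admits only p = 1/2 or 1
  for (s in 1:6) {
    p1 <- monte_carlo_pvalue(si, w, R = 1, seed = s)$p_value
    expect_true(p1 %in% c(0.5, 1))
  }
  expect_error(monte_carlo_pvalue(si, w, R = 0), "R must be")
})

test_that("reported maximum equals the exhaustive brute-force maximum", {
  # randomized small instances (<= 12 CBGs) against the enumeration oracle
  set.seed(14)
  for (rep in 1:8) {
    k <- sample(4:12, 1)
    nvec <- sample(20:60, k, replace = TRUE)
    cvec <- vapply(nvec, function(m) rbinom(1, m, 0.2), integer(1))
    if (sum(cvec) == 0) cvec[1] <- 1L
    si <- scan_input(sprintf("C%02d", 1:k), cvec, nvec,
                     x = runif(k), y = runif(k))
    w <- build_windows(si)
    got <- raapscan:::scan_max_llr(si$c, w, sum(si$c), sum(si$n),
                                   want_argmax = TRUE)
    ora <- oracle_scan_max(si$cbg_id, si$c, si$n, si$x, si$y)
    expect_equal(got$max_llr, ora$max_llr, tolerance = 1e-12)
  }
})

test_that("cluster detection finds dominant and planted clusters", {
  # all cases concentrated in one CBG with equal populations
  si <- scan_input(sprintf("C%d", 1:5), c(0, 0, 12, 0, 0), rep(30, 5),
                   x = c(0, 2, 4, 6, 8), y = rep(0, 5))
  expect_warning(res <- detect_clusters(si, R = 99, seed = 2), "infinite")
  expect_equal(res$clusters[[1]]$cbg_ids, "C3")
  expect_equal(res$clusters[[1]]$n_cbgs, 1L)
  expect_identical(res$clusters[[1]]$rr, Inf)  # all cases inside the window

  # C = 0 yields an empty result with a warning
  si0 <- scan_input(c("A", "B", "C", "D"), rep(0, 4), rep(10, 4),
                    x = 1:4, y = rep(0, 4))
  expect_warning(res0 <- detect_clusters(si0, R = 9), "no cases")
  expect_length(res0$clusters, 0)
})

test_that("scan results are invariant to relabeling and rigid motions", {
  run <- small_labeled_cohort(seed = 71, grid = 4, n = 1200)
  si <- make_scan_input(run$cases, run$geo)
  res <- detect_clusters(si, R = 49, seed = 9)
  # translation + rotation of all centroids
  th <- 0.7
  xr <- cos(th) * si$x - sin(th) * si$y + 100
  yr <- sin(th) * si$x + cos(th) * si$y - 50
  si_rot <- scan_input(si$cbg_id, si$c, si$n, xr, yr)
  res_rot <- detect_clusters(si_rot, R = 49, seed = 9)
  expect_equal(res_rot$max_llr, res$max_llr, tolerance = 1e-9)
  expect_equal(res_rot$p_value, res$p_value)
  expect_equal(sort(res_rot$clusters[[1]]$cbg_ids),
               sort(res$clusters[[1]]$cbg_ids))
  # relabeling CBGs leaves the p-value unchanged (same geometry, new names)
  relab <- sprintf("Z%02d", seq_len(nrow(si)))
  si_rel <- scan_input(relab, si$c, si$n, si$x, si$y)
  res_rel <- detect_clusters(si_rel, R = 49, seed = 9)
  expect_equal(res_rel$p_value, res$p_value)
  expect_equal(res_rel$max_llr, res$max_llr)
})

test_that("adding cases to the best window does not decrease its LLR", {
  run <- small_labeled_cohort(seed = 81, grid = 4, n = 1200)
  si <- make_scan_input(run$cases, run$geo)
  res <- detect_clusters(si, R = 9, seed = 1)
  cl <- res$clusters[[1]]
  idx <- match(cl$cbg_ids, si$cbg_id)
  si2 <- si
  # move 5 cases into the argmax window from outside (totals C grows)
  room <- si2$n[idx[1]] - si2$c[idx[1]]
  add <- min(5L, room)
  si2$c[idx[1]] <- si2$c[idx[1]] + add
  C2 <- sum(si2$c); N2 <- sum(si2$n)
  w <- build_windows(si2)
  E2 <- C2 * sum(si2$n[idx]) / N2
  llr2 <- poisson_llr(cl$c + add, E2, C2)
  expect_gte(llr2, cl$llr - 1e-9)
})
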