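## Disparity and cluster characterization: RAAP cross-tabulations with
## Pearson chi-square, logistic regression of CBG cluster membership on
## neighborhood covariates, and Moran's I on model residuals.

#' Cross-tabulate RAAP against a grouping variable
#'
#' Counts and row percentages of the 3-level RAAP label (columns ordered
#' above / median / below, i.e., high to low prophylaxis) by neighborhood
#' disadvantage quartile, race, or any other case-level grouping.
#'
#' @param cases labeled data.frame with a `raap` column.
#' @param by name of the grouping column (e.g., `"nd_quartile"`, `"race"`).
#' @return a `raap_crosstab`: list with `counts` (r x 3 integer matrix),
#'   `row_pct` (percentages to 2 decimals), `row_totals`, `col_totals`, `N`.
#' @export
crosstab_raap <- function(cases, by) {
  if (!by %in% names(cases)) stop("unknown grouping column: ", by)
  if (anyNA(cases[[by]]) || anyNA(cases$raap)) stop("missing labels in crosstab input")
  tab <- table(cases[[by]], factor(cases$raap, levels = c("above", "median", "below")))
  counts <- matrix(as.integer(tab), nrow = nrow(tab),
                   dimnames = list(rownames(tab), c("above", "median", "below")))
  row_totals <- rowSums(counts)
  pct <- round(100 * counts / row_totals, 2)
  structure(list(counts = counts, row_pct = pct, row_totals = row_totals,
                 col_totals = colSums(counts), N = sum(counts), by = by),
            class = "raap_crosstab")
}

#' @export
print.raap_crosstab <- function(x, ...) {
  cat(sprintf("RAAP by %s (N = %d)\n", x$by, x$N))
  disp <- matrix(sprintf("%d (%.2f)", x$counts, x$row_pct),
                 nrow = nrow(x$counts), dimnames = dimnames(x$counts))
  print(cbind(disp, total = as.character(x$row_totals)), quote = FALSE)
  invisible(x)
}

#' Pearson chi-square test of independence
#'
#' Classical `sum((O - E)^2 / E)` statistic with expected counts from the
#' row/column margins, `(r - 1)(c - 1)` degrees of freedom and the asymptotic
#' chi-square p-value; no continuity correction.
#'
#' @param counts integer matrix of observed counts (r x c), or a
#'   `raap_crosstab`.
#' @return list with `statistic`, `df`, `p_value`, `expected`.
#' @export
pearson_chi2 <- function(counts) {
  if (inherits(counts, "raap_crosstab")) counts <- counts$counts
  counts <- as.matrix(counts)
  if (any(rowSums(counts) == 0) || any(colSums(counts) == 0)) {
    stop("zero row or column margin in contingency table")
  }
  ht <- stats::chisq.test(counts, correct = FALSE)
  if (any(ht$expected <= 0)) stop("expected cell count <= 0")
  list(statistic = unname(ht$statistic), df = unname(ht$parameter),
       p_value = unname(ht$p.value), expected = ht$expected)
}

#' Pairwise RAAP chi-square comparisons between race categories
#'
#' One 2 x 3 Pearson chi-square per pair of race categories, on the raw
#' (uncorrected) p-value scale.
#'
#' @param cases labeled data.frame with `race` and `raap` columns.
#' @return data.frame with one row per pair: `group1`, `group2`,
#'   `statistic`, `df`, `p_value`.
#' @export
pairwise_race_chi2 <- function(cases) {
  ct <- crosstab_raap(cases, "race")$counts
  groups <- rownames(ct)
  pairs <- utils::combn(groups, 2)
  out <- apply(pairs, 2, function(pr) {
    res <- pearson_chi2(ct[pr, , drop = FALSE])
    data.frame(group1 = pr[1], group2 = pr[2], statistic = res$statistic,
               df = res$df, p_value = res$p_value, stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Logistic regression of cluster membership on CBG covariates
#'
#' Maximum-likelihood fit by iteratively reweighted least squares
#' (`stats::glm`, binomial logit; convergence when the relative deviance
#' change drops below 1e-8, at most 25 iterations), with Wald standard
#' errors from the inverse Fisher information. In univariate mode each
#' covariate is fit in its own model. Degenerate outcomes (all 0 or all 1)
#' and separation are flagged as non-converged and no coefficients are
#' reported for that fit.
#'
#' @param X data.frame or matrix of CBG-level covariates.
#' @param y binary cluster-membership indicator (0/1), one per CBG row.
#' @param univariate fit one single-covariate model per column instead of the
#'   joint model.
#' @return a `raap_logit` (multivariate) or list of them (univariate): each
#'   with `coefficients` data.frame (`estimate`, `se`, `z`, `p_value`),
#'   `deviance`, `converged`, and the underlying `glm` fit.
#' @export
fit_cluster_logistic <- function(X, y, univariate = FALSE) {
  X <- as.data.frame(X)
  stopifnot(nrow(X) == length(y))
  if (nrow(X) <= ncol(X)) stop("need more CBG rows than covariates")
  if (univariate) {
    fits <- lapply(names(X), function(nm) {
      fit_cluster_logistic(X[, nm, drop = FALSE], y, univariate = FALSE)
    })
    names(fits) <- names(X)
    return(fits)
  }
  df <- cbind(.y = as.numeric(y), X)
  degenerate <- length(unique(df$.y)) < 2
  fit <- suppressWarnings(
    stats::glm(.y ~ ., data = df, family = stats::binomial(),
               control = stats::glm.control(epsilon = 1e-8, maxit = 25))
  )
  mu <- stats::fitted(fit)
  separated <- any(mu > 1 - 1e-8) || any(mu < 1e-8)
  sm <- suppressWarnings(summary(fit))
  se <- sm$coefficients[, "Std. Error"]
  converged <- fit$converged && !fit$boundary && !degenerate && !separated &&
    all(is.finite(se)) && all(se < 1e3)
  coefs <- NULL
  if (converged) {
    coefs <- data.frame(
      term = rownames(sm$coefficients),
      estimate = sm$coefficients[, "Estimate"],
      se = se,
      z = sm$coefficients[, "z value"],
      p_value = sm$coefficients[, "Pr(>|z|)"],
      row.names = NULL, stringsAsFactors = FALSE
    )
  }
  structure(list(coefficients = coefs, deviance = fit$deviance,
                 converged = converged, fit = fit),
            class = "raap_logit")
}

#' @export
print.raap_logit <- function(x, ...) {
  if (!x$converged) {
    cat("raap_logit: did not converge (degenerate outcome or separation); no coefficients reported\n")
    return(invisible(x))
  }
  cat(sprintf("raap_logit (deviance %.3f)\n", x$deviance))
  print(x$coefficients, row.names = FALSE, digits = 4)
  invisible(x)
}

#' Queen-contiguity spatial weights from polygon geography
#'
#' Two block groups are neighbors when their rings share at least one vertex
#' (within a snapping tolerance) — the conventional queen rule for tiled
#' polygon layers, where adjacent polygons reuse boundary vertices. Weights
#' are row-standardized by default. Block groups with no neighbors keep a
#' zero row.
#'
#' @param geography a `raap_geography`.
#' @param row_standardize divide each row by its sum (rows of all zeros stay
#'   zero).
#' @param snap vertex-matching tolerance.
#' @return K x K weight matrix with zero diagonal, dimnames = `cbg_id`.
#' @export
queen_weights <- function(geography, row_standardize = TRUE, snap = 1e-7) {
  stopifnot(inherits(geography, "raap_geography"))
  k <- nrow(geography)
  verts <- lapply(geography$polygon, function(r) {
    unique(round(r[-nrow(r), , drop = FALSE] / snap))
  })
  keys <- lapply(verts, function(v) paste(v[, 1], v[, 2]))
  W <- matrix(0, k, k, dimnames = list(geography$cbg_id, geography$cbg_id))
  for (i in seq_len(k - 1)) {
    for (j in (i + 1):k) {
      if (any(keys[[i]] %in% keys[[j]])) {
        W[i, j] <- 1
        W[j, i] <- 1
      }
    }
  }
  if (row_standardize) {
    rs <- rowSums(W)
    pos <- rs > 0
    W[pos, ] <- W[pos, , drop = FALSE] / rs[pos]
  }
  W
}

#' Moran's I with permutation inference
#'
#' Global spatial autocorrelation
#' `I = (n / S0) * sum_ij w_ij (x_i - xbar)(x_j - xbar) / sum_i (x_i - xbar)^2`
#' with `S0 = sum_ij w_ij`, null expectation `-1/(n-1)`, and a two-sided
#' permutation p-value obtained by shuffling the value labels over the
#' locations with the weights fixed
#' (`p = min(1, 2 * min(Pr(I* >= I), Pr(I* <= I)))`, each tail with the
#' `+1` correction).
#'
#' @param x numeric values, one per location (not all equal).
#' @param W nonnegative weight matrix with zero diagonal. Locations with an
#'   all-zero weight row and column (no neighbors) are dropped with a
#'   warning before computing.
#' @param permutations number of permutations.
#' @param seed integer seed.
#' @return a `raap_moran`: list with `I`, `expected`, `p_value`,
#'   `permutations`, `weight_scheme`, `n`.
#' @export
morans_i <- function(x, W, permutations = 999, seed = 1) {
  W <- as.matrix(W)
  n <- length(x)
  stopifnot(nrow(W) == n, ncol(W) == n)
  if (any(W < 0)) stop("weights must be nonnegative")
  if (any(diag(W) != 0)) stop("weight matrix must have a zero diagonal")
  isolated <- rowSums(W) == 0 & colSums(W) == 0
  if (any(isolated)) {
    warning(sum(isolated), " location(s) with no neighbors dropped from Moran's I")
    W <- W[!isolated, !isolated, drop = FALSE]
    x <- x[!isolated]
    n <- length(x)
  }
  if (n < 3) stop("Moran's I needs at least 3 connected locations")
  if (stats::var(x) == 0) stop("Moran's I is undefined for constant values")
  S0 <- sum(W)
  if (S0 == 0) stop("weight matrix sums to zero")
  stat <- function(v) {
    z <- v - mean(v)
    (n / S0) * as.numeric(z %*% W %*% z) / sum(z^2)
  }
  I_obs <- stat(x)
  perm <- with_local_seed(seed, function() {
    vapply(seq_len(permutations), function(i) stat(sample(x)), numeric(1))
  })
  p_hi <- (1 + sum(perm >= I_obs)) / (permutations + 1)
  p_lo <- (1 + sum(perm <= I_obs)) / (permutations + 1)
  structure(list(I = I_obs, expected = -1 / (n - 1),
                 p_value = min(1, 2 * min(p_hi, p_lo)),
                 permutations = permutations,
                 weight_scheme = "user-supplied (zero-diagonal, nonnegative)",
                 n = n),
            class = "raap_moran")
}

#' @export
print.raap_moran <- function(x, ...) {
  cat(sprintf("Moran's I = %.4f (null expectation %.4f), permutation p = %s [n = %d, %d permutations]\n",
              x$I, x$expected, format.pval(x$p_value, digits = 3), x$n,
              x$permutations))
  invisible(x)
}
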