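# Independent oracles and shared fixtures. Each oracle re-derives its
# quantity from first principles (explicit loops, closed forms), never
# through the package code paths it checks.

# Exhaustive Poisson-scan maximum: enumerate every center, every distance
# prefix (ties by cbg_id), apply the population cap (singletons always
# allowed), and evaluate the one-sided LLR directly.
oracle_scan_max <- function(cbg_id, cvec, nvec, x, y, max_fraction = 0.5) {
  C <- sum(cvec); N <- sum(nvec); k <- length(cvec)
  best <- -Inf; best_members <- NULL
  for (j in seq_len(k)) {
    d <- sqrt((x - x[j])^2 + (y - y[j])^2)
    o <- order(d, cbg_id)
    for (l in seq_len(k)) {
      members <- o[seq_len(l)]
      nw <- sum(nvec[members])
      if (l > 1 && nw > max_fraction * N) break
      cw <- sum(cvec[members])
      E <- C * nw / N
      if (E <= 0 || E >= C) next
      llr <- 0
      if (cw > E) {
        t1 <- if (cw > 0) cw * log(cw / E) else 0
        t2 <- if (C - cw > 0) (C - cw) * log((C - cw) / (C - E)) else 0
        llr <- t1 + t2
      }
      if (llr > best) {
        best <- llr
        best_members <- sort(cbg_id[members])
      }
    }
  }
  list(max_llr = best, members = best_members)
}

# All distance-prefix member sets for a center, by brute force.
oracle_prefix_sets <- function(center, cbg_id, x, y) {
  d <- sqrt((x - x[center])^2 + (y - y[center])^2)
  o <- order(d, cbg_id)
  lapply(seq_along(o), function(l) sort(cbg_id[o[seq_len(l)]]))
}

# Pearson chi-square by direct summation over cells.
oracle_chi2 <- function(O) {
  E <- outer(rowSums(O), colSums(O)) / sum(O)
  sum((O - E)^2 / E)
}

# Moran's I by explicit double loop.
oracle_moran <- function(x, W) {
  n <- length(x); xb <- mean(x); S0 <- sum(W)
  num <- 0
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      num <- num + W[i, j] * (x[i] - xb) * (x[j] - xb)
    }
  }
  (n / S0) * num / sum((x - xb)^2)
}

# The published quartile-by-RAAP contingency block (printed counts used as
# test inputs; columns ordered high -> low prophylaxis).
table2_quartile_counts <- matrix(
  c(2390, 1788, 692,
    2331, 1858, 680,
    2128, 1962, 779,
    2001, 2033, 835),
  nrow = 4, byrow = TRUE,
  dimnames = list(c("Q1", "Q2", "Q3", "Q4"), c("above", "median", "below"))
)

# Expand a counts matrix into one labeled row per patient.
expand_counts <- function(counts, group_col = "group") {
  rows <- lapply(rownames(counts), function(g) {
    lapply(colnames(counts), function(r) {
      n <- counts[g, r]
      if (n == 0) return(NULL)
      data.frame(group = rep(g, n), raap = rep(r, n), stringsAsFactors = FALSE)
    })
  })
  df <- do.call(rbind, unlist(rows, recursive = FALSE))
  names(df)[1] <- group_col
  df$raap <- factor(df$raap, levels = c("below", "median", "above"))
  df
}

# A fully labeled small synthetic cohort, shared by cohort/scan/profile tests.
small_labeled_cohort <- function(seed = 11, grid = 6, n = 2500, or = 1.5) {
  cfg <- synthetic_config(grid_rows = grid, grid_cols = grid, n_patients = n,
                          planted_undertreat_or = or, seed = seed)
  geo <- generate_geography(cfg)
  gen <- generate_cohort(cfg, geo)
  lab <- label_raap(apply_inclusion(geocode_cases(gen$cases, geo))$cases)
  lab$nd_quartile <- assign_quartiles(lab$nd, lab$cbg_id, lab$patient_id)
  list(cfg = cfg, geo = geo, truth = gen$truth, cases = lab)
}

# Rook/row-standardized weights of a path graph 1-2-...-n.
path_weights <- function(n, row_standardize = TRUE) {
  W <- matrix(0, n, n)
  for (i in seq_len(n - 1)) {
    W[i, i + 1] <- 1
    W[i + 1, i] <- 1
  }
  if (row_standardize) W <- W / rowSums(W)
  W
}
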