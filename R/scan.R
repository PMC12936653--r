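## Poisson spatial scan statistic (Kulldorff-style) for clusters of low-RAAP
## cases: circular (distance-prefix) windows over CBG centroids, one-sided
## high-rate log-likelihood ratio, Monte Carlo inference conditional on the
## total case count, and relative risks.

#' Aggregate labeled cases to per-CBG scan counts
#'
#' @param cases labeled patient data.frame with `cbg_id` and `raap` columns.
#' @param geography a `raap_geography` supplying centroids; every CBG appears
#'   in the result (zero counts where no patient lives).
#' @param case_level which RAAP label counts as a "case" (default `below`:
#'   under-treatment).
#' @return a `raap_scan_input` data.frame with columns `cbg_id`, `c`
#'   (cases), `n` (at-risk patients), `x`, `y` (centroids).
#' @export
make_scan_input <- function(cases, geography, case_level = "below") {
  stopifnot(inherits(geography, "raap_geography"))
  if (anyNA(cases$cbg_id)) stop("cases contain unassigned cbg_id; apply inclusion first")
  idx <- match(cases$cbg_id, geography$cbg_id)
  if (anyNA(idx)) stop("cases reference cbg_id absent from geography")
  n_i <- tabulate(idx, nbins = nrow(geography))
  c_i <- tabulate(idx[cases$raap == case_level], nbins = nrow(geography))
  scan_input(geography$cbg_id, c_i, n_i, geography$cx, geography$cy)
}

#' Construct a scan input from raw counts
#'
#' @param cbg_id identifiers; `c` case counts; `n` at-risk counts; `x`, `y`
#'   planar centroid coordinates.
#' @return a `raap_scan_input`.
#' @export
scan_input <- function(cbg_id, c, n, x, y) {
  stopifnot(length(cbg_id) == length(c), length(c) == length(n),
            length(n) == length(x), length(x) == length(y))
  if (any(c < 0) || any(n < 0) || any(c > n)) stop("need 0 <= c_i <= n_i")
  df <- data.frame(cbg_id = as.character(cbg_id), c = as.integer(c),
                   n = as.integer(n), x = x, y = y, stringsAsFactors = FALSE)
  class(df) <- c("raap_scan_input", "data.frame")
  df
}

#' Build the circular scan window system
#'
#' For each center CBG, candidate windows are the nested prefixes of all CBGs
#' sorted by Euclidean centroid distance from the center (ties broken by
#' `cbg_id`), truncated at the largest prefix whose cumulative at-risk count
#' does not exceed `max_fraction * N`. Every singleton window is always kept,
#' even when a single CBG alone exceeds the cap.
#'
#' @param scan_input a `raap_scan_input`.
#' @param max_fraction maximum fraction of the at-risk population a window
#'   may cover, in (0, 0.5].
#' @return a `raap_windows` list: `order` (K x K matrix, column j = CBG
#'   indices by distance from center j), `len` (max prefix length per
#'   center), `cum_n` (cumulative at-risk counts along each column).
#' @export
build_windows <- function(scan_input, max_fraction = 0.5) {
  if (max_fraction <= 0 || max_fraction > 0.5) {
    stop("max_fraction must lie in (0, 0.5]")
  }
  k <- nrow(scan_input)
  key <- paste(scan_input$x, scan_input$y)
  dup <- duplicated(key)
  if (any(dup)) stop("duplicate centroids in scan input")
  N <- sum(scan_input$n)
  ord <- matrix(0L, k, k)
  cum_n <- matrix(0, k, k)
  len <- integer(k)
  for (j in seq_len(k)) {
    d <- sqrt((scan_input$x - scan_input$x[j])^2 + (scan_input$y - scan_input$y[j])^2)
    o <- order(d, scan_input$cbg_id, method = "radix")
    ord[, j] <- o
    cn <- cumsum(scan_input$n[o])
    cum_n[, j] <- cn
    len[j] <- max(1L, sum(cn <= max_fraction * N))
  }
  structure(list(order = ord, len = len, cum_n = cum_n,
                 cbg_id = scan_input$cbg_id, max_fraction = max_fraction),
            class = "raap_windows")
}

# x * log(x / y) with the 0 * log(0) = 0 convention.
xlogxy <- function(x, y) {
  out <- numeric(length(x))
  pos <- x > 0
  out[pos] <- x[pos] * log(x[pos] / y[pos])
  out
}

#' Poisson scan log-likelihood ratio of a window
#'
#' One-sided (high-rate) LLR:
#' `c*log(c/E) + (C-c)*log((C-c)/(C-E))` when the rate inside exceeds the
#' rate outside (equivalently `c > E`), else 0. Vectorized.
#'
#' @param c observed cases in the window.
#' @param E expected cases `C * n_window / N`.
#' @param C total cases in the study region.
#' @return nonnegative LLR values.
#' @export
poisson_llr <- function(c, E, C) {
  if (any(E <= 0) || any(E >= C)) stop("E must lie strictly between 0 and C")
  if (any(c < 0) || any(c > C)) stop("need 0 <= c <= C")
  llr <- xlogxy(c, E) + xlogxy(C - c, C - E)
  ifelse(c > E, llr, 0)
}

#' Relative risk of a window
#'
#' Rate inside the window relative to the rate outside:
#' `(c/E) / ((C-c)/(C-E))`. Zero when the window holds no cases; infinite
#' (with a warning) when it holds all of them.
#'
#' @inheritParams poisson_llr
#' @return relative risk values.
#' @export
window_relative_risk <- function(c, E, C) {
  if (any(E <= 0) || any(E >= C)) stop("E must lie strictly between 0 and C")
  if (any(c == C)) warning("window contains all cases; relative risk is infinite")
  ifelse(c == C, Inf, (c / E) / ((C - c) / (C - E)))
}

# Max LLR over all windows for one case vector. Returns the maximum and the
# (prefix length, center) attaining it under the tie rule: fewer members,
# then lowest center cbg_id.
scan_max_llr <- function(c_vec, windows, C, N, want_argmax = FALSE) {
  k <- length(c_vec)
  cmat <- matrix(c_vec[windows$order], k, k)
  ccum <- apply(cmat, 2, cumsum)
  if (k == 1) ccum <- matrix(ccum, 1, 1)
  Emat <- C * windows$cum_n / N
  valid <- row(Emat) <= rep(windows$len, each = k) & Emat > 0 & Emat < C
  llr <- xlogxy(ccum, Emat) + xlogxy(C - ccum, C - Emat)
  dim(llr) <- dim(ccum)
  llr[ccum <= Emat] <- 0
  llr[!valid] <- -Inf
  best <- max(llr)
  if (!want_argmax) return(list(max_llr = best))
  hits <- which(llr == best, arr.ind = TRUE)
  # tie rule: fewest members (row), then lowest center cbg_id (column rank)
  center_rank <- rank(windows$cbg_id, ties.method = "first")
  o <- order(hits[, 1], center_rank[hits[, 2]])
  pick <- hits[o[1], ]
  list(max_llr = best, length = unname(pick[1]), center = unname(pick[2]),
       llr = llr)
}

#' Monte Carlo p-value for the maximum scan statistic
#'
#' Each null replicate redistributes the `C` cases across CBGs multinomially
#' with probabilities `n_i / N` (the conditional Poisson null) and recomputes
#' the maximum LLR over all windows. The p-value is
#' `(1 + #{null max >= observed max}) / (R + 1)`.
#'
#' @param scan_input a `raap_scan_input`.
#' @param windows a `raap_windows` built from it.
#' @param R number of Monte Carlo replicates (>= 1).
#' @param seed integer seed for the replicate stream.
#' @param observed_c optional replacement case vector to score against the
#'   null (defaults to the scan input's counts). Useful for calibration
#'   studies where the observed counts are themselves drawn from the
#'   conditional Poisson null, which does not cap a CBG's cases at its
#'   at-risk count.
#' @return list with `max_llr_observed`, `p_value`, `null_llr` (length-`R`
#'   vector of null maxima).
#' @export
monte_carlo_pvalue <- function(scan_input, windows, R = 999, seed = 1,
                               observed_c = scan_input$c) {
  if (R < 1) stop("R must be >= 1")
  if (length(observed_c) != nrow(scan_input) || any(observed_c < 0)) {
    stop("observed_c must be a nonnegative vector over the scan input's CBGs")
  }
  C <- sum(observed_c)
  N <- sum(scan_input$n)
  obs <- scan_max_llr(observed_c, windows, C, N)$max_llr
  null_llr <- with_local_seed(seed, function() {
    prob <- scan_input$n / N
    vapply(seq_len(R), function(r) {
      cstar <- as.vector(stats::rmultinom(1, C, prob))
      scan_max_llr(cstar, windows, C, N)$max_llr
    }, numeric(1))
  })
  p <- (1 + sum(null_llr >= obs)) / (R + 1)
  list(max_llr_observed = obs, p_value = p, null_llr = null_llr)
}

#' Detect spatial clusters of excess cases
#'
#' Runs the full Poisson spatial scan: builds the circular window system,
#' finds the most likely cluster (maximum LLR; ties resolved toward fewer
#' members, then the lowest center `cbg_id`), assigns Monte Carlo p-values by
#' comparing each cluster's LLR to the null distribution of the maximum, and
#' reports secondary clusters in decreasing LLR among windows sharing no CBG
#' with an already-reported cluster. The most likely cluster is always
#' reported; additional clusters are reported while significant at `alpha`.
#'
#' @param scan_input a `raap_scan_input`.
#' @param max_fraction window population cap, in (0, 0.5].
#' @param R Monte Carlo replicates.
#' @param alpha significance level for reported secondary clusters.
#' @param seed integer seed.
#' @return a `raap_scan_result`: list of clusters (each with member
#'   `cbg_ids`, `c`, `E`, `llr`, `rr`, `p_value`, `significant`, and
#'   per-member CBG relative risks), plus totals and the null LLR
#'   distribution. All evaluated windows remain retrievable through the
#'   `windows` and `llr_matrix` elements.
#' @export
detect_clusters <- function(scan_input, max_fraction = 0.5, R = 999,
                            alpha = 0.05, seed = 1) {
  C <- sum(scan_input$c)
  N <- sum(scan_input$n)
  if (C == 0) {
    warning("no cases in scan input; nothing to detect")
    return(structure(list(clusters = list(), C = 0L, N = N,
                          windows = NULL, llr_matrix = NULL,
                          null_llr = numeric(0)),
                     class = "raap_scan_result"))
  }
  windows <- build_windows(scan_input, max_fraction)
  obs <- scan_max_llr(scan_input$c, windows, C, N, want_argmax = TRUE)
  mc <- monte_carlo_pvalue(scan_input, windows, R = R, seed = seed)

  k <- nrow(scan_input)
  E_i <- C * scan_input$n / N
  llr <- obs$llr
  # enumerate windows in decreasing LLR for greedy non-overlapping reporting
  pos <- which(llr > 0)
  center_rank <- rank(windows$cbg_id, ties.method = "first")
  pos <- pos[order(-llr[pos],
                   (pos - 1) %% k + 1,
                   center_rank[(pos - 1) %/% k + 1])]
  used <- rep(FALSE, k)
  clusters <- list()
  for (w in pos) {
    l <- (w - 1) %% k + 1
    j <- (w - 1) %/% k + 1
    members <- windows$order[seq_len(l), j]
    if (any(used[members])) next
    cw <- sum(scan_input$c[members])
    Ew <- C * sum(scan_input$n[members]) / N
    pval <- (1 + sum(mc$null_llr >= llr[w])) / (R + 1)
    signif <- pval <= alpha
    if (length(clusters) > 0 && !signif) break
    member_ids <- scan_input$cbg_id[members]
    rr_members <- vapply(members, function(i) {
      if (scan_input$c[i] == C) Inf
      else (scan_input$c[i] / E_i[i]) / ((C - scan_input$c[i]) / (C - E_i[i]))
    }, numeric(1))
    clusters[[length(clusters) + 1]] <- list(
      center_cbg_id = scan_input$cbg_id[j],
      cbg_ids = member_ids,
      n_cbgs = length(members),
      c = cw, E = Ew,
      n = sum(scan_input$n[members]),
      llr = llr[w],
      rr = window_relative_risk(cw, Ew, C),
      cbg_rr = stats::setNames(rr_members, member_ids),
      p_value = pval,
      significant = signif
    )
    used[members] <- TRUE
    if (!signif) break
  }
  structure(list(clusters = clusters, C = C, N = N, windows = windows,
                 llr_matrix = llr, null_llr = mc$null_llr,
                 alpha = alpha, R = R,
                 max_llr = mc$max_llr_observed, p_value = mc$p_value),
            class = "raap_scan_result")
}

#' @export
print.raap_scan_result <- function(x, ...) {
  cat(sprintf("raap_scan_result: %d cases among %d at risk\n", x$C, x$N))
  if (!length(x$clusters)) {
    cat("  no clusters detected\n")
    return(invisible(x))
  }
  for (i in seq_along(x$clusters)) {
    cl <- x$clusters[[i]]
    cat(sprintf(
      "  %s cluster: %d CBGs, %d obs / %.2f exp, RR %.2f, LLR %.3f, p %s\n",
      if (i == 1) "most likely" else "secondary",
      cl$n_cbgs, cl$c, cl$E, cl$rr, cl$llr,
      format.pval(cl$p_value, digits = 3)))
  }
  invisible(x)
}
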