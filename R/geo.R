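## Geocoding surrogate: point-to-CBG assignment, neighborhood disadvantage,
## and patient-level ND quartiles.

#' Neighborhood-disadvantage index
#'
#' ND is the arithmetic mean of five census proportions: non-Hispanic Black
#' population, female-headed families, households on public assistance or
#' food stamps, income below the federal poverty level, and unemployment.
#' Higher values indicate more disadvantage. Vectorized.
#'
#' @param p_nhblack,p_female_headed,p_public_assist,p_poverty,p_unemployed
#'   proportions in \[0, 1\].
#' @return numeric vector of ND values in \[0, 1\].
#' @export
compute_nd <- function(p_nhblack, p_female_headed, p_public_assist,
                       p_poverty, p_unemployed) {
  p <- cbind(p_nhblack, p_female_headed, p_public_assist, p_poverty, p_unemployed)
  if (anyNA(p)) stop("ND proportions contain missing values")
  if (any(p < 0 | p > 1)) stop("ND proportions must lie in [0, 1]")
  rowMeans(p)
}

#' Assign points to census block groups
#'
#' Planar point-in-polygon containment against the geography, the surrogate
#' for street-address geocoding. Polygons are tested in their stored (sorted
#' `cbg_id`) order; a point on a shared boundary therefore resolves to the
#' lowest-index containing polygon, and a point contained by no polygon gets
#' `NA` (unmatched).
#'
#' @param x,y numeric point coordinates (may contain `NA` for cases whose
#'   geocode failed upstream; these come back `NA`).
#' @param geography a `raap_geography`.
#' @return character vector of `cbg_id` values, `NA` where unmatched.
#' @export
assign_cbg <- function(x, y, geography) {
  stopifnot(inherits(geography, "raap_geography"), length(x) == length(y))
  out <- rep(NA_character_, length(x))
  usable <- !is.na(x) & !is.na(y)
  if (!any(usable)) return(out)
  pending <- which(usable)
  for (i in seq_len(nrow(geography))) {
    if (!length(pending)) break
    ring <- geography$polygon[[i]]
    bb <- c(range(ring[, 1]), range(ring[, 2]))
    px <- x[pending]; py <- y[pending]
    near <- px >= bb[1] - 1e-9 & px <= bb[2] + 1e-9 &
            py >= bb[3] - 1e-9 & py <= bb[4] + 1e-9
    if (!any(near)) next
    cand <- pending[near]
    hit <- point_in_ring(x[cand], y[cand], ring)
    if (any(hit)) {
      out[cand[hit]] <- geography$cbg_id[i]
      pending <- setdiff(pending, cand[hit])
    }
  }
  out
}

#' Attach CBG id and neighborhood disadvantage to patient cases
#'
#' Runs [assign_cbg()] on every case with a usable point and joins the
#' containing block group's ND index. Cases with no usable point (failed
#' geocode) or no containing polygon stay `NA` and are expected to be dropped
#' by the inclusion rules downstream.
#'
#' @param cases patient case data.frame with `x`, `y` columns.
#' @param geography a `raap_geography`.
#' @return `cases` with `cbg_id` and `nd` columns appended.
#' @export
geocode_cases <- function(cases, geography) {
  cases$cbg_id <- assign_cbg(cases$x, cases$y, geography)
  idx <- match(cases$cbg_id, geography$cbg_id)
  cases$nd <- geography$nd[idx]
  cases
}

#' Patient-level neighborhood-disadvantage quartiles
#'
#' Quartiles are computed on the patient-level ND distribution so each group
#' holds as near one quarter of the cohort as possible: patients are stably
#' sorted by `(nd, cbg_id, patient_id)` and split into four contiguous blocks
#' of sizes `q+1` (first `r` blocks) and `q`, where `N = 4q + r`. Q1 is the
#' least disadvantaged quartile. Ties in ND are broken deterministically by
#' the sort key, so the assignment is invariant to input order.
#'
#' @param nd numeric ND values, one per patient.
#' @param cbg_id,patient_id tie-breaking keys, same length as `nd`.
#' @return factor with levels `Q1` < `Q2` < `Q3` < `Q4`, aligned to the input.
#' @export
assign_quartiles <- function(nd, cbg_id = seq_along(nd), patient_id = seq_along(nd)) {
  n <- length(nd)
  if (n < 4) stop("at least 4 patients are required for quartile assignment")
  if (anyNA(nd)) stop("ND values contain missing values")
  ord <- order(nd, as.character(cbg_id), as.character(patient_id), method = "radix")
  q <- n %/% 4L
  r <- n %% 4L
  sizes <- rep(q, 4L) + c(rep(1L, r), rep(0L, 4L - r))
  lab <- rep(factor(paste0("Q", 1:4), levels = paste0("Q", 1:4), ordered = TRUE), sizes)
  out <- lab
  out[ord] <- lab
  out
}
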