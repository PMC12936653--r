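## Synthetic study region and cohort generator.
##
## Emulates the statistical structure the disparity analysis assumes: a
## contiguous planar grid of census block groups with Beta-distributed census
## proportions and a monotone deprivation trend toward a focal point, a
## surgical cohort whose risk-factor prevalences match a real tertiary-center
## case mix, intervention counts tied to PONV risk through a binomial-logistic
## model, and a planted circular region where the odds of receiving each
## prophylactic intervention are divided by a configurable factor.

#' Build a synthetic-study configuration
#'
#' Returns the full set of generator parameters with defaults calibrated to
#' the final-cohort case mix of a large academic surgical population: 56%
#' female, 98.6% nonsmokers, 11.1% with PONV/motion-sickness history, 98.5%
#' receiving opioids, 40.2% with inhalational anesthesia over one hour, and a
#' median age near 48, giving a median of 4 PONV risk factors and a median of
#' 2 antiemetic interventions.
#'
#' @param grid_rows,grid_cols grid dimensions (product must be at least 4).
#' @param cell_size side length of each square block group, planar units.
#' @param pop_low,pop_high per-CBG population bounds (uniform integer draw).
#' @param n_patients cohort size before exclusions.
#' @param prevalences named list of Bernoulli prevalences for the binary
#'   attributes: `female`, `ponv_history`, `nonsmoker`, `opioid_use`,
#'   `duration_gt_1h`, `high_risk_procedure`, `icu_transfer`, `tiva_propofol`.
#' @param race_probs,asa_probs,anesthesia_probs categorical distributions for
#'   race, ASA physical status 1..6, and anesthesia type.
#' @param age_mean,age_sd parameters of the (rounded, clamped to \[0, 100\])
#'   normal age model.
#' @param census_beta_params named list of `c(shape1, shape2)` Beta parameters
#'   for the five ND indicators and the profiling covariates.
#' @param spatial_trend_strength mixing weight in \[0, 1\] of the deterministic
#'   deprivation gradient toward the planted center.
#' @param planted_center `(row, col)` grid index of the planted region center.
#' @param planted_radius radius (planar units) of the planted circular region.
#' @param planted_undertreat_or odds divisor (>= 1) applied to the
#'   per-intervention success odds inside the planted region.
#' @param intervention_alpha,intervention_beta intercept and risk-score slope
#'   of the binomial-logistic intervention model
#'   `count ~ Binomial(6, plogis(alpha + beta * risk_score - log(OR) * inside))`.
#' @param geocode_fail_rate fraction of cases whose address cannot be geocoded
#'   to a street point (they carry no usable coordinates).
#' @param seed integer seed; the geography consumes `seed` and the cohort
#'   `seed + 1`, each through one Mersenne-Twister stream with draws in a
#'   fixed order, so outputs are bit-stable across runs.
#' @return a `raap_synth_config` list.
#' @export
synthetic_config <- function(grid_rows = 20L, grid_cols = 20L, cell_size = 1,
                             pop_low = 600L, pop_high = 3000L,
                             n_patients = 20000L,
                             prevalences = list(),
                             race_probs = c(White = 0.782, `non-White` = 0.218, unknown = 0),
                             asa_probs = c(0.1235, 0.4685, 0.3700, 0.0350, 0.0025, 0.0005),
                             anesthesia_probs = c(general = 0.944, regional = 0.050,
                                                  MAC = 0.005, sedation = 0.001),
                             age_mean = 48.7, age_sd = 17.55,
                             census_beta_params = list(),
                             spatial_trend_strength = 0.3,
                             planted_center = NULL,
                             planted_radius = 3.5,
                             planted_undertreat_or = 1.5,
                             intervention_alpha = -2.05,
                             intervention_beta = 0.45,
                             geocode_fail_rate = 0.069,
                             seed = 1L) {
  prev_default <- list(
    female = 0.560, ponv_history = 0.111, nonsmoker = 0.986,
    opioid_use = 0.985, duration_gt_1h = 0.402, high_risk_procedure = 0.23,
    icu_transfer = 0.005, tiva_propofol = 0.15
  )
  prev <- utils::modifyList(prev_default, as.list(prevalences))
  beta_default <- list(
    p_nhblack = c(2, 38), p_female_headed = c(2, 18), p_public_assist = c(2, 18),
    p_poverty = c(2.5, 17.5), p_unemployed = c(2, 38),
    p_nonwhite = c(3, 12), p_less_hs = c(2, 18), p_married = c(5, 5),
    p_age_over65 = c(3, 22), p_renter = c(3, 7), p_male = c(50, 50)
  )
  bp <- utils::modifyList(beta_default, as.list(census_beta_params))
  if (is.null(planted_center)) {
    planted_center <- c(ceiling(grid_rows / 2), ceiling(grid_cols / 2))
  }
  cfg <- list(
    grid_rows = as.integer(grid_rows), grid_cols = as.integer(grid_cols),
    cell_size = cell_size, pop_low = as.integer(pop_low),
    pop_high = as.integer(pop_high), n_patients = as.integer(n_patients),
    prevalences = prev, race_probs = race_probs, asa_probs = asa_probs,
    anesthesia_probs = anesthesia_probs, age_mean = age_mean, age_sd = age_sd,
    census_beta_params = bp, spatial_trend_strength = spatial_trend_strength,
    planted_center = as.integer(planted_center), planted_radius = planted_radius,
    planted_undertreat_or = planted_undertreat_or,
    intervention_alpha = intervention_alpha, intervention_beta = intervention_beta,
    geocode_fail_rate = geocode_fail_rate, seed = as.integer(seed)
  )
  validate_synth_config(cfg)
  class(cfg) <- "raap_synth_config"
  cfg
}

validate_synth_config <- function(cfg) {
  if (cfg$grid_rows < 1 || cfg$grid_cols < 1 || cfg$grid_rows * cfg$grid_cols < 4) {
    stop("invalid grid dimensions: grid_rows * grid_cols must be >= 4")
  }
  probs <- c(unlist(cfg$prevalences), cfg$geocode_fail_rate,
             cfg$spatial_trend_strength)
  if (any(probs < 0 | probs > 1)) stop("probabilities must lie in [0, 1]")
  if (cfg$planted_undertreat_or < 1) stop("planted_undertreat_or must be >= 1")
  if (cfg$n_patients < 0) stop("n_patients must be >= 0")
  if (cfg$pop_low < 0 || cfg$pop_high < cfg$pop_low) stop("invalid population bounds")
  invisible(cfg)
}

# Evaluate fn with a locally seeded Mersenne-Twister stream, restoring the
# caller's RNG state afterwards so generator calls never perturb user code.
with_local_seed <- function(seed, fn) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed, kind = "Mersenne-Twister", normal.kind = "Inversion")
  fn()
}

# Planar coordinates of the planted-region center.
planted_center_xy <- function(cfg) {
  c((cfg$planted_center[2] - 0.5) * cfg$cell_size,
    (cfg$planted_center[1] - 0.5) * cfg$cell_size)
}

#' CBG identifiers of the planted under-treatment region
#'
#' A block group is planted when its centroid lies within `planted_radius`
#' of the planted center.
#'
#' @param geography a `raap_geography` generated from `config`.
#' @param config the `raap_synth_config` used to generate it.
#' @return character vector of planted `cbg_id`s.
#' @export
planted_cbgs <- function(geography, config) {
  ctr <- planted_center_xy(config)
  d <- sqrt((geography$cx - ctr[1])^2 + (geography$cy - ctr[2])^2)
  geography$cbg_id[d <= config$planted_radius]
}

#' Generate a synthetic study-region geography
#'
#' Tiles the plane with `grid_rows * grid_cols` square block groups. Each
#' carries a uniform-integer population and Beta-distributed census
#' proportions blended with a deterministic gradient toward the planted
#' center: an indicator with trend weight `s` takes the value
#' `(1 - s) * Beta_draw + s * (1 - d)` where `d` is the centroid's distance to
#' the planted center, normalized by the maximum over the grid. The married
#' proportion trends away from the center (affluence gradient); the remaining
#' profiling covariates trend toward it at half strength. Deterministic under
#' a fixed seed.
#'
#' @param config a `raap_synth_config`.
#' @return a `raap_geography`.
#' @export
generate_geography <- function(config) {
  validate_synth_config(config)
  cfg <- config
  with_local_seed(cfg$seed, function() {
    nr <- cfg$grid_rows; nc <- cfg$grid_cols; cs <- cfg$cell_size
    n <- nr * nc
    row <- rep(seq_len(nr), each = nc)
    col <- rep(seq_len(nc), times = nr)
    polys <- lapply(seq_len(n), function(i) {
      x0 <- (col[i] - 1) * cs; x1 <- col[i] * cs
      y0 <- (row[i] - 1) * cs; y1 <- row[i] * cs
      rbind(c(x0, y0), c(x1, y0), c(x1, y1), c(x0, y1), c(x0, y0))
    })
    cx <- (col - 0.5) * cs
    cy <- (row - 0.5) * cs
    ctr <- planted_center_xy(cfg)
    d <- sqrt((cx - ctr[1])^2 + (cy - ctr[2])^2)
    d_norm <- if (max(d) > 0) d / max(d) else d
    population <- sample(cfg$pop_low:cfg$pop_high, n, replace = TRUE)

    s_full <- cfg$spatial_trend_strength
    trended <- function(name, s, toward_center = TRUE) {
      ab <- cfg$census_beta_params[[name]]
      u <- stats::rbeta(n, ab[1], ab[2])
      g <- if (toward_center) 1 - d_norm else d_norm
      (1 - s) * u + s * g
    }
    df <- data.frame(
      cbg_id = sprintf("CBG%04d", seq_len(n)),
      population = population,
      p_nhblack = trended("p_nhblack", s_full),
      p_female_headed = trended("p_female_headed", s_full),
      p_public_assist = trended("p_public_assist", s_full),
      p_poverty = trended("p_poverty", s_full),
      p_unemployed = trended("p_unemployed", s_full),
      p_nonwhite = trended("p_nonwhite", s_full / 2),
      p_less_hs = trended("p_less_hs", s_full / 2),
      p_married = trended("p_married", s_full / 2, toward_center = FALSE),
      p_age_over65 = trended("p_age_over65", 0),
      p_renter = trended("p_renter", s_full / 2),
      p_male = trended("p_male", 0),
      stringsAsFactors = FALSE
    )
    new_geography(df, polys)
  })
}

# Exact distribution of the PONV risk score implied by the configured
# prevalences (Poisson-binomial over the seven indicators), used for the
# truth object's expected under-treatment rates.
risk_score_distribution <- function(cfg) {
  p_age_lt50 <- stats::pnorm((49.5 - cfg$age_mean) / cfg$age_sd)
  p <- c(cfg$prevalences$female, cfg$prevalences$ponv_history,
         cfg$prevalences$nonsmoker, cfg$prevalences$opioid_use,
         cfg$prevalences$duration_gt_1h, p_age_lt50,
         cfg$prevalences$high_risk_procedure)
  dist <- 1
  for (pi in p) dist <- c(dist * (1 - pi), 0) + c(0, dist * pi)
  dist
}

# Expected rate of the lowest intervention level (count <= 1) under the
# binomial-logistic model, marginal over the risk-score distribution.
expected_low_intervention_rate <- function(cfg, inside) {
  sdist <- risk_score_distribution(cfg)
  scores <- seq_along(sdist) - 1
  eta <- cfg$intervention_alpha + cfg$intervention_beta * scores -
    log(cfg$planted_undertreat_or) * inside
  p <- stats::plogis(eta)
  sum(sdist * stats::pbinom(1, 6, p))
}

#' Generate a synthetic surgical cohort over a geography
#'
#' Assigns each case to a block group with probability proportional to
#' population and a uniform point within it; draws independent Bernoulli risk
#' factors at the configured prevalences; draws the total antiemetic
#' intervention count from `Binomial(6, plogis(alpha + beta * risk_score))`
#' with the success odds divided by `planted_undertreat_or` for cases living
#' in the planted region; and withholds coordinates from a `geocode_fail_rate`
#' fraction of cases (failed geocodes). Deterministic under a fixed seed.
#'
#' @param config a `raap_synth_config`.
#' @param geography the matching `raap_geography` (nonempty).
#' @return list with `cases` (patient data.frame) and `truth`
#'   (`raap_synth_truth`: planted CBG ids and expected lowest-level
#'   intervention rates inside/outside the planted region).
#' @export
generate_cohort <- function(config, geography) {
  validate_synth_config(config)
  if (!inherits(geography, "raap_geography") || nrow(geography) == 0) {
    stop("geography must be a nonempty raap_geography")
  }
  cfg <- config
  planted <- planted_cbgs(geography, cfg)
  truth <- structure(
    list(
      planted_cbg_ids = planted,
      planted_undertreat_or = cfg$planted_undertreat_or,
      expected_low_rate_inside = expected_low_intervention_rate(cfg, TRUE),
      expected_low_rate_outside = expected_low_intervention_rate(cfg, FALSE)
    ),
    class = "raap_synth_truth"
  )
  n <- cfg$n_patients
  if (n == 0) {
    cases <- empty_cohort()
    return(list(cases = cases, truth = truth))
  }
  cases <- with_local_seed(cfg$seed + 1L, function() {
    k <- nrow(geography)
    cbg_idx <- sample.int(k, n, replace = TRUE, prob = geography$population)
    bbox <- t(vapply(geography$polygon, function(r) {
      c(min(r[, 1]), max(r[, 1]), min(r[, 2]), max(r[, 2]))
    }, numeric(4)))
    x <- stats::runif(n, bbox[cbg_idx, 1], bbox[cbg_idx, 2])
    y <- stats::runif(n, bbox[cbg_idx, 3], bbox[cbg_idx, 4])
    pr <- cfg$prevalences
    sex <- ifelse(stats::rbinom(n, 1, pr$female) == 1, "female", "male")
    age <- pmin(pmax(round(stats::rnorm(n, cfg$age_mean, cfg$age_sd)), 0), 100)
    race <- sample(names(cfg$race_probs), n, replace = TRUE, prob = cfg$race_probs)
    asa <- sample.int(6, n, replace = TRUE, prob = cfg$asa_probs)
    anesthesia <- sample(names(cfg$anesthesia_probs), n, replace = TRUE,
                         prob = cfg$anesthesia_probs)
    icu <- stats::rbinom(n, 1, pr$icu_transfer) == 1
    nonsmoker <- stats::rbinom(n, 1, pr$nonsmoker) == 1
    ponv_hist <- stats::rbinom(n, 1, pr$ponv_history) == 1
    opioid <- stats::rbinom(n, 1, pr$opioid_use) == 1
    dur <- stats::rbinom(n, 1, pr$duration_gt_1h) == 1
    hrp <- stats::rbinom(n, 1, pr$high_risk_procedure) == 1

    score <- (sex == "female") + ponv_hist + nonsmoker + opioid + dur +
      (age < 50) + hrp
    inside <- geography$cbg_id[cbg_idx] %in% planted
    eta <- cfg$intervention_alpha + cfg$intervention_beta * score -
      log(cfg$planted_undertreat_or) * inside
    total <- stats::rbinom(n, 6, stats::plogis(eta))
    tiva <- total > 0 & stats::runif(n) < pr$tiva_propofol
    classes <- total - tiva

    fail <- stats::runif(n) < cfg$geocode_fail_rate
    x[fail] <- NA_real_
    y[fail] <- NA_real_

    data.frame(
      patient_id = sprintf("P%06d", seq_len(n)),
      x = x, y = y, geocode_failed = fail,
      age = age, sex = sex, race = race, asa = asa,
      anesthesia_type = anesthesia, icu_transfer = icu,
      duration_gt_1h = dur, nonsmoker = nonsmoker, ponv_history = ponv_hist,
      opioid_use = opioid, high_risk_procedure = hrp,
      n_antiemetic_classes = as.integer(classes),
      tiva_propofol = tiva,
      stringsAsFactors = FALSE
    )
  })
  list(cases = cases, truth = truth)
}

empty_cohort <- function() {
  data.frame(
    patient_id = character(), x = numeric(), y = numeric(),
    geocode_failed = logical(), age = numeric(), sex = character(),
    race = character(), asa = integer(), anesthesia_type = character(),
    icu_transfer = logical(), duration_gt_1h = logical(),
    nonsmoker = logical(), ponv_history = logical(), opioid_use = logical(),
    high_risk_procedure = logical(), n_antiemetic_classes = integer(),
    tiva_propofol = logical(), stringsAsFactors = FALSE
  )
}

#' @export
print.raap_synth_truth <- function(x, ...) {
  cat(sprintf("raap_synth_truth: %d planted CBGs, under-treatment OR %.2f\n",
              length(x$planted_cbg_ids), x$planted_undertreat_or))
  cat(sprintf("  expected lowest-level intervention rate: %.3f inside, %.3f outside\n",
              x$expected_low_rate_inside, x$expected_low_rate_outside))
  invisible(x)
}

#' Write cohort CSV and truth JSON
#'
#' @param cases patient data.frame as produced by [generate_cohort()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_cohort_csv <- function(cases, path) {
  utils::write.csv(cases, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_cohort_csv
#' @param truth a `raap_synth_truth`.
#' @export
write_truth_json <- function(truth, path) {
  txt <- jsonlite::toJSON(unclass(truth), auto_unbox = TRUE, digits = NA)
  writeLines(txt, path, useBytes = TRUE)
  invisible(path)
}

#' Read a cohort CSV written by [write_cohort_csv()]
#' @param path CSV path.
#' @return patient data.frame.
#' @export
read_cohort_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  for (nm in c("geocode_failed", "icu_transfer", "duration_gt_1h", "nonsmoker",
               "ponv_history", "opioid_use", "high_risk_procedure",
               "tiva_propofol")) {
    if (nm %in% names(df)) df[[nm]] <- as.logical(df[[nm]])
  }
  df
}
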