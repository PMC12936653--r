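## End-to-end orchestration: synthesize or ingest -> geocode -> inclusion ->
## RAAP labels -> spatial scan -> cluster profiling, with artifact export and
## a deterministic run manifest.

#' Load a pipeline configuration from YAML or a list
#'
#' Exactly one of `input` (paths to an existing `geography` GeoJSON and
#' `cohort` CSV) or `synth` (arguments for [synthetic_config()]) must be
#' supplied. Scan parameters and the seed have package defaults; every
#' paper-gap default (999 replicates, 50% window cap, alpha 0.05, lower
#' median RAAP reference) is overridable here.
#'
#' @param config path to a YAML file, or an equivalent named list.
#' @return a validated `raap_pipeline_config` list.
#' @export
pipeline_config <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  stopifnot(is.list(config))
  has_input <- !is.null(config$input)
  has_synth <- !is.null(config$synth)
  if (has_input == has_synth) {
    stop("exactly one of 'input' or 'synth' must be supplied")
  }
  if (is.null(config$seed)) stop("a seed is mandatory")
  cfg <- list(
    input = config$input,
    synth = config$synth,
    scan = utils::modifyList(
      list(max_fraction = 0.5, reps = 999L, alpha = 0.05, case_level = "below"),
      as.list(config$scan)),
    seed = as.integer(config$seed),
    out_dir = if (is.null(config$out_dir)) NULL else config$out_dir,
    moran_permutations = if (is.null(config$moran_permutations)) 999L
                         else as.integer(config$moran_permutations),
    verbose = isTRUE(config$verbose)
  )
  class(cfg) <- "raap_pipeline_config"
  cfg
}

pipeline_log <- function(cfg, fmt, ...) {
  if (isTRUE(cfg$verbose)) message(sprintf(paste0("[raapscan] ", fmt), ...))
}

#' Run the full disparity-analysis pipeline
#'
#' Stages, in order: obtain geography and cohort (synthetic or from files);
#' geocode cases to block groups; apply inclusion rules; compute risk
#' scores, intervention counts and RAAP labels; assign patient-level ND
#' quartiles; scan for clusters of low-RAAP cases; profile the result
#' (RAAP-by-quartile and RAAP-by-race crosstabs with pairwise race
#' chi-squares, uni/multivariate logistic regression of cluster membership
#' on CBG covariates, Moran's I on the multivariate deviance residuals).
#' Any stage failure aborts with a stage-tagged error. When `out_dir` is
#' set, all artifacts (GeoJSON, CSV, JSON) and a deterministic manifest are
#' written there; the manifest carries no wall-clock timestamp so identical
#' configs yield byte-identical manifests.
#'
#' @param config a `raap_pipeline_config`, a list coercible to one, or a
#'   YAML path.
#' @return list with `manifest`, `geography`, `cases` (labeled, included),
#'   `scan` (`raap_scan_result`), `truth` (synthetic runs only), `profile`
#'   (crosstabs, chi-squares, regressions, Moran result).
#' @export
run_pipeline <- function(config) {
  cfg <- if (inherits(config, "raap_pipeline_config")) config else pipeline_config(config)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("[stage %s] %s", name, conditionMessage(e)), call. = FALSE)
    })
  }

  truth <- NULL
  if (!is.null(cfg$synth)) {
    synth_args <- cfg$synth
    if (is.null(synth_args$seed)) synth_args$seed <- cfg$seed
    scfg <- stage("synth", do.call(synthetic_config, synth_args))
    geography <- stage("synth", generate_geography(scfg))
    gen <- stage("synth", generate_cohort(scfg, geography))
    cohort <- gen$cases
    truth <- gen$truth
    pipeline_log(cfg, "synthesized %d CBGs, %d cases", nrow(geography), nrow(cohort))
  } else {
    geography <- stage("ingest", read_geography_geojson(cfg$input$geography))
    cohort <- stage("ingest", read_cohort_csv(cfg$input$cohort))
    pipeline_log(cfg, "ingested %d CBGs, %d cases", nrow(geography), nrow(cohort))
  }

  cohort <- stage("geo", geocode_cases(cohort, geography))
  incl <- stage("cohort", apply_inclusion(cohort))
  if (nrow(incl$cases) == 0) {
    stop("[stage cohort] every case failed inclusion; nothing to analyze", call. = FALSE)
  }
  labeled <- stage("cohort", label_raap(incl$cases))
  labeled$nd_quartile <- stage("geo", assign_quartiles(
    labeled$nd, labeled$cbg_id, labeled$patient_id))

  sinput <- stage("scan", make_scan_input(labeled, geography,
                                          case_level = cfg$scan$case_level))
  scan_res <- stage("scan", detect_clusters(
    sinput, max_fraction = cfg$scan$max_fraction, R = cfg$scan$reps,
    alpha = cfg$scan$alpha, seed = cfg$seed))
  pipeline_log(cfg, "scan: %d cluster(s), max LLR %.3f, p %.4g",
               length(scan_res$clusters), scan_res$max_llr, scan_res$p_value)

  prof <- stage("profile", profile_clusters(
    labeled, geography, scan_res,
    moran_permutations = cfg$moran_permutations, seed = cfg$seed))

  cfg_echo <- unclass(cfg)
  cfg_echo$out_dir <- NULL  # analysis identity excludes where artifacts land
  cfg_echo$verbose <- NULL
  manifest <- list(
    config = cfg_echo,
    package_version = as.character(utils::packageVersion("raapscan")),
    stages = list(
      input_cases = nrow(cohort),
      exclusions = as.list(incl$tally[c("age", "asa", "icu",
                                        "anesthesia_type", "geography")]),
      retained = nrow(labeled),
      raap = as.list(table(labeled$raap)),
      n_cbgs = nrow(geography),
      scan_cases = scan_res$C,
      clusters_reported = length(scan_res$clusters),
      clusters_significant = sum(vapply(scan_res$clusters,
                                        function(cl) cl$significant, logical(1)))
    )
  )

  if (!is.null(cfg$out_dir)) {
    dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
    p <- function(f) file.path(cfg$out_dir, f)
    write_geography_geojson(geography, p("geography.geojson"))
    write_cohort_csv(labeled, p("cohort_labeled.csv"))
    writeLines(jsonlite::toJSON(as.list(incl$tally), auto_unbox = TRUE),
               p("exclusions.json"), useBytes = TRUE)
    write_clusters_json(scan_res, p("clusters.json"))
    export_cluster_geojson(geography, scan_res, labeled,
                           path = p("clusters.geojson"))
    utils::write.csv(crosstab_to_df(prof$crosstab_quartile),
                     p("crosstab_quartile.csv"), row.names = FALSE)
    utils::write.csv(crosstab_to_df(prof$crosstab_race),
                     p("crosstab_race.csv"), row.names = FALSE)
    utils::write.csv(prof$race_chi2, p("race_chi2.csv"), row.names = FALSE)
    write_regression_json(prof, p("regression.json"))
    writeLines(jsonlite::toJSON(unclass(prof$moran), auto_unbox = TRUE,
                                digits = NA),
               p("moran.json"), useBytes = TRUE)
    writeLines(jsonlite::toJSON(manifest, auto_unbox = TRUE, digits = NA,
                                pretty = TRUE),
               p("manifest.json"), useBytes = TRUE)
    if (!is.null(truth)) write_truth_json(truth, p("truth.json"))
    pipeline_log(cfg, "artifacts written to %s", cfg$out_dir)
  }

  list(manifest = manifest, geography = geography, cases = labeled,
       scan = scan_res, truth = truth, profile = prof)
}

#' Profile detected clusters
#'
#' RAAP crosstabs by ND quartile and race (with pairwise race chi-squares),
#' univariate and multivariate logistic regressions of CBG cluster
#' membership on the neighborhood covariates (% non-White, % less than high
#' school, % below poverty, % married, % over 65, % renters, % male), and
#' Moran's I on the multivariate fit's deviance residuals under
#' row-standardized queen weights.
#'
#' @param labeled included, labeled cases (with `nd_quartile`).
#' @param geography a `raap_geography` with the covariate proportions.
#' @param scan_res a `raap_scan_result`.
#' @param moran_permutations permutation count for Moran's I.
#' @param seed integer seed for the permutation test.
#' @return list with `crosstab_quartile`, `crosstab_race`, `race_chi2`,
#'   `logit_multi`, `logit_uni`, `moran`.
#' @export
profile_clusters <- function(labeled, geography, scan_res,
                             moran_permutations = 999, seed = 1) {
  ct_q <- crosstab_raap(labeled, "nd_quartile")
  ct_r <- crosstab_raap(labeled, "race")
  race_chi2 <- pairwise_race_chi2(labeled)

  in_cluster <- cluster_membership(geography, scan_res)
  wanted <- c("p_nonwhite", "p_less_hs", "p_poverty", "p_married",
              "p_age_over65", "p_renter", "p_male")
  have <- intersect(wanted, names(geography))
  if (!length(have)) stop("geography carries none of the profiling covariates")
  if (length(have) < length(wanted)) {
    message("profiling covariates absent from geography and skipped: ",
            paste(setdiff(wanted, have), collapse = ", "))
  }
  covars <- as.data.frame(unclass(geography)[have], stringsAsFactors = FALSE)
  logit_multi <- fit_cluster_logistic(covars, in_cluster)
  logit_uni <- fit_cluster_logistic(covars, in_cluster, univariate = TRUE)

  moran <- NULL
  if (logit_multi$converged) {
    resid_dev <- stats::residuals(logit_multi$fit, type = "deviance")
    W <- queen_weights(geography)
    moran <- morans_i(resid_dev, W, permutations = moran_permutations,
                      seed = seed)
  }
  list(crosstab_quartile = ct_q, crosstab_race = ct_r, race_chi2 = race_chi2,
       logit_multi = logit_multi, logit_uni = logit_uni, moran = moran)
}

# 0/1 membership of each geography CBG in any significant cluster (or the
# most likely cluster when none is significant, matching the scan's
# always-report-primary convention is NOT applied here: membership means a
# significant cluster).
cluster_membership <- function(geography, scan_res) {
  member <- rep(0L, nrow(geography))
  for (cl in scan_res$clusters) {
    if (cl$significant) {
      member[geography$cbg_id %in% cl$cbg_ids] <- 1L
    }
  }
  member
}

#' Export per-CBG cluster results as GeoJSON
#'
#' One feature per block group with properties `cbg_id`, `population`, `nd`,
#' `c` (low-RAAP cases), `n` (at-risk), `rr` (the CBG's own relative risk
#' within the global totals), `in_cluster`, and `cluster_p` (the p-value of
#' its reported cluster, `NA` otherwise).
#'
#' @param geography a `raap_geography`.
#' @param scan_res a `raap_scan_result`.
#' @param labeled labeled cases used to rebuild the per-CBG counts.
#' @param path output GeoJSON path.
#' @return `path`, invisibly.
#' @export
export_cluster_geojson <- function(geography, scan_res, labeled, path) {
  for (cl in scan_res$clusters) {
    if (!all(cl$cbg_ids %in% geography$cbg_id)) {
      stop("cluster references cbg_id absent from geography")
    }
  }
  si <- make_scan_input(labeled, geography)
  C <- sum(si$c); N <- sum(si$n)
  E_i <- C * si$n / N
  rr <- rep(NA_real_, nrow(si))
  ok <- E_i > 0 & E_i < C
  rr[ok] <- ifelse(si$c[ok] == C, Inf,
                   (si$c[ok] / E_i[ok]) / ((C - si$c[ok]) / (C - E_i[ok])))
  in_cluster <- rep(FALSE, nrow(geography))
  cluster_p <- rep(NA_real_, nrow(geography))
  for (cl in scan_res$clusters) {
    if (!cl$significant) next
    hit <- geography$cbg_id %in% cl$cbg_ids
    in_cluster[hit] <- TRUE
    cluster_p[hit] <- cl$p_value
  }
  feats <- lapply(seq_len(nrow(geography)), function(i) {
    ring <- geography$polygon[[i]]
    list(
      type = "Feature",
      properties = list(
        cbg_id = geography$cbg_id[i],
        population = geography$population[i],
        nd = geography$nd[i],
        c = si$c[i], n = si$n[i], rr = rr[i],
        in_cluster = in_cluster[i],
        cluster_p = cluster_p[i]
      ),
      geometry = list(
        type = "Polygon",
        coordinates = list(lapply(seq_len(nrow(ring)), function(k) ring[k, ]))
      )
    )
  })
  fc <- list(type = "FeatureCollection", features = feats)
  writeLines(jsonlite::toJSON(fc, auto_unbox = TRUE, digits = NA, na = "null"),
             path, useBytes = TRUE)
  invisible(path)
}

write_clusters_json <- function(scan_res, path) {
  clusters <- lapply(scan_res$clusters, function(cl) {
    cl$cbg_rr <- as.list(cl$cbg_rr)
    cl
  })
  out <- list(C = scan_res$C, N = scan_res$N, max_llr = scan_res$max_llr,
              p_value = scan_res$p_value, alpha = scan_res$alpha,
              R = scan_res$R, clusters = clusters)
  writeLines(jsonlite::toJSON(out, auto_unbox = TRUE, digits = NA),
             path, useBytes = TRUE)
  invisible(path)
}

write_regression_json <- function(prof, path) {
  fit_to_list <- function(f) {
    list(converged = f$converged, deviance = f$deviance,
         coefficients = f$coefficients)
  }
  out <- list(multivariate = fit_to_list(prof$logit_multi),
              univariate = lapply(prof$logit_uni, fit_to_list))
  writeLines(jsonlite::toJSON(out, auto_unbox = TRUE, digits = NA),
             path, useBytes = TRUE)
  invisible(path)
}

crosstab_to_df <- function(ct) {
  data.frame(
    group = rownames(ct$counts),
    above_n = ct$counts[, "above"], above_pct = ct$row_pct[, "above"],
    median_n = ct$counts[, "median"], median_pct = ct$row_pct[, "median"],
    below_n = ct$counts[, "below"], below_pct = ct$row_pct[, "below"],
    total = ct$row_totals,
    row.names = NULL, stringsAsFactors = FALSE
  )
}
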