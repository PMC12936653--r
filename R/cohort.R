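## Cohort construction: inclusion/exclusion, PONV risk scoring, antiemetic
## intervention counting, and the 3-level risk-adjusted antiemetic
## prophylaxis (RAAP) label.

# The shared 6-level ordinal scale for risk scores and intervention counts.
.raap_levels <- c("0-1", "2", "3", "4", "5", "6+")

#' Map integer counts onto the 6-level ordinal scale
#'
#' Both the PONV risk score and the intervention count are categorized on the
#' same scale: 0 and 1 collapse to `"0-1"`, 6 and above to `"6+"`.
#'
#' @param x nonnegative integer vector.
#' @return ordered factor with levels `0-1 < 2 < 3 < 4 < 5 < 6+`.
#' @export
ordinal_level <- function(x) {
  if (anyNA(x) || any(x < 0)) stop("counts must be nonnegative and non-missing")
  idx <- pmax(pmin(floor(x), 6), 1)  # 0 -> "0-1", >=6 -> "6+"
  factor(.raap_levels[idx], levels = .raap_levels, ordered = TRUE)
}

#' Apply cohort inclusion and exclusion rules
#'
#' Drops cases with age < 18, ASA physical status 5 or 6, ICU transfer,
#' anesthesia without general or regional technique (MAC and deep sedation),
#' and cases without a usable in-region location (failed geocode or point
#' outside every study-region polygon). Each dropped case is tallied under
#' one primary reason, in the fixed precedence order
#' age > ASA > ICU > anesthesia type > geography.
#'
#' @param cases patient data.frame; geography screening uses the `cbg_id`
#'   column when present (see [geocode_cases()]), and is skipped with a
#'   message when absent.
#' @return list with `cases` (retained rows) and `tally` (named integer
#'   vector: input, excluded counts per reason, retained).
#' @export
apply_inclusion <- function(cases) {
  n <- nrow(cases)
  reason <- rep(NA_character_, n)
  mark <- function(reason_vec, cond, label) {
    ifelse(is.na(reason_vec) & cond, label, reason_vec)
  }
  if (n > 0) {
    reason <- mark(reason, cases$age < 18, "age")
    reason <- mark(reason, cases$asa %in% c(5L, 6L), "asa")
    reason <- mark(reason, cases$icu_transfer, "icu")
    reason <- mark(reason, !cases$anesthesia_type %in% c("general", "regional"),
                   "anesthesia_type")
    if ("cbg_id" %in% names(cases)) {
      reason <- mark(reason, is.na(cases$cbg_id), "geography")
    } else {
      message("apply_inclusion: no cbg_id column; geography screening skipped")
    }
  }
  keep <- is.na(reason)
  tally <- c(
    input = n,
    age = sum(reason == "age", na.rm = TRUE),
    asa = sum(reason == "asa", na.rm = TRUE),
    icu = sum(reason == "icu", na.rm = TRUE),
    anesthesia_type = sum(reason == "anesthesia_type", na.rm = TRUE),
    geography = sum(reason == "geography", na.rm = TRUE),
    retained = sum(keep)
  )
  list(cases = cases[keep, , drop = FALSE], tally = tally)
}

#' PONV risk score and ordinal risk level
#'
#' Counts the seven guideline risk factors for postoperative nausea and
#' vomiting: female sex, history of PONV or motion sickness, nonsmoking,
#' opioid use, inhalational anesthesia longer than one hour, age under 50,
#' and a high-PONV-risk procedure. Missing indicator values are an error —
#' no imputation is performed.
#'
#' @param cases patient data.frame with columns `sex`, `ponv_history`,
#'   `nonsmoker`, `opioid_use`, `duration_gt_1h`, `age`,
#'   `high_risk_procedure`.
#' @return data.frame with `risk_score` (integer 0..7) and `risk_level`
#'   (ordered factor on the 6-level scale).
#' @export
risk_score <- function(cases) {
  ind <- cbind(
    cases$sex == "female",
    cases$ponv_history,
    cases$nonsmoker,
    cases$opioid_use,
    cases$duration_gt_1h,
    cases$age < 50,
    cases$high_risk_procedure
  )
  if (anyNA(ind)) stop("missing PONV risk indicator; records with missing data must be excluded, not imputed")
  score <- as.integer(rowSums(ind))
  data.frame(risk_score = score, risk_level = ordinal_level(score))
}

#' Antiemetic intervention count and ordinal level
#'
#' One point per distinct prophylactic antiemetic class administered, plus
#' one for propofol-based total intravenous anesthesia, categorized on the
#' same 6-level ordinal scale as the risk score.
#'
#' @param cases patient data.frame with `n_antiemetic_classes` and
#'   `tiva_propofol` columns.
#' @return data.frame with `intervention_count` and `intervention_level`.
#' @export
intervention_count <- function(cases) {
  cls <- cases$n_antiemetic_classes
  if (anyNA(cls) || any(cls < 0)) stop("n_antiemetic_classes must be nonnegative and non-missing")
  if (anyNA(cases$tiva_propofol)) stop("tiva_propofol must be non-missing")
  cnt <- as.integer(cls + cases$tiva_propofol)
  data.frame(intervention_count = cnt, intervention_level = ordinal_level(cnt))
}

#' Assign the 3-level risk-adjusted antiemetic prophylaxis label
#'
#' Within each PONV-risk stratum, the reference is the lower median of the
#' intervention levels — the `ceiling(n/2)`-th order statistic on the 6-level
#' ordinal scale — which is always an attained level, so every non-empty
#' stratum contains at least one `median`-labeled case. Each case is labeled
#' `below`, `median`, or `above` by strict comparison of its intervention
#' level to the stratum reference.
#'
#' @param records data.frame with `risk_level` and `intervention_level`
#'   columns (ordered factors from [risk_score()] and
#'   [intervention_count()]).
#' @return `records` with `stratum_median` (attained level, ordered factor)
#'   and `raap` (factor `below`/`median`/`above`) appended.
#' @export
assign_raap <- function(records) {
  stopifnot(all(c("risk_level", "intervention_level") %in% names(records)))
  iv <- as.integer(records$intervention_level)
  med_idx <- rep(NA_integer_, nrow(records))
  for (lev in levels(records$risk_level)) {
    in_stratum <- records$risk_level == lev
    n <- sum(in_stratum)
    if (n == 0) next
    m <- sort(iv[in_stratum])[ceiling(n / 2)]
    med_idx[in_stratum] <- m
  }
  records$stratum_median <- factor(.raap_levels[med_idx], levels = .raap_levels,
                                   ordered = TRUE)
  records$raap <- factor(
    ifelse(iv < med_idx, "below", ifelse(iv > med_idx, "above", "median")),
    levels = c("below", "median", "above")
  )
  records
}

#' Label a cohort end to end
#'
#' Convenience wrapper: risk score, intervention count, and RAAP label in one
#' call on an included cohort.
#'
#' @param cases included patient data.frame.
#' @return `cases` with `risk_score`, `risk_level`, `intervention_count`,
#'   `intervention_level`, `stratum_median`, `raap` columns appended.
#' @export
label_raap <- function(cases) {
  cases <- cbind(cases, risk_score(cases), intervention_count(cases))
  assign_raap(cases)
}
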