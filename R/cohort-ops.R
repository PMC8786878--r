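#' Cohort screening configuration
#'
#' @param window_hours observation window after ICU admission (default 48).
#' @param min_age minimum age in years (default 18).
#' @param min_los_hours minimum length of stay; stays must exceed this
#'   strictly ("more than 48 hours"), so a stay at exactly 48.0 h is
#'   excluded (default 48).
#' @return object of class `cohort_config`.
#' @export
cohort_config <- function(window_hours = 48L, min_age = 18, min_los_hours = 48) {
  if (window_hours <= 0 || min_age <= 0 || min_los_hours <= 0)
    config_error("cohort_config fields must all be positive")
  structure(list(window_hours = as.integer(window_hours), min_age = min_age,
                 min_los_hours = min_los_hours),
            class = "cohort_config")
}

#' Apply benchmark cohort exclusion rules
#'
#' Keeps stays that (1) are adults (`age >= min_age`), (2) are the only ICU
#' stay of their hospital admission, (3) have a known length of stay strictly
#' greater than `min_los_hours`, and (4) carry at least one observation
#' inside the analysis window. Every excluded stay is attributed to the first
#' rule it violates, in the fixed order age, multi-stay, length of stay,
#' observations; rule predicates are evaluated on the input cohort so the two
#' stays of a shared admission are both counted under the multi-stay rule.
#'
#' @param cohort an `icu_cohort`.
#' @param config a [cohort_config()].
#' @return the filtered cohort, with an `exclusions` attribute: named integer
#'   vector of per-rule exclusion counts (`age`, `multi_stay`, `los`,
#'   `no_observations`) plus `kept`.
#' @export
apply_exclusions <- function(cohort, config = cohort_config()) {
  st <- cohort$stays
  if (nrow(st) == 0L) {
    out <- cohort
    attr(out, "exclusions") <- c(age = 0L, multi_stay = 0L, los = 0L,
                                 no_observations = 0L, kept = 0L)
    return(out)
  }
  adm_multi <- table(st$admission_id)
  has_obs_ids <- unique(cohort$observations$stay_id[
    cohort$observations$hour >= 0 & cohort$observations$hour < config$window_hours])

  v_age  <- st$age < config$min_age
  v_mult <- as.vector(adm_multi[st$admission_id]) > 1L
  v_los  <- st$los_hours <= config$min_los_hours
  v_obs  <- !(st$stay_id %in% has_obs_ids)

  first_rule <- ifelse(v_age, 1L,
                ifelse(v_mult, 2L,
                ifelse(v_los, 3L,
                ifelse(v_obs, 4L, 0L))))
  counts <- vapply(1:4, function(k) sum(first_rule == k), integer(1))
  keep <- st$stay_id[first_rule == 0L]
  out <- subset_cohort(cohort, keep)
  attr(out, "exclusions") <- c(age = counts[1], multi_stay = counts[2],
                               los = counts[3], no_observations = counts[4],
                               kept = length(keep))
  out
}

.check_levels <- function(stays) {
  for (a in .fairicu_attributes) {
    bad <- setdiff(unique(stays[[a]]), .fairicu_levels[[a]])
    if (length(bad))
      schema_error(sprintf("unknown %s level(s): %s", a,
                           paste(bad, collapse = ", ")))
  }
  invisible(NULL)
}

#' Demographics and outcome table
#'
#' One row per demographic level (gender, age band, ethnicity, insurance):
#' distinct patient count and share, stay count and share, and the
#' in-hospital mortality rate (percent of stays) within the level, plus a
#' totals row. Patients are deduplicated by `patient_id` within each level,
#' so a patient whose insurance differs across stays is counted under each
#' level they appear in.
#'
#' @param cohort a non-empty `icu_cohort`.
#' @return data frame with columns `attribute`, `level`, `patients`,
#'   `patients_pct`, `stays`, `stays_pct`, `event_rate_pct`.
#' @export
demographics_table <- function(cohort) {
  st <- cohort$stays
  if (nrow(st) == 0L) schema_error("demographics_table requires a non-empty cohort")
  .check_levels(st)
  st$age_band <- as.character(age_band(st$age))
  n_stays <- nrow(st)
  n_pat <- length(unique(st$patient_id))
  rows <- lapply(c("gender", "age_band", "ethnicity", "insurance"), function(a) {
    lv <- .fairicu_levels[[a]]
    do.call(rbind, lapply(lv, function(l) {
      sel <- st[[a]] == l
      data.frame(
        attribute = a, level = l,
        patients = length(unique(st$patient_id[sel])),
        stays = sum(sel),
        event_rate_pct = if (any(sel)) 100 * mean(st$label[sel]) else NA_real_,
        stringsAsFactors = FALSE
      )
    }))
  })
  out <- do.call(rbind, rows)
  out <- rbind(out, data.frame(
    attribute = "total", level = "Total", patients = n_pat, stays = n_stays,
    event_rate_pct = 100 * mean(st$label), stringsAsFactors = FALSE))
  out$patients_pct <- 100 * out$patients / n_pat
  out$stays_pct <- 100 * out$stays / n_stays
  out[, c("attribute", "level", "patients", "patients_pct", "stays",
          "stays_pct", "event_rate_pct")]
}

#' Per-variable missingness profile
#'
#' For every variable of the physiological catalog: the percentage of stays
#' with no observations at all inside the window (`pct_none`), the percentage
#' with at least one observation in every hour bucket (`pct_full`), and the
#' mean number of hour buckets covered (`avg_points`, with its percentage of
#' the window maximum). A stay contributes one countable point per hour
#' bucket containing at least one observation of the variable.
#'
#' @param cohort a non-empty `icu_cohort`.
#' @param config a [cohort_config()] (window length).
#' @return data frame with columns `variable_id`, `pct_none`, `pct_full`,
#'   `avg_points`, `avg_points_pct`.
#' @export
missingness_profile <- function(cohort, config = cohort_config()) {
  st <- cohort$stays
  if (nrow(st) == 0L) schema_error("missingness_profile requires a non-empty cohort")
  n <- nrow(st)
  w <- config$window_hours
  obs <- data.table::as.data.table(cohort$observations)
  obs <- obs[obs$hour >= 0 & obs$hour < w & obs$stay_id %in% st$stay_id]
  if (nrow(obs)) {
    pts <- obs[, list(points = data.table::uniqueN(hour)),
               by = c("stay_id", "variable_id")]
  } else {
    pts <- data.table::data.table(stay_id = character(),
                                  variable_id = character(),
                                  points = integer())
  }
  out <- do.call(rbind, lapply(.fairicu_variables, function(v) {
    pv <- pts[pts$variable_id == v]
    covered <- nrow(pv)
    data.frame(
      variable_id = v,
      pct_none = 100 * (n - covered) / n,
      pct_full = 100 * sum(pv$points == w) / n,
      avg_points = sum(pv$points) / n,
      stringsAsFactors = FALSE
    )
  }))
  out$avg_points_pct <- 100 * out$avg_points / w
  out
}
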