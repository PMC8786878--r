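# Printed cohort characteristics the default configurations emulate: patient
# shares (as proportions) and per-level in-hospital mortality rates for two
# real critical-care cohorts, plus per-variable data-coverage statistics
# (percentage of stays with no data at all, and mean covered hours out of 48)
# for the 17-variable physiological catalog.

.mimic_table1 <- list(
  overall_rate = 0.1323,
  shares = list(
    gender    = c(Female = 0.447, Male = 0.553),
    ethnicity = c(Asian = 0.024, Black = 0.082, Hispanic = 0.031,
                  White = 0.710, Other = 0.152),
    insurance = c(Medicare = 0.571, Medicaid = 0.082, Private = 0.310,
                  Other = 0.037),
    age_band  = c(`18-29` = 0.043, `30-49` = 0.148, `50-69` = 0.367,
                  `70-89` = 0.389, `90+` = 0.053)
  ),
  rates = list(
    gender    = c(Female = 0.135, Male = 0.130),
    ethnicity = c(Asian = 0.138, Black = 0.092, Hispanic = 0.081,
                  White = 0.129, Other = 0.187),
    insurance = c(Medicare = 0.153, Medicaid = 0.103, Private = 0.102,
                  Other = 0.116),
    age_band  = c(`18-29` = 0.056, `30-49` = 0.093, `50-69` = 0.111,
                  `70-89` = 0.165, `90+` = 0.218)
  )
)

.starr_table1 <- list(
  overall_rate = 0.1018,
  shares = list(
    gender    = c(Female = 0.410, Male = 0.590),
    ethnicity = c(Asian = 0.138, Black = 0.054, Hispanic = 0.156,
                  White = 0.527, Other = 0.125),
    insurance = c(Medicare = 0.518, Medicaid = 0.156, Private = 0.282,
                  Other = 0.044),
    age_band  = c(`18-29` = 0.045, `30-49` = 0.145, `50-69` = 0.439,
                  `70-89` = 0.342, `90+` = 0.029)
  ),
  rates = list(
    gender    = c(Female = 0.116, Male = 0.092),
    ethnicity = c(Asian = 0.119, Black = 0.093, Hispanic = 0.114,
                  White = 0.087, Other = 0.135),
    insurance = c(Medicare = 0.105, Medicaid = 0.103, Private = 0.091,
                  Other = 0.121),
    age_band  = c(`18-29` = 0.072, `30-49` = 0.088, `50-69` = 0.091,
                  `70-89` = 0.117, `90+` = 0.208)
  )
)

# pct_none: % of stays with zero observations; avg_hours: mean covered hour
# buckets out of 48 (over all stays). mean/sd give plausible measurement
# scales; values are carried for missingness accounting only.
.variable_coverage <- function(which = c("mimic", "starr")) {
  which <- match.arg(which)
  base <- data.frame(
    variable_id = .fairicu_variables,
    mean = c(2, 60, 0.5, 3.5, 5.2, 12, 3.8, 140, 85, 170, 80, 96, 18, 120,
             37, 80, 7.4),
    sd   = c(0.5, 12, 0.15, 1, 1.2, 3, 1.3, 45, 15, 10, 14, 3, 5, 20, 0.7,
             22, 0.07),
    stringsAsFactors = FALSE
  )
  if (which == "mimic") {
    base$pct_none <- c(98.1, 1.2, 70.5, 0.9, 0.9, 41.8, 1.0, 0.1, 1.2, 81.0,
                       1.2, 0.7, 1.3, 1.2, 2.0, 27.0, 17.3)
    base$avg_hours <- c(0.2, 43.4, 3.0, 14.8, 14.8, 8.8, 14.8, 12.5, 44.4,
                        0.2, 43.2, 42.8, 43.7, 43.4, 15.7, 1.5, 6.3)
  } else {
    base$pct_none <- c(100, 1.0, 43.5, 14.3, 14.2, 14.0, 14.7, 9.8, 1.8, 9.7,
                       1.0, 1.7, 13.7, 1.0, 3.8, 4.8, 22.2)
    base$avg_hours <- c(0.0, 20.2, 3.5, 6.7, 7.2, 9.8, 5.6, 15.2, 45.8, 42.9,
                        20.2, 45.5, 38.1, 20.2, 20.0, 45.3, 7.8)
  }
  base
}

#' Missingness profile for the synthetic generator
#'
#' Builds the per-variable missingness parameterization from a published-style
#' coverage table: the probability that a stay has no observations of the
#' variable at all (`p_none`) and, conditional on the variable being present,
#' the per-hour observation probability (`p_hour`) chosen so the expected mean
#' number of covered hour buckets matches `avg_hours`.
#'
#' @param coverage data frame with columns `variable_id`, `pct_none` (percent),
#'   `avg_hours` (mean covered hours out of `window`), `mean`, `sd`.
#' @param window observation window length in hours (default 48).
#' @return data frame with columns `variable_id`, `p_none`, `p_hour`,
#'   `mean`, `sd`.
#' @export
missingness_profile_from_coverage <- function(coverage, window = 48L) {
  p_none <- coverage$pct_none / 100
  p_hour <- ifelse(p_none >= 1, 0,
                   pmin(1, (coverage$avg_hours / window) / (1 - p_none)))
  data.frame(variable_id = coverage$variable_id, p_none = p_none,
             p_hour = p_hour, mean = coverage$mean, sd = coverage$sd,
             stringsAsFactors = FALSE)
}

#' A missingness profile with no observations at all
#'
#' Useful for fast simulations where physiological observations are not part
#' of the question under study (every variable completely absent).
#'
#' @return data frame in the format of [missingness_profile_from_coverage()].
#' @export
no_observation_profile <- function() {
  cov <- .variable_coverage("mimic")
  cov$pct_none <- 100
  cov$avg_hours <- 0
  missingness_profile_from_coverage(cov)
}

zero_offsets <- function() {
  lapply(.fairicu_levels, function(lv) setNames(rep(0, length(lv)), lv))
}

# Offsets per level as log-odds deviations from the overall rate.
.offsets_from_rates <- function(rates, overall) {
  lapply(rates, function(r) qlogis(r) - qlogis(overall))
}

#' Default synthetic Charlson comorbidity model
#'
#' Twelve synthetic comorbidity factors (`F01`..`F12`) with integer weights
#' 1,1,1,1,1,1,2,2,2,3,6,6, two diagnosis codes each (suffix `a`/`b`),
#' marginal prevalences, and a common log-odds association with the latent
#' acuity so comorbidity burden correlates with outcome risk. The code table
#' is synthetic; real ICD mappings are user-supplied.
#'
#' @param assoc log-odds increase in factor prevalence per unit of latent
#'   acuity (default 0.35).
#' @return list with `factors` (data frame: `factor_id`, `weight`,
#'   `prevalence`, `assoc`) and `mapping` (data frame: `code`, `factor_id`,
#'   `weight`).
#' @export
default_charlson_model <- function(assoc = 0.35) {
  factors <- data.frame(
    factor_id  = sprintf("F%02d", 1:12),
    weight     = c(1, 1, 1, 1, 1, 1, 2, 2, 2, 3, 6, 6),
    prevalence = c(0.22, 0.18, 0.15, 0.12, 0.10, 0.08, 0.07, 0.05, 0.04,
                   0.03, 0.02, 0.015),
    assoc      = assoc,
    stringsAsFactors = FALSE
  )
  mapping <- data.frame(
    code      = paste0(rep(factors$factor_id, each = 2), c("a", "b")),
    factor_id = rep(factors$factor_id, each = 2),
    weight    = rep(factors$weight, each = 2),
    stringsAsFactors = FALSE
  )
  list(factors = factors, mapping = mapping)
}

.check_marginal <- function(p, name) {
  if (anyNA(p) || any(p < 0) || any(p > 1))
    config_error(sprintf("marginal for '%s' has probabilities outside [0,1]", name))
  if (abs(sum(p) - 1) > 1e-9)
    config_error(sprintf("marginal for '%s' does not sum to 1 (got %.12f)", name, sum(p)))
  want <- .fairicu_levels[[name]]
  if (!identical(sort(names(p)), sort(want)))
    config_error(sprintf("marginal for '%s' must be named with levels: %s",
                         name, paste(want, collapse = ", ")))
  p[want]
}

#' Synthetic ICU cohort generator configuration
#'
#' Full parameterization of the synthetic cohort: demographic marginals,
#' an additive log-odds outcome model with optional latent acuity
#' heterogeneity, per-group miscalibration shifts and score-noise SDs for the
#' emitted risk scores, per-variable missingness, a Charlson comorbidity
#' model, and the multi-stay patient fraction. All randomness is governed by
#' one master seed; components consume fixed-offset child seeds.
#'
#' @param n_stays number of ICU stays to generate.
#' @param seed master integer seed.
#' @param marginals named list of probability vectors for `gender`,
#'   `ethnicity`, `insurance`, `age_band`; each must sum to 1.
#' @param intercept outcome-model intercept on the log-odds scale.
#' @param offsets named list of additive log-odds offsets per level for the
#'   four attributes (default all zero).
#' @param risk_heterogeneity_sd SD of a per-stay latent acuity term added to
#'   the outcome log-odds (default 0: risk fully determined by demographics).
#' @param miscalibration_shifts named list (attribute -> named numeric per
#'   level) of log-odds shifts applied to emitted scores (default all zero).
#' @param noise_degradation named list (same shape) of Gaussian log-odds
#'   score-noise SDs (default all zero); SDs from multiple attributes combine
#'   in quadrature.
#' @param missingness per-variable missingness profile
#'   (see [missingness_profile_from_coverage()]); must cover the 17-variable
#'   catalog exactly.
#' @param charlson Charlson comorbidity generation model as from
#'   [default_charlson_model()], or `NULL` for no diagnosis data.
#' @param multi_stay_fraction fraction of patients contributing two stays
#'   (separate admissions, shared demographics); default 0.15.
#' @return object of class `generator_config`.
#' @seealso [mimic_generator_config()], [starr_generator_config()],
#'   [generate_cohort()]
#' @export
generator_config <- function(n_stays,
                             seed = 1L,
                             marginals = lapply(.mimic_table1$shares,
                                                function(p) p / sum(p)),
                             intercept = qlogis(0.1323),
                             offsets = zero_offsets(),
                             risk_heterogeneity_sd = 0,
                             miscalibration_shifts = zero_offsets(),
                             noise_degradation = zero_offsets(),
                             missingness = missingness_profile_from_coverage(
                               .variable_coverage("mimic")),
                             charlson = NULL,
                             multi_stay_fraction = 0.15) {
  if (!is.numeric(n_stays) || length(n_stays) != 1L || n_stays < 1)
    config_error("n_stays must be a positive integer")
  check_seed(seed)
  marginals <- lapply(names(.fairicu_levels), function(a) {
    p <- marginals[[a]]
    if (is.null(p)) config_error(sprintf("missing marginal for '%s'", a))
    .check_marginal(p / 1, a)
  })
  names(marginals) <- names(.fairicu_levels)
  fill_levels <- function(x, what) {
    out <- zero_offsets()
    for (a in names(x %||% list())) {
      if (!a %in% names(out))
        config_error(sprintf("unknown attribute '%s' in %s", a, what))
      lv <- names(x[[a]])
      bad <- setdiff(lv, .fairicu_levels[[a]])
      if (length(bad))
        config_error(sprintf("unknown level(s) %s for '%s' in %s",
                             paste(bad, collapse = ", "), a, what))
      out[[a]][lv] <- x[[a]]
    }
    out
  }
  offsets <- fill_levels(offsets, "offsets")
  miscalibration_shifts <- fill_levels(miscalibration_shifts,
                                       "miscalibration_shifts")
  noise_degradation <- fill_levels(noise_degradation, "noise_degradation")
  if (any(unlist(noise_degradation) < 0))
    config_error("noise_degradation SDs must be non-negative")
  if (!identical(sort(missingness$variable_id), sort(.fairicu_variables)))
    config_error("missingness profile must cover the 17-variable catalog exactly")
  if (any(missingness$p_none < 0 | missingness$p_none > 1) ||
      any(missingness$p_hour < 0 | missingness$p_hour > 1))
    config_error("missingness probabilities must lie in [0,1]")
  if (risk_heterogeneity_sd < 0)
    config_error("risk_heterogeneity_sd must be non-negative")
  if (multi_stay_fraction < 0 || multi_stay_fraction > 1)
    config_error("multi_stay_fraction must lie in [0,1]")
  structure(list(
    n_stays = as.integer(n_stays), seed = seed, marginals = marginals,
    outcome = list(intercept = intercept, offsets = offsets,
                   risk_heterogeneity_sd = risk_heterogeneity_sd),
    miscalibration_shifts = miscalibration_shifts,
    noise_degradation = noise_degradation,
    missingness = missingness[order(match(missingness$variable_id,
                                          .fairicu_variables)), ],
    charlson = charlson,
    multi_stay_fraction = multi_stay_fraction
  ), class = "generator_config")
}

# Expected pooled event rate under the configured logistic model: exact
# enumeration over the demographic cells, Gaussian quadrature over the latent
# acuity term.
.acuity_grid <- function(sd, n = 801L) {
  if (sd == 0) return(list(z = 0, w = 1))
  z <- seq(-8, 8, length.out = n)
  w <- dnorm(z); w <- w / sum(w)
  list(z = z * sd, w = w)
}

.cell_table <- function(config) {
  cells <- expand.grid(lapply(config$marginals, names),
                       KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  p <- Reduce(`*`, lapply(names(config$marginals), function(a)
    config$marginals[[a]][cells[[a]]]))
  eta <- config$outcome$intercept +
    Reduce(`+`, lapply(names(config$marginals), function(a)
      config$outcome$offsets[[a]][cells[[a]]]))
  cells$p <- unname(p)
  cells$eta <- unname(eta)
  cells
}

#' Expected event rates implied by a generator configuration
#'
#' Computes, without simulation, the pooled event rate and the per-level
#' event rate for every demographic attribute implied by the configured
#' additive log-odds model (integrating over the latent acuity term).
#'
#' @param config a [generator_config()].
#' @return list with `overall` (scalar) and `by_level` (data frame:
#'   `attribute`, `level`, `rate`).
#' @export
implied_event_rates <- function(config) {
  cells <- .cell_table(config)
  gr <- .acuity_grid(config$outcome$risk_heterogeneity_sd)
  cell_rate <- vapply(cells$eta,
                      function(e) sum(plogis(e + gr$z) * gr$w), numeric(1))
  overall <- sum(cells$p * cell_rate)
  rows <- do.call(rbind, lapply(names(config$marginals), function(a) {
    lv <- .fairicu_levels[[a]]
    rate <- vapply(lv, function(l) {
      sel <- cells[[a]] == l
      sum(cells$p[sel] * cell_rate[sel]) / sum(cells$p[sel])
    }, numeric(1))
    data.frame(attribute = a, level = lv, rate = unname(rate),
               stringsAsFactors = FALSE)
  }))
  list(overall = overall, by_level = rows)
}

# Root-find the intercept giving a target pooled event rate.
.calibrate_intercept <- function(marginals, offsets, sd, target) {
  probe <- function(b0) {
    cfg <- list(marginals = marginals,
                outcome = list(intercept = b0, offsets = offsets,
                               risk_heterogeneity_sd = sd))
    cells <- .cell_table(cfg)
    gr <- .acuity_grid(sd)
    sum(cells$p * vapply(cells$eta, function(e)
      sum(plogis(e + gr$z) * gr$w), numeric(1))) - target
  }
  uniroot(probe, c(-12, 6), tol = 1e-10)$root
}

.published_config <- function(tab, coverage, n_stays, seed, charlson,
                              risk_heterogeneity_sd,
                              missingness = NULL, ...) {
  marginals <- lapply(tab$shares, function(p) p / sum(p))
  offsets <- .offsets_from_rates(tab$rates, tab$overall_rate)
  offsets$age_band <- offsets$age_band %||% rep(0, 5)
  b0 <- .calibrate_intercept(marginals, offsets, risk_heterogeneity_sd,
                             tab$overall_rate)
  generator_config(
    n_stays = n_stays, seed = seed, marginals = marginals,
    intercept = b0, offsets = offsets,
    risk_heterogeneity_sd = risk_heterogeneity_sd,
    missingness = missingness %||% missingness_profile_from_coverage(coverage),
    charlson = charlson, ...
  )
}

#' MIMIC-like default generator configuration
#'
#' Ships the demographic marginals (patient shares), per-level mortality
#' rates (pooled rate 13.23%) and per-variable missingness of the MIMIC-style
#' development cohort. Diagnosis histories are disabled by default, mirroring
#' that an ICU-only database does not support comorbidity lookback.
#'
#' @param n_stays,seed see [generator_config()].
#' @param risk_heterogeneity_sd latent acuity SD (default 1.8, giving a
#'   latent-risk AUROC of about 0.86).
#' @param charlson Charlson model or `NULL` (default `NULL`).
#' @param ... further arguments passed to [generator_config()].
#' @return a `generator_config`.
#' @export
mimic_generator_config <- function(n_stays = 20000L, seed = 1L,
                                   risk_heterogeneity_sd = 1.8,
                                   charlson = NULL, ...) {
  .published_config(.mimic_table1, .variable_coverage("mimic"), n_stays,
                    seed, charlson, risk_heterogeneity_sd, ...)
}

#' STARR-like default generator configuration
#'
#' Demographic marginals, per-level mortality rates (pooled rate 10.18%) and
#' missingness of the STARR-style external cohort. Diagnosis histories are
#' enabled (full-EHR source supports a two-year comorbidity lookback).
#'
#' @inheritParams mimic_generator_config
#' @return a `generator_config`.
#' @export
starr_generator_config <- function(n_stays = 6400L, seed = 1L,
                                   risk_heterogeneity_sd = 1.8,
                                   charlson = default_charlson_model(), ...) {
  .published_config(.starr_table1, .variable_coverage("starr"), n_stays,
                    seed, charlson, risk_heterogeneity_sd, ...)
}

#' Write / read a generator configuration as YAML
#'
#' @param config a `generator_config`.
#' @param path file path.
#' @return `read_generator_config` returns a validated `generator_config`.
#' @export
write_generator_config <- function(config, path) {
  x <- unclass(config)
  # named numeric vectors must become maps, not sequences
  as_map <- function(l) lapply(l, as.list)
  x$marginals <- as_map(x$marginals)
  x$outcome$offsets <- as_map(x$outcome$offsets)
  x$miscalibration_shifts <- as_map(x$miscalibration_shifts)
  x$noise_degradation <- as_map(x$noise_degradation)
  x$missingness <- as.list(x$missingness)
  if (!is.null(x$charlson)) {
    x$charlson$factors <- as.list(x$charlson$factors)
    x$charlson$mapping <- as.list(x$charlson$mapping)
  }
  yaml::write_yaml(x, path, precision = 15L)
  invisible(path)
}

#' @rdname write_generator_config
#' @export
read_generator_config <- function(path) {
  x <- yaml::read_yaml(path)
  to_named <- function(l) lapply(l, function(v) unlist(v))
  charlson <- x$charlson
  if (!is.null(charlson)) {
    charlson$factors <- as.data.frame(charlson$factors,
                                      stringsAsFactors = FALSE)
    charlson$mapping <- as.data.frame(charlson$mapping,
                                      stringsAsFactors = FALSE)
  }
  generator_config(
    n_stays = x$n_stays, seed = x$seed, marginals = to_named(x$marginals),
    intercept = x$outcome$intercept,
    offsets = to_named(x$outcome$offsets),
    risk_heterogeneity_sd = x$outcome$risk_heterogeneity_sd,
    miscalibration_shifts = to_named(x$miscalibration_shifts),
    noise_degradation = to_named(x$noise_degradation),
    missingness = as.data.frame(x$missingness, stringsAsFactors = FALSE),
    charlson = charlson,
    multi_stay_fraction = x$multi_stay_fraction
  )
}
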