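#' Generate a synthetic ICU cohort
#'
#' Draws a cohort of ICU stays from a [generator_config()]: demographics are
#' sampled independently from the configured marginals at the patient level
#' (multi-stay patients share demographics across their admissions), the
#' in-hospital mortality label is Bernoulli with probability
#' `plogis(intercept + sum of level offsets + latent acuity)`, hourly
#' physiological observations follow the per-variable missingness profile,
#' and dated diagnosis codes follow the Charlson comorbidity model. The
#' latent true risk of every stay is retained on the in-memory object (column
#' `.true_risk`) but never exported to files.
#'
#' @param config a [generator_config()].
#' @return object of class `icu_cohort`: list with data frames `stays`
#'   (stay_id, patient_id, admission_id, age, gender, ethnicity, insurance,
#'   label, los_hours, .true_risk, .eta), `observations` (stay_id,
#'   variable_id, hour, value) and `diagnoses` (stay_id, code,
#'   days_before_admission), plus `provenance` and `config_digest`.
#' @export
generate_cohort <- function(config) {
  if (!inherits(config, "generator_config"))
    config_error("config must be a generator_config object")
  n <- config$n_stays
  seed <- config$seed

  # --- patients and demographics -------------------------------------------
  f <- config$multi_stay_fraction
  n_pat <- max(1L, round(n / (1 + f)))
  n_two <- n - n_pat                 # patients contributing two stays
  if (n_two < 0L) { n_pat <- n; n_two <- 0L }
  demo <- with_seed(child_seed(seed, 1L), {
    d <- lapply(names(config$marginals), function(a) {
      lv <- names(config$marginals[[a]])
      lv[sample.int(length(lv), n_pat, replace = TRUE,
                    prob = config$marginals[[a]])]
    })
    names(d) <- names(config$marginals)
    lo <- c(`18-29` = 18, `30-49` = 30, `50-69` = 50, `70-89` = 70, `90+` = 90)
    hi <- c(`18-29` = 29, `30-49` = 49, `50-69` = 69, `70-89` = 89, `90+` = 99)
    d$age <- lo[d$age_band] +
      floor(runif(n_pat) * (hi[d$age_band] - lo[d$age_band] + 1))
    d
  })
  # first n_two patients contribute a second stay (separate admission)
  pat_idx <- c(seq_len(n_pat), seq_len(n_two))
  stays <- data.frame(
    stay_id      = sprintf("S%07d", seq_len(n)),
    patient_id   = sprintf("P%07d", pat_idx),
    admission_id = sprintf("A%07d", seq_len(n)),
    age          = unname(demo$age[pat_idx]),
    gender       = demo$gender[pat_idx],
    ethnicity    = demo$ethnicity[pat_idx],
    insurance    = demo$insurance[pat_idx],
    stringsAsFactors = FALSE
  )
  band <- as.character(age_band(stays$age))

  # --- outcome model -------------------------------------------------------
  off <- config$outcome$offsets
  eta <- config$outcome$intercept +
    off$gender[stays$gender] + off$ethnicity[stays$ethnicity] +
    off$insurance[stays$insurance] + off$age_band[band]
  out <- with_seed(child_seed(seed, 2L), {
    sdz <- config$outcome$risk_heterogeneity_sd
    eta2 <- eta + if (sdz > 0) rnorm(n, 0, sdz) else 0
    risk <- plogis(eta2)
    list(eta = unname(eta2), risk = unname(risk),
         label = rbinom(n, 1L, risk))
  })
  stays$label <- out$label
  stays$los_hours <- with_seed(child_seed(seed, 5L),
                               48 + rgamma(n, shape = 1.6, scale = 70))
  stays$.true_risk <- out$risk
  stays$.eta <- out$eta

  # --- hourly observations -------------------------------------------------
  obs <- with_seed(child_seed(seed, 3L), {
    ms <- config$missingness
    parts <- vector("list", nrow(ms))
    for (v in seq_len(nrow(ms))) {
      present <- which(runif(n) >= ms$p_none[v])
      np <- length(present)
      if (np == 0L || ms$p_hour[v] <= 0) next
      keep <- matrix(runif(np * 48L) < ms$p_hour[v], nrow = np)
      # a present stay always has at least one observation, so the share of
      # stays with zero observations equals p_none exactly
      empty <- which(rowSums(keep) == 0L)
      if (length(empty))
        keep[cbind(empty, sample.int(48L, length(empty), replace = TRUE))] <- TRUE
      w <- which(keep)
      stay_i <- present[(w - 1L) %% np + 1L]
      hour   <- (w - 1L) %/% np
      parts[[v]] <- data.table::data.table(
        stay_id = stays$stay_id[stay_i],
        variable_id = ms$variable_id[v],
        hour = hour,
        value = rnorm(sum(keep), ms$mean[v], ms$sd[v])
      )
    }
    parts <- parts[!vapply(parts, is.null, logical(1))]
    if (length(parts)) as.data.frame(data.table::rbindlist(parts))
    else data.frame(stay_id = character(), variable_id = character(),
                    hour = integer(), value = numeric(),
                    stringsAsFactors = FALSE)
  })

  # --- diagnosis histories -------------------------------------------------
  dx <- with_seed(child_seed(seed, 4L), {
    ch <- config$charlson
    if (is.null(ch)) {
      data.frame(stay_id = character(), code = character(),
                 days_before_admission = integer(),
                 stringsAsFactors = FALSE)
    } else {
      fac <- ch$factors
      parts <- lapply(seq_len(nrow(fac)), function(k) {
        # prevalence tilted by latent acuity: sicker stays carry more burden
        p <- plogis(qlogis(fac$prevalence[k]) +
                      fac$assoc[k] * (out$eta - config$outcome$intercept))
        has <- which(runif(n) < p)
        if (!length(has)) return(NULL)
        codes <- ch$mapping$code[ch$mapping$factor_id == fac$factor_id[k]]
        data.table::data.table(
          stay_id = stays$stay_id[has],
          code = codes[sample.int(length(codes), length(has), replace = TRUE)],
          days_before_admission = sample.int(1095L, length(has),
                                             replace = TRUE) - 1L
        )
      })
      parts <- parts[!vapply(parts, is.null, logical(1))]
      if (length(parts)) as.data.frame(data.table::rbindlist(parts))
      else data.frame(stay_id = character(), code = character(),
                      days_before_admission = integer(),
                      stringsAsFactors = FALSE)
    }
  })

  new_cohort(stays, obs, dx,
             provenance = "synthetic",
             config_digest = rlang::hash(unclass(config)))
}

#' Construct an ICU cohort from its component tables
#'
#' Assembles an `icu_cohort` from hand-built or externally loaded tables.
#' `stays` needs columns `stay_id`, `patient_id`, `admission_id`, `age`,
#' `gender`, `ethnicity`, `insurance`, `label`, `los_hours`; `observations`
#' needs `stay_id`, `variable_id`, `hour`, `value`; `diagnoses` needs
#' `stay_id`, `code`, `days_before_admission`.
#'
#' @param stays,observations,diagnoses component data frames.
#' @param provenance free-text label.
#' @return an `icu_cohort`.
#' @export
icu_cohort <- function(stays,
                       observations = data.frame(stay_id = character(),
                                                 variable_id = character(),
                                                 hour = integer(),
                                                 value = numeric()),
                       diagnoses = data.frame(stay_id = character(),
                                              code = character(),
                                              days_before_admission = integer()),
                       provenance = "manual") {
  missing_cols <- setdiff(.cohort_schemas$stays, names(stays))
  if (length(missing_cols))
    schema_error(sprintf("stays table lacks column(s): %s",
                         paste(missing_cols, collapse = ", ")))
  new_cohort(stays, observations, diagnoses, provenance = provenance)
}

new_cohort <- function(stays, observations, diagnoses,
                       provenance = "", config_digest = "") {
  if (anyDuplicated(stays$stay_id))
    schema_error("stay_id values must be unique within a cohort")
  structure(list(stays = stays, observations = observations,
                 diagnoses = diagnoses, provenance = provenance,
                 config_digest = config_digest),
            class = "icu_cohort")
}

#' @export
print.icu_cohort <- function(x, ...) {
  cat(sprintf("<icu_cohort> %d stays, %d patients, %d observation rows, %d diagnosis rows\n",
              nrow(x$stays), length(unique(x$stays$patient_id)),
              nrow(x$observations), nrow(x$diagnoses)))
  if (nrow(x$stays))
    cat(sprintf("  event rate: %.2f%%  provenance: %s\n",
                100 * mean(x$stays$label), x$provenance))
  invisible(x)
}

#' Emit risk scores for a synthetic cohort
#'
#' Stands in for an external risk model: the emitted score is the latent true
#' risk perturbed on the log-odds scale by the configured per-group
#' miscalibration shifts (summed over attributes) and Gaussian score noise
#' (per-attribute SDs combined in quadrature), then clipped to the open unit
#' interval. With all shifts and SDs zero the score equals the true risk
#' exactly, giving a calibrated-by-construction oracle.
#'
#' @param cohort a cohort produced by [generate_cohort()] (latent risks
#'   required).
#' @param config the [generator_config()] carrying `miscalibration_shifts`
#'   and `noise_degradation`.
#' @return a `prediction_set`: data frame with columns `stay_id`, `score`.
#' @export
emit_predictions <- function(cohort, config) {
  st <- cohort$stays
  if (is.null(st$.true_risk))
    fairicu_stop("cohort lacks latent true risks; emit_predictions requires a generated cohort",
                 "fairicu_unsupported_input")
  band <- as.character(age_band(st$age))
  sh <- config$miscalibration_shifts
  shift <- sh$gender[st$gender] + sh$ethnicity[st$ethnicity] +
    sh$insurance[st$insurance] + sh$age_band[band]
  nd <- config$noise_degradation
  noise_sd <- sqrt(nd$gender[st$gender]^2 + nd$ethnicity[st$ethnicity]^2 +
                     nd$insurance[st$insurance]^2 + nd$age_band[band]^2)
  score <- with_seed(child_seed(config$seed, 10L), {
    eps <- if (any(noise_sd > 0)) rnorm(nrow(st), 0, 1) * noise_sd else 0
    plogis(qlogis(st$.true_risk) + unname(shift) + eps)
  })
  prediction_set(st$stay_id, pmin(pmax(score, 1e-12), 1 - 1e-12))
}

#' Construct a prediction set
#'
#' @param stay_id character vector of stay identifiers.
#' @param score risk scores in `[0,1]`.
#' @return data frame of class `prediction_set`.
#' @export
prediction_set <- function(stay_id, score) {
  if (length(stay_id) != length(score))
    schema_error("stay_id and score must have equal length")
  if (anyNA(score) || any(score < 0 | score > 1))
    schema_error("scores must lie in [0,1] and contain no missing values")
  structure(data.frame(stay_id = as.character(stay_id), score = score,
                       stringsAsFactors = FALSE),
            class = c("prediction_set", "data.frame"))
}

.cohort_schemas <- list(
  stays = c("stay_id", "patient_id", "admission_id", "age", "gender",
            "ethnicity", "insurance", "label", "los_hours"),
  observations = c("stay_id", "variable_id", "hour", "value"),
  diagnoses = c("stay_id", "code", "days_before_admission")
)

#' Write / read a cohort as delimited text files
#'
#' A cohort is stored as three UTF-8 tab-separated files with mandatory
#' header rows: `stays.tsv`, `observations.tsv` and `diagnoses.tsv`. Missing
#' values are encoded as empty fields. Latent true risks are deliberately
#' excluded from the export schema so file round-trips cannot leak them.
#'
#' @param cohort an `icu_cohort`.
#' @param dir directory to write into (created if needed).
#' @return `read_cohort` returns an `icu_cohort` (with empty
#'   `config_digest`, marking a file-loaded cohort).
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (part in names(.cohort_schemas)) {
    df <- cohort[[part]][, .cohort_schemas[[part]], drop = FALSE]
    data.table::fwrite(df, file.path(dir, paste0(part, ".tsv")),
                       sep = "\t", na = "", quote = FALSE)
  }
  invisible(dir)
}

#' @rdname write_cohort
#' @param provenance label recorded on the loaded cohort (default the
#'   directory path).
#' @export
read_cohort <- function(dir, provenance = dir) {
  parts <- lapply(names(.cohort_schemas), function(part) {
    path <- file.path(dir, paste0(part, ".tsv"))
    if (!file.exists(path)) schema_error(sprintf("missing cohort file: %s", path))
    df <- as.data.frame(data.table::fread(path, sep = "\t",
                                          colClasses = list(character = "stay_id")))
    missing_cols <- setdiff(.cohort_schemas[[part]], names(df))
    if (length(missing_cols))
      schema_error(sprintf("file %s lacks column(s): %s", path,
                           paste(missing_cols, collapse = ", ")))
    df[, .cohort_schemas[[part]], drop = FALSE]
  })
  names(parts) <- names(.cohort_schemas)
  for (col in c("patient_id", "admission_id")) {
    parts$stays[[col]] <- as.character(parts$stays[[col]])
  }
  new_cohort(parts$stays, parts$observations, parts$diagnoses,
             provenance = provenance, config_digest = "")
}

# Subset a cohort to a set of stay_ids, keeping all three tables aligned.
subset_cohort <- function(cohort, stay_ids) {
  new_cohort(
    cohort$stays[cohort$stays$stay_id %in% stay_ids, , drop = FALSE],
    cohort$observations[cohort$observations$stay_id %in% stay_ids, , drop = FALSE],
    cohort$diagnoses[cohort$diagnoses$stay_id %in% stay_ids, , drop = FALSE],
    provenance = cohort$provenance, config_digest = cohort$config_digest
  )
}
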