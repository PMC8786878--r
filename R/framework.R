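#' Framework configuration
#'
#' Bundles the per-task configurations and split fractions for the
#' three-stage audit. All random operations consume explicit child seeds
#' derived from `seed`.
#'
#' @param seed master seed for splits, bootstraps and the predictor.
#' @param split_a training fraction of the development cohort (stage 1
#'   train/test split, default 0.85).
#' @param split_b training fraction of the external cohort (stage 3 split,
#'   default 0.80).
#' @param paper_mode if `TRUE`, stage 2 scores the whole external cohort;
#'   the default `FALSE` scores the external cohort's held-out stage-3 test
#'   partition so stages 2 and 3 share a test set and are directly
#'   comparable.
#' @param metric a [metric_config()].
#' @param bootstrap a [bootstrap_config()].
#' @param calibration a [calibration_config()].
#' @param cohort a [cohort_config()].
#' @param charlson a [charlson_config()].
#' @param parity_tol scenario-1 event-rate tolerance in percentage points.
#' @return object of class `framework_config`.
#' @export
framework_config <- function(seed = 1L, split_a = 0.85, split_b = 0.80,
                             paper_mode = FALSE,
                             metric = metric_config(),
                             bootstrap = bootstrap_config(),
                             calibration = calibration_config(),
                             cohort = cohort_config(),
                             charlson = charlson_config(),
                             parity_tol = 1.0) {
  check_seed(seed)
  if (split_a <= 0 || split_a >= 1 || split_b <= 0 || split_b >= 1)
    config_error("split fractions must lie strictly inside (0,1)")
  structure(list(seed = seed, split_a = split_a, split_b = split_b,
                 paper_mode = isTRUE(paper_mode), metric = metric,
                 bootstrap = bootstrap, calibration = calibration,
                 cohort = cohort, charlson = charlson,
                 parity_tol = parity_tol),
            class = "framework_config")
}

# Per-stay feature frame for the baseline predictor: demographics as factors
# with the canonical level sets plus per-variable covered-hour counts
# (scaled to [0,1] by the window length).
.predictor_features <- function(cohort, window = 48L) {
  st <- cohort$stays
  df <- data.frame(
    gender = factor(st$gender, levels = .fairicu_levels$gender),
    ethnicity = factor(st$ethnicity, levels = .fairicu_levels$ethnicity),
    insurance = factor(st$insurance, levels = .fairicu_levels$insurance),
    age_band = factor(as.character(age_band(st$age)),
                      levels = .fairicu_levels$age_band)
  )
  obs <- data.table::as.data.table(cohort$observations)
  counts <- matrix(0, nrow = nrow(st), ncol = length(.fairicu_variables),
                   dimnames = list(NULL, paste0("obs_", .fairicu_variables)))
  if (nrow(obs)) {
    obs <- obs[obs$hour >= 0 & obs$hour < window]
    pts <- obs[, list(points = data.table::uniqueN(hour)),
               by = c("stay_id", "variable_id")]
    ri <- match(pts$stay_id, st$stay_id)
    ci <- match(paste0("obs_", pts$variable_id), colnames(counts))
    ok <- !is.na(ri) & !is.na(ci)
    counts[cbind(ri[ok], ci[ok])] <- pts$points[ok] / window
  }
  cbind(df, as.data.frame(counts))
}

#' Fit the bundled baseline risk predictor
#'
#' A transparent additive logistic model of the in-hospital mortality label
#' on demographics (gender, ethnicity, insurance, age band) and the 17
#' per-variable observation counts. It is deliberately simple: the audit
#' framework treats the predictor as pluggable, and this model exists so
#' every stage of the pipeline can be exercised end to end with coefficients
#' that are fully exposed in the report.
#'
#' @param train an `icu_cohort` containing both outcome classes.
#' @param seed integer seed recorded on the predictor (the fit itself is
#'   deterministic).
#' @return object of class `baseline_predictor` with elements
#'   `coefficients`, `id`, `seed`.
#' @export
fit_baseline_predictor <- function(train, seed = 1L) {
  if (length(unique(train$stays$label)) < 2L)
    fairicu_stop("training cohort must contain both outcome classes",
                 "fairicu_fit_error")
  X <- .predictor_features(train)
  X$label <- train$stays$label
  fit <- suppressWarnings(
    glm(label ~ ., data = X, family = binomial())
  )
  coefs <- coef(fit)
  coefs[is.na(coefs)] <- 0       # aliased columns (e.g. all-absent variable)
  structure(list(coefficients = coefs, id = "baseline-logistic",
                 seed = seed, formula_terms = attr(fit$terms, "term.labels"),
                 xlevels = fit$xlevels),
            class = "baseline_predictor")
}

#' Score a cohort with a fitted baseline predictor
#'
#' @param object a `baseline_predictor`.
#' @param cohort an `icu_cohort` to score.
#' @param ... unused.
#' @return a [prediction_set()].
#' @export
predict.baseline_predictor <- function(object, cohort, ...) {
  X <- .predictor_features(cohort)
  mm <- stats::model.matrix(~ ., data = X)
  beta <- object$coefficients
  common <- intersect(colnames(mm), names(beta))
  eta <- as.vector(mm[, common, drop = FALSE] %*% beta[common])
  prediction_set(cohort$stays$stay_id,
                 pmin(pmax(plogis(eta), 1e-12), 1 - 1e-12))
}

#' Oracle predictor for synthetic cohorts
#'
#' A predictor whose scores are the generator's emitted risk scores
#' ([emit_predictions()]): the latent true risk perturbed by the configured
#' miscalibration shifts and score noise. It stands in for a strong
#' externally trained risk model when auditing the pipeline on synthetic
#' data, and supports parameter-recovery experiments (known injected bias).
#' Only cohorts generated by [generate_cohort()] can be scored.
#'
#' @param config the [generator_config()] whose shift/noise parameters
#'   define the emitted scores.
#' @return object of class `oracle_predictor`.
#' @export
oracle_predictor <- function(config) {
  structure(list(id = "synthetic-oracle", config = config,
                 seed = config$seed),
            class = "oracle_predictor")
}

#' @rdname oracle_predictor
#' @param object an `oracle_predictor`.
#' @param cohort a generated `icu_cohort`.
#' @param ... unused.
#' @export
predict.oracle_predictor <- function(object, cohort, ...) {
  emit_predictions(cohort, object$config)
}

# Align a prediction set to a cohort's stay order.
.aligned_scores <- function(cohort, predictions) {
  m <- match(cohort$stays$stay_id, predictions$stay_id)
  if (anyNA(m))
    schema_error(sprintf("predictions missing for %d stay(s), e.g. %s",
                         sum(is.na(m)),
                         cohort$stays$stay_id[which(is.na(m))[1]]))
  predictions$score[m]
}

#' Run one audit stage
#'
#' Executes the three audit tasks on a test cohort: (A) descriptive
#' profiling (demographics/outcome table and missingness profile), (B)
#' performance evaluation (event rate, bootstrap discrimination metrics,
#' validation curve) and fairness evaluation (classification parity,
#' per-group calibration-in-the-large, and — when the cohort carries
#' diagnosis data — Charlson comorbidity-vs-risk-percentile curves), and
#' (C) assembly into a structured stage report.
#'
#' @param stage_id one of `"internal"`, `"external"`,
#'   `"retrained_internal"`.
#' @param test the test `icu_cohort`.
#' @param predictor a fitted predictor (used when `train` is `NULL`).
#' @param train optional training cohort; when given, a baseline predictor
#'   is fitted on it first.
#' @param config a [framework_config()].
#' @return object of class `stage_report`.
#' @export
run_stage <- function(stage_id, test, predictor = NULL, train = NULL,
                      config = framework_config()) {
  stage_id <- match.arg(stage_id,
                        c("internal", "external", "retrained_internal"))
  if (!is.null(train))
    predictor <- fit_baseline_predictor(train, seed = child_seed(config$seed, 20L))
  if (is.null(predictor))
    config_error("run_stage needs either a fitted predictor or a training cohort")
  preds <- predict(predictor, test)
  scores <- .aligned_scores(test, preds)
  labels <- test$stays$label

  demo <- demographics_table(test)
  miss <- missingness_profile(test, config$cohort)

  boot <- config$bootstrap
  metric_names <- c("auroc", "auprc", "accuracy", "precision_event",
                    "precision_nonevent", "recall_event", "recall_nonevent")
  metrics <- do.call(rbind, lapply(seq_along(metric_names), function(i) {
    est <- tryCatch(
      bootstrap_ci(metric_names[i], scores, labels,
                   bootstrap_config(K = boot$K, alpha = boot$alpha,
                                    seed = child_seed(config$seed, 30L + i)),
                   config$metric),
      # e.g. precision of a never-predicted class: reported as flagged
      # undefined, never silently zero (the accuracy-paradox case)
      fairicu_metric_undefined = function(e) NULL)
    if (is.null(est))
      data.frame(metric = metric_names[i], point = NA_real_,
                 ci_lo = NA_real_, ci_hi = NA_real_, undefined = TRUE,
                 stringsAsFactors = FALSE)
    else
      data.frame(metric = est$name, point = est$point, ci_lo = est$ci_lo,
                 ci_hi = est$ci_hi, undefined = FALSE,
                 stringsAsFactors = FALSE)
  }))

  vc <- validation_curve(scores, labels, config$calibration,
                         threshold = config$metric$threshold)
  grp <- test$stays[, .fairicu_attributes]
  parity <- classification_parity(
    scores, labels, grp,
    bootstrap_config(K = boot$K, alpha = boot$alpha,
                     seed = child_seed(config$seed, 40L)),
    parity_tol = config$parity_tol)
  citl <- calibration_in_the_large(
    scores, labels, grp,
    bootstrap_config(K = boot$K, alpha = boot$alpha,
                     seed = child_seed(config$seed, 50L)))

  comorbidity <- NULL
  if (nrow(test$diagnoses) > 0L) {
    ch <- charlson_scores(test, config$charlson)
    comorbidity <- comorbidity_risk_curve(scores, unname(ch), grp)
  }

  structure(list(
    stage_id = stage_id,
    test_digest = rlang::hash(test$stays$stay_id),
    predictor_id = predictor$id,
    predictor_coefficients = predictor$coefficients,
    n = nrow(test$stays),
    event_rate_pct = 100 * mean(labels),
    demographics = demo,
    missingness = miss,
    metrics = metrics,
    validation = vc,
    parity = parity,
    citl = citl,
    comorbidity = comorbidity,
    has_comorbidity_block = !is.null(comorbidity),
    meta = list(seed = config$seed, K = boot$K, alpha = boot$alpha,
                threshold = config$metric$threshold,
                timestamp = format(Sys.time(), tz = "UTC"))
  ), class = "stage_report")
}

#' @export
print.stage_report <- function(x, ...) {
  cat(sprintf("<stage_report> stage %s: n=%d, event rate %.2f%%\n",
              x$stage_id, x$n, x$event_rate_pct))
  print(x$metrics, digits = 3)
  invisible(x)
}

.split_cohort <- function(cohort, frac, seed) {
  ids <- cohort$stays$stay_id
  n_train <- round(frac * length(ids))
  train_ids <- with_seed(seed, sample(ids, n_train))
  list(train = subset_cohort(cohort, train_ids),
       test = subset_cohort(cohort, setdiff(ids, train_ids)))
}

#' Run the full three-stage audit
#'
#' Stage 1 (internal validation): the development cohort is split into
#' train/test, the baseline predictor is fitted on the training partition
#' and audited on the held-out test partition. Stage 2 (external
#' validation): the stage-1 model is audited on the external cohort — by
#' default on the external cohort's stage-3 test partition so stages 2 and 3
#' evaluate on the identical test set (`paper_mode = TRUE` audits the whole
#' external cohort instead). Stage 3 (retrained internal validation): the
#' model is refitted on the external training partition and audited on the
#' same external test partition. Benchmark exclusion rules are applied to
#' both cohorts first.
#'
#' @param cohort_a development cohort (`icu_cohort`).
#' @param cohort_b external cohort (`icu_cohort`).
#' @param config a [framework_config()].
#' @param predictor_factory function `(train_cohort, seed) -> predictor`
#'   implementing the pluggable-predictor contract (default
#'   [fit_baseline_predictor()]).
#' @return object of class `framework_report`: list with `stages` (named
#'   list of three `stage_report`s), `deltas` (data frame of cross-stage
#'   metric differences with CI-overlap indicators) and `exclusions`.
#' @export
run_framework <- function(cohort_a, cohort_b, config = framework_config(),
                          predictor_factory = fit_baseline_predictor) {
  a <- apply_exclusions(cohort_a, config$cohort)
  b <- apply_exclusions(cohort_b, config$cohort)
  excl <- list(a = attr(a, "exclusions"), b = attr(b, "exclusions"))
  for (co in list(a, b))
    if (length(unique(co$stays$label)) < 2L)
      fairicu_stop("both cohorts must contain both outcome classes after exclusions",
                   "fairicu_fit_error")
  sa <- .split_cohort(a, config$split_a, child_seed(config$seed, 60L))
  sb <- .split_cohort(b, config$split_b, child_seed(config$seed, 61L))

  model_a <- predictor_factory(sa$train, seed = child_seed(config$seed, 20L))
  stage1 <- run_stage("internal", sa$test, predictor = model_a, config = config)
  stage2_test <- if (config$paper_mode) b else sb$test
  stage2 <- run_stage("external", stage2_test, predictor = model_a,
                      config = config)
  model_b <- predictor_factory(sb$train, seed = child_seed(config$seed, 21L))
  stage3 <- run_stage("retrained_internal", sb$test, predictor = model_b,
                      config = config)

  stages <- list(internal = stage1, external = stage2,
                 retrained_internal = stage3)
  pairs <- list(c("internal", "external"),
                c("external", "retrained_internal"))
  deltas <- do.call(rbind, lapply(pairs, function(p) {
    m1 <- stages[[p[1]]]$metrics
    m2 <- stages[[p[2]]]$metrics
    data.frame(
      from = p[1], to = p[2], metric = m1$metric,
      delta = m2$point - m1$point,
      ci_overlap = !(m1$ci_lo > m2$ci_hi | m2$ci_lo > m1$ci_hi),
      stringsAsFactors = FALSE)
  }))
  structure(list(stages = stages, deltas = deltas, exclusions = excl,
                 config_seed = config$seed),
            class = "framework_report")
}

#' @export
print.framework_report <- function(x, ...) {
  for (s in x$stages) print(s)
  cat("\nCross-stage deltas:\n")
  print(x$deltas, digits = 3)
  invisible(x)
}

#' Serialize / restore a stage or framework report
#'
#' Reports are written with `jsonlite::serializeJSON`, which preserves R
#' types and attributes exactly, so write-read-write round-trips are
#' byte-identical.
#'
#' @param report a `stage_report` or `framework_report`.
#' @param path file path (`.json`).
#' @return `read_report` returns the restored report object.
#' @export
write_report <- function(report, path) {
  writeLines(jsonlite::serializeJSON(report, digits = NA), path)
  invisible(path)
}

#' @rdname write_report
#' @export
read_report <- function(path) {
  jsonlite::unserializeJSON(paste(readLines(path), collapse = "\n"))
}

#' Export the delimited tables of a stage report
#'
#' Writes the report's plot-ready data blocks as tab-separated text files
#' (demographics, missingness, Table-3-shaped metrics, risk bins, LOWESS
#' grid, histogram, group panels, parity findings, calibration-in-the-large
#' rows and, when present, comorbidity curves) into a directory.
#'
#' @param report a `stage_report`.
#' @param dir output directory (created if needed).
#' @return invisibly, the vector of files written.
#' @export
export_stage_tables <- function(report, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  tabs <- list(
    demographics = report$demographics,
    missingness = report$missingness,
    metrics = report$metrics,
    risk_bins = report$validation$bins,
    lowess = report$validation$lowess,
    histogram = report$validation$histogram,
    group_panels = report$parity$panels,
    parity_findings = report$parity$findings,
    citl = as.data.frame(report$citl)
  )
  if (!is.null(report$comorbidity))
    tabs$comorbidity_curves <- as.data.frame(report$comorbidity)
  files <- character(0)
  for (nm in names(tabs)) {
    f <- file.path(dir, paste0(report$stage_id, "_", nm, ".tsv"))
    data.table::fwrite(tabs[[nm]], f, sep = "\t")
    files <- c(files, f)
  }
  invisible(files)
}
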