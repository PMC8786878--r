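#' @import data.table
#' @importFrom stats rnorm rbinom runif rgamma plogis qlogis qnorm quantile
#'   glm binomial predict uniroot dnorm setNames aggregate coef model.matrix
#'   approx
#' @importFrom graphics hist
#' @importFrom utils head tail
NULL

.datatable.aware <- TRUE

# Canonical demographic attribute levels used throughout the audit.
.fairicu_levels <- list(
  gender    = c("Female", "Male"),
  ethnicity = c("Asian", "Black", "Hispanic", "White", "Other"),
  insurance = c("Medicare", "Medicaid", "Private", "Other"),
  age_band  = c("18-29", "30-49", "50-69", "70-89", "90+")
)

.fairicu_attributes <- c("gender", "ethnicity", "insurance")

# 17-variable physiological catalog (first-48h observation window).
.fairicu_variables <- c(
  "capillary_refill_rate", "diastolic_blood_pressure",
  "fraction_inspired_oxygen", "gcs_eye", "gcs_motor", "gcs_total",
  "gcs_verbal", "glucose", "heart_rate", "height",
  "mean_arterial_pressure", "oxygen_saturation", "respiratory_rate",
  "systolic_blood_pressure", "temperature", "weight", "ph"
)

fairicu_stop <- function(msg, class, ...) {
  stop(structure(
    class = c(class, "fairicu_error", "error", "condition"),
    list(message = msg, call = sys.call(-1), ...)
  ))
}

config_error <- function(msg) fairicu_stop(msg, "fairicu_config_error")
schema_error <- function(msg) fairicu_stop(msg, "fairicu_schema_error")
metric_undefined_error <- function(msg) fairicu_stop(msg, "fairicu_metric_undefined")

#' Age band of an age in years
#'
#' Bands follow the audit's demographic table layout (adults only; cohorts
#' are restricted to age >= 18 by the benchmark exclusions).
#'
#' @param age numeric vector of ages in years.
#' @return factor with levels `18-29`, `30-49`, `50-69`, `70-89`, `90+`.
#' @export
age_band <- function(age) {
  cut(age, breaks = c(18, 30, 50, 70, 90, Inf),
      labels = .fairicu_levels$age_band, right = FALSE)
}

# Evaluate `expr` under a fixed seed without disturbing the caller's RNG
# state; a NULL seed means "use the ambient RNG stream".
with_seed <- function(seed, expr) {
  if (is.null(seed)) expr else withr::with_seed(as.integer(seed), expr)
}

check_seed <- function(seed) {
  if (is.null(seed)) return(invisible(NULL))
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed) ||
      abs(seed) >= 2^31 - 1000)
    config_error("seed must be a single integer with |seed| < 2^31 - 1000")
  invisible(NULL)
}

# Child seeds are derived from one master seed by fixed offsets so that each
# random component consumes an independent, reproducible stream.
child_seed <- function(seed, offset) {
  if (is.null(seed)) NULL else as.integer(seed) + as.integer(offset)
}

check_scores_labels <- function(scores, labels) {
  if (length(scores) != length(labels))
    schema_error("scores and labels must have equal length")
  if (anyNA(scores) || anyNA(labels))
    schema_error("scores and labels must not contain missing values")
  if (!all(labels %in% c(0, 1)))
    schema_error("labels must be coded 0/1")
  invisible(NULL)
}

`%||%` <- function(x, y) if (is.null(x)) y else x
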