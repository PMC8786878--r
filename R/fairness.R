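# groups argument: a factor/character vector (one attribute) or a data frame
# of attribute columns. Normalized to a named list of character vectors.
.normalize_groups <- function(groups, n) {
  if (is.data.frame(groups)) {
    out <- lapply(groups, as.character)
  } else {
    out <- list(group = as.character(groups))
  }
  for (a in names(out)) {
    if (length(out[[a]]) != n)
      schema_error(sprintf("group column '%s' must match the number of stays", a))
    if (anyNA(out[[a]]))
      schema_error(sprintf("group column '%s' contains missing values", a))
    if (a %in% names(.fairicu_levels)) {
      bad <- setdiff(unique(out[[a]]), .fairicu_levels[[a]])
      if (length(bad))
        schema_error(sprintf("unknown %s level(s): %s", a,
                             paste(bad, collapse = ", ")))
    }
  }
  out
}

#' Classification parity assessment
#'
#' Computes per-group AUROC and AUPRC with bootstrap confidence intervals
#' (resampling within each level) and derives pairwise parity findings under
#' the class-imbalance-aware interpretation rule: an observed performance
#' difference can be attributed to unfair predictions only when (scenario 1)
#' the two groups have materially similar event rates, or (scenario 2) the
#' event-rate ordering is the converse of the performance ordering (the
#' better-performing group carries the event rate that should disadvantage
#' it). A `parity_violation` verdict additionally requires disjoint
#' confidence intervals; overlapping intervals yield
#' `no_material_difference`, and disjoint intervals whose gap is explained by
#' the event-rate direction yield `imbalance_confounded`.
#'
#' @inheritParams auroc
#' @param groups factor/character vector or data frame of demographic
#'   attribute columns aligned with `scores`.
#' @param bootstrap_cfg a [bootstrap_config()].
#' @param parity_tol event-rate similarity tolerance in percentage points
#'   for scenario 1 (default 1.0).
#' @return list of class `parity_assessment` with `panels` (data frame:
#'   `attribute`, `level`, `n`, `event_rate_pct`, `assessable`, `metric`,
#'   `point`, `ci_lo`, `ci_hi`) and `findings` (data frame: `attribute`,
#'   `level_a`, `level_b`, `metric`, `event_rate_gap_pp`, `ci_overlap`,
#'   `verdict`, `rationale`).
#' @export
classification_parity <- function(scores, labels, groups,
                                  bootstrap_cfg = bootstrap_config(),
                                  parity_tol = 1.0) {
  check_scores_labels(scores, labels)
  groups <- .normalize_groups(groups, length(scores))
  panels <- list()
  for (a in names(groups)) {
    g <- groups[[a]]
    for (i in seq_along(lv <- sort(unique(g)))) {
      l <- lv[i]
      sel <- g == l
      nn <- sum(sel)
      rate <- 100 * mean(labels[sel])
      assessable <- nn >= 2L && length(unique(labels[sel])) == 2L
      if (assessable) {
        est <- .boot_rank_metrics(scores[sel], labels[sel],
                                  K = bootstrap_cfg$K,
                                  alpha = bootstrap_cfg$alpha,
                                  seed = child_seed(bootstrap_cfg$seed,
                                                    100L * match(a, names(groups)) + i))
        rows <- data.frame(
          attribute = a, level = l, n = nn, event_rate_pct = rate,
          assessable = TRUE,
          metric = c("auroc", "auprc"),
          point = c(est$auroc$point, est$auprc$point),
          ci_lo = c(est$auroc$ci_lo, est$auprc$ci_lo),
          ci_hi = c(est$auroc$ci_hi, est$auprc$ci_hi),
          stringsAsFactors = FALSE)
      } else {
        rows <- data.frame(
          attribute = a, level = l, n = nn, event_rate_pct = rate,
          assessable = FALSE, metric = c("auroc", "auprc"),
          point = NA_real_, ci_lo = NA_real_, ci_hi = NA_real_,
          stringsAsFactors = FALSE)
      }
      panels[[length(panels) + 1L]] <- rows
    }
  }
  panels <- do.call(rbind, panels)

  findings <- list()
  for (a in names(groups)) {
    pa <- panels[panels$attribute == a & panels$assessable, , drop = FALSE]
    lv <- unique(pa$level)
    if (length(lv) < 2L) next
    for (i in seq_len(length(lv) - 1L)) for (j in (i + 1L):length(lv)) {
      for (m in c("auroc", "auprc")) {
        ri <- pa[pa$level == lv[i] & pa$metric == m, ]
        rj <- pa[pa$level == lv[j] & pa$metric == m, ]
        gap <- ri$event_rate_pct - rj$event_rate_pct
        overlap <- !(ri$ci_lo > rj$ci_hi || rj$ci_lo > ri$ci_hi)
        scen1 <- abs(gap) <= parity_tol
        scen2 <- (gap > parity_tol && ri$point > rj$point) ||
                 (gap < -parity_tol && ri$point < rj$point)
        if (overlap) {
          verdict <- "no_material_difference"
          why <- "confidence intervals overlap"
        } else if (scen1) {
          verdict <- "parity_violation"
          why <- sprintf("similar event rates (gap %.2f pp) cannot explain the disjoint intervals", gap)
        } else if (scen2) {
          verdict <- "parity_violation"
          why <- "event-rate ordering is converse to the performance ordering"
        } else {
          verdict <- "imbalance_confounded"
          why <- "event rates differ in the direction that explains the performance gap"
        }
        findings[[length(findings) + 1L]] <- data.frame(
          attribute = a, level_a = lv[i], level_b = lv[j], metric = m,
          event_rate_gap_pp = gap, ci_overlap = overlap, verdict = verdict,
          rationale = why, stringsAsFactors = FALSE)
      }
    }
  }
  findings <- if (length(findings)) do.call(rbind, findings) else
    data.frame(attribute = character(), level_a = character(),
               level_b = character(), metric = character(),
               event_rate_gap_pp = numeric(), ci_overlap = logical(),
               verdict = character(), rationale = character(),
               stringsAsFactors = FALSE)
  structure(list(panels = panels, findings = findings,
                 parity_tol = parity_tol),
            class = "parity_assessment")
}

#' Calibration-in-the-large per demographic group
#'
#' For every level of every attribute, compares the mean predicted risk with
#' the observed event rate as a relative difference
#' `(mean predicted - observed) / observed`, and builds a percentile
#' bootstrap interval of the per-resample relative differences (resampling
#' stays within the level; resamples without any observed event are
#' redrawn). A confidence interval containing zero is reported as consistent
#' with calibration. Levels without observed events are flagged not
#' assessable rather than divided by zero.
#'
#' @inheritParams classification_parity
#' @return data frame of class `citl_estimates` with columns `attribute`,
#'   `level`, `n`, `mean_predicted`, `observed_rate`, `rel_diff`, `ci_lo`,
#'   `ci_hi`, `assessable`, `consistent_with_calibration`.
#' @export
calibration_in_the_large <- function(scores, labels, groups,
                                     bootstrap_cfg = bootstrap_config()) {
  check_scores_labels(scores, labels)
  groups <- .normalize_groups(groups, length(scores))
  rows <- list()
  for (a in names(groups)) {
    g <- groups[[a]]
    for (i in seq_along(lv <- sort(unique(g)))) {
      l <- lv[i]
      sel <- g == l
      nn <- sum(sel)
      mp <- mean(scores[sel])
      obs <- mean(labels[sel])
      if (obs == 0) {
        rows[[length(rows) + 1L]] <- data.frame(
          attribute = a, level = l, n = nn, mean_predicted = mp,
          observed_rate = obs, rel_diff = NA_real_, ci_lo = NA_real_,
          ci_hi = NA_real_, assessable = FALSE,
          consistent_with_calibration = NA, stringsAsFactors = FALSE)
        next
      }
      rel <- (mp - obs) / obs
      s <- scores[sel]; y <- labels[sel]
      K <- bootstrap_cfg$K
      reldist <- with_seed(child_seed(bootstrap_cfg$seed,
                                      200L * match(a, names(groups)) + i), {
        out <- numeric(K)
        # matrix resampling in blocks; columns without events are redrawn
        todo <- seq_len(K)
        while (length(todo)) {
          idx <- matrix(sample.int(nn, nn * length(todo), replace = TRUE),
                        nrow = nn)
          ob <- colMeans(matrix(y[idx], nrow = nn))
          pb <- colMeans(matrix(s[idx], nrow = nn))
          ok <- ob > 0
          out[todo[ok]] <- (pb[ok] - ob[ok]) / ob[ok]
          todo <- todo[!ok]
        }
        out
      })
      ci <- quantile(reldist, c(bootstrap_cfg$alpha / 2,
                                1 - bootstrap_cfg$alpha / 2),
                     type = 7, names = FALSE)
      rows[[length(rows) + 1L]] <- data.frame(
        attribute = a, level = l, n = nn, mean_predicted = mp,
        observed_rate = obs, rel_diff = rel, ci_lo = ci[1], ci_hi = ci[2],
        assessable = TRUE,
        consistent_with_calibration = ci[1] <= 0 && ci[2] >= 0,
        stringsAsFactors = FALSE)
    }
  }
  structure(do.call(rbind, rows), class = c("citl_estimates", "data.frame"))
}

#' Charlson comorbidity configuration
#'
#' @param mapping data frame with columns `code`, `factor_id`, `weight`
#'   mapping diagnosis codes to exactly 12 comorbidity factors with integer
#'   weights `>= 1`. The default is the package's synthetic 12-factor table
#'   (weights 1,1,1,1,1,1,2,2,2,3,6,6); real ICD mappings are user-supplied.
#' @param lookback_days observation window before admission (default 730,
#'   i.e. two years).
#' @return object of class `charlson_config`.
#' @export
charlson_config <- function(mapping = default_charlson_model()$mapping,
                            lookback_days = 730L) {
  if (!all(c("code", "factor_id", "weight") %in% names(mapping)))
    config_error("mapping needs columns code, factor_id, weight")
  fac <- unique(mapping[, c("factor_id", "weight")])
  if (anyDuplicated(fac$factor_id))
    config_error("each factor must have a single weight")
  if (nrow(fac) != 12L)
    config_error(sprintf("mapping must define exactly 12 factors (got %d)", nrow(fac)))
  if (any(fac$weight < 1))
    config_error("factor weights must be >= 1")
  if (lookback_days <= 0) config_error("lookback_days must be positive")
  structure(list(mapping = mapping, lookback_days = as.integer(lookback_days)),
            class = "charlson_config")
}

#' Charlson comorbidity score
#'
#' Weighted sum over distinct comorbidity factors with at least one mapped
#' diagnosis code dated within the lookback window before admission; a
#' factor present through multiple codes or dates counts once. Codes absent
#' from the mapping are ignored and counted in the `unmapped` attribute.
#'
#' @param diagnoses data frame with columns `code` and
#'   `days_before_admission` (non-negative).
#' @param config a [charlson_config()].
#' @return non-negative integer score with attribute `unmapped` (count of
#'   ignored codes).
#' @export
charlson_score <- function(diagnoses, config = charlson_config()) {
  if (nrow(diagnoses) == 0L)
    return(structure(0L, unmapped = 0L))
  if (any(diagnoses$days_before_admission < 0))
    schema_error("days_before_admission must be non-negative")
  inwin <- diagnoses[diagnoses$days_before_admission <= config$lookback_days, ,
                     drop = FALSE]
  m <- match(inwin$code, config$mapping$code)
  unmapped <- sum(is.na(m))
  fac <- unique(config$mapping$factor_id[m[!is.na(m)]])
  w <- config$mapping$weight[match(fac, config$mapping$factor_id)]
  structure(as.integer(sum(w)), unmapped = unmapped)
}

#' Charlson scores for every stay of a cohort
#'
#' @param cohort an `icu_cohort` carrying diagnosis data.
#' @param config a [charlson_config()].
#' @return named integer vector of scores, one per stay (0 for stays without
#'   in-window mapped diagnoses), with attribute `unmapped`.
#' @export
charlson_scores <- function(cohort, config = charlson_config()) {
  dx <- data.table::as.data.table(cohort$diagnoses)
  scores <- setNames(integer(nrow(cohort$stays)), cohort$stays$stay_id)
  if (nrow(dx) == 0L) return(structure(scores, unmapped = 0L))
  dx <- dx[dx$days_before_admission >= 0 &
             dx$days_before_admission <= config$lookback_days]
  map <- data.table::as.data.table(config$mapping)
  merged <- merge(dx, map, by = "code")
  unmapped <- nrow(dx) - nrow(merged)
  if (nrow(merged)) {
    merged <- unique(merged[, c("stay_id", "factor_id", "weight")])
    agg <- merged[, list(score = sum(weight)), by = "stay_id"]
    scores[agg$stay_id] <- as.integer(agg$score)
  }
  structure(scores, unmapped = unmapped)
}

#' Comorbidity burden along risk-score percentiles
#'
#' Ranks every stay's risk score on the pooled cohort (percentiles 1..100,
#' shared x-axis across groups) and, for every demographic level, computes
#' the mean Charlson score within a sliding window of +/- 5 percentile
#' points evaluated on the integer grid 1..100. Windows holding fewer than
#' 10 stays are flagged sparse.
#'
#' @param scores risk scores.
#' @param charlson per-stay Charlson scores aligned with `scores`.
#' @param groups as in [classification_parity()].
#' @param window half-width of the percentile window (default 5).
#' @param sparse_n minimum window occupancy below which the point is flagged
#'   (default 10).
#' @return data frame of class `comorbidity_curves` with columns
#'   `attribute`, `level`, `percentile`, `mean_charlson`, `n_window`,
#'   `sparse`.
#' @export
comorbidity_risk_curve <- function(scores, charlson, groups, window = 5L,
                                   sparse_n = 10L) {
  if (length(scores) != length(charlson))
    schema_error("scores and charlson must have equal length")
  groups <- .normalize_groups(groups, length(scores))
  pctl <- pmin(100L, pmax(1L, as.integer(ceiling(
    100 * rank(scores, ties.method = "average") / length(scores)))))
  rows <- list()
  for (a in names(groups)) {
    g <- groups[[a]]
    for (l in sort(unique(g))) {
      sel <- g == l
      cnt <- tabulate(pctl[sel], nbins = 100L)
      tot <- vapply(split(charlson[sel], factor(pctl[sel], levels = 1:100)),
                    sum, numeric(1))
      # sliding-window sums over the percentile grid
      csum_n <- cumsum(c(0, cnt))
      csum_t <- cumsum(c(0, tot))
      lo <- pmax(1L, (1:100) - window)
      hi <- pmin(100L, (1:100) + window)
      nw <- csum_n[hi + 1L] - csum_n[lo]
      tw <- csum_t[hi + 1L] - csum_t[lo]
      rows[[length(rows) + 1L]] <- data.frame(
        attribute = a, level = l, percentile = 1:100,
        mean_charlson = ifelse(nw > 0, tw / nw, NA_real_),
        n_window = as.integer(nw), sparse = nw < sparse_n,
        stringsAsFactors = FALSE)
    }
  }
  structure(do.call(rbind, rows),
            class = c("comorbidity_curves", "data.frame"))
}
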