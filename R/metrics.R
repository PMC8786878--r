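#' Threshold metric configuration
#'
#' @param threshold risk cut-off for the binary prediction; a score exactly
#'   at the threshold predicts the event (default 0.5).
#' @return object of class `metric_config`.
#' @export
metric_config <- function(threshold = 0.5) {
  if (threshold <= 0 || threshold >= 1)
    config_error("threshold must lie strictly inside (0,1)")
  structure(list(threshold = threshold), class = "metric_config")
}

#' Bootstrap configuration
#'
#' @param K number of bootstrap resamples (default 10000).
#' @param alpha two-sided miscoverage level for percentile intervals
#'   (default 0.05).
#' @param seed integer seed for the resampling stream (`NULL` = ambient RNG).
#' @param exhaustive if `TRUE`, enumerate all `n^n` ordered resamples instead
#'   of drawing `K` random ones (only sensible for very small `n`).
#' @return object of class `bootstrap_config`.
#' @export
bootstrap_config <- function(K = 10000L, alpha = 0.05, seed = NULL,
                             exhaustive = FALSE) {
  if (K < 1) config_error("K must be at least 1")
  if (alpha <= 0 || alpha >= 1) config_error("alpha must lie in (0,1)")
  check_seed(seed)
  structure(list(K = as.integer(K), alpha = alpha, seed = seed,
                 exhaustive = isTRUE(exhaustive)),
            class = "bootstrap_config")
}

#' Area under the ROC curve
#'
#' Mann-Whitney formulation: the probability that a uniformly random event
#' stay outranks a uniformly random non-event stay, with ties counted one
#' half (midranks).
#'
#' @param scores risk scores.
#' @param labels 0/1 outcome labels; both classes must be present.
#' @return AUROC in `[0,1]`.
#' @export
auroc <- function(scores, labels) {
  check_scores_labels(scores, labels)
  n1 <- as.numeric(sum(labels == 1))
  n0 <- length(labels) - n1
  if (n1 == 0 || n0 == 0)
    metric_undefined_error("AUROC is undefined when only one class is present")
  r <- rank(scores)
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Area under the precision-recall curve
#'
#' Step-wise average precision: the mean, over event stays ranked by
#' descending score, of the precision at each event's rank. Tied scores are
#' treated as one rank block; every event in the block receives the
#' block-level precision (precision after including the whole block). No
#' trapezoidal interpolation is applied.
#'
#' @inheritParams auroc
#' @return AUPRC in `(0,1]`.
#' @export
auprc <- function(scores, labels) {
  check_scores_labels(scores, labels)
  n_pos <- sum(labels == 1)
  if (n_pos == 0L)
    metric_undefined_error("AUPRC is undefined without any event")
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]
  l <- labels[ord]
  n <- length(s)
  ends <- which(c(s[-n] != s[-1], TRUE))     # last index of each score block
  tp_cum <- cumsum(l)[ends]
  tp_block <- diff(c(0L, tp_cum))
  prec <- tp_cum / ends
  sum(tp_block * prec) / n_pos
}

#' Confusion-matrix metrics at a risk threshold
#'
#' Predictions are `score >= threshold`. Ratios with an empty denominator are
#' returned as `NA` and flagged in the `undefined` column rather than
#' silently coerced to zero.
#'
#' @inheritParams auroc
#' @param config a [metric_config()].
#' @return data frame with columns `metric`
#'   (`accuracy`, `precision_event`, `precision_nonevent`, `recall_event`,
#'   `recall_nonevent`), `value`, `undefined`.
#' @export
threshold_metrics <- function(scores, labels, config = metric_config()) {
  check_scores_labels(scores, labels)
  if (length(unique(labels)) < 2L)
    metric_undefined_error("threshold metrics require both classes")
  pred <- as.integer(scores >= config$threshold)
  tp <- sum(pred == 1 & labels == 1)
  fp <- sum(pred == 1 & labels == 0)
  fn <- sum(pred == 0 & labels == 1)
  tn <- sum(pred == 0 & labels == 0)
  ratio <- function(num, den) if (den == 0L) NA_real_ else num / den
  vals <- c(
    accuracy = (tp + tn) / length(labels),
    precision_event = ratio(tp, tp + fp),
    precision_nonevent = ratio(tn, tn + fn),
    recall_event = ratio(tp, tp + fn),
    recall_nonevent = ratio(tn, tn + fp)
  )
  data.frame(metric = names(vals), value = unname(vals),
             undefined = is.na(vals), row.names = NULL,
             stringsAsFactors = FALSE)
}

# Resolve a metric specification (name or function) to a closure
# scores, labels -> scalar; undefined metrics raise fairicu_metric_undefined.
.resolve_metric <- function(metric, metric_cfg = metric_config()) {
  if (is.function(metric)) return(list(fn = metric, name = "custom"))
  stopifnot(is.character(metric), length(metric) == 1L)
  threshold_one <- function(which) {
    force(which)
    function(s, l) {
      tm <- threshold_metrics(s, l, metric_cfg)
      v <- tm$value[tm$metric == which]
      if (is.na(v))
        metric_undefined_error(sprintf("%s undefined (empty denominator)", which))
      v
    }
  }
  fn <- switch(metric,
    auroc = auroc,
    auprc = auprc,
    accuracy = threshold_one("accuracy"),
    precision_event = threshold_one("precision_event"),
    precision_nonevent = threshold_one("precision_nonevent"),
    recall_event = threshold_one("recall_event"),
    recall_nonevent = threshold_one("recall_nonevent"),
    config_error(sprintf("unknown metric '%s'", metric))
  )
  list(fn = fn, name = metric)
}

.try_metric <- function(fn, s, l) {
  tryCatch(fn(s, l),
           fairicu_metric_undefined = function(e) NA_real_)
}

#' Percentile bootstrap confidence interval for a metric
#'
#' Resamples (score, label) pairs jointly, n out of n, `K` times, and takes
#' the empirical `alpha/2` and `1 - alpha/2` percentiles of the resample
#' statistics. Resamples on which the metric is undefined (e.g. a
#' single-class draw) are redrawn and the redraw count recorded; in
#' exhaustive mode (all `n^n` ordered resamples) undefined resamples are
#' dropped instead.
#'
#' @inheritParams auroc
#' @param metric metric name (`"auroc"`, `"auprc"`, `"accuracy"`,
#'   `"precision_event"`, `"precision_nonevent"`, `"recall_event"`,
#'   `"recall_nonevent"`) or a function `(scores, labels) -> scalar`.
#' @param config a [bootstrap_config()].
#' @param metric_cfg a [metric_config()] (threshold for threshold metrics).
#' @return object of class `metric_estimate`: list with `name`, `point`,
#'   `ci_lo`, `ci_hi`, `K`, `alpha`, `n_redraws`, `degenerate` (flag set in
#'   the pathological case where the point estimate falls outside the
#'   percentile interval).
#' @export
bootstrap_ci <- function(metric, scores, labels,
                         config = bootstrap_config(),
                         metric_cfg = metric_config()) {
  m <- .resolve_metric(metric, metric_cfg)
  point <- m$fn(scores, labels)      # undefined on the full sample propagates
  n <- length(scores)
  n_redraws <- 0L
  if (config$exhaustive) {
    if (n^n > 2e5)
      config_error("exhaustive bootstrap enumeration is limited to n^n <= 2e5")
    grid <- as.matrix(expand.grid(rep(list(seq_len(n)), n)))
    stats <- apply(grid, 1L, function(idx)
      .try_metric(m$fn, scores[idx], labels[idx]))
    n_redraws <- sum(is.na(stats))
    stats <- stats[!is.na(stats)]
    K_used <- length(stats)
  } else {
    stats <- with_seed(config$seed, {
      vapply(seq_len(config$K), function(k) {
        for (attempt in seq_len(1000L)) {
          idx <- sample.int(n, n, replace = TRUE)
          v <- .try_metric(m$fn, scores[idx], labels[idx])
          if (!is.na(v)) return(v)
          n_redraws <<- n_redraws + 1L
        }
        metric_undefined_error("metric undefined on 1000 consecutive resamples")
      }, numeric(1))
    })
    K_used <- config$K
  }
  ci <- quantile(stats, c(config$alpha / 2, 1 - config$alpha / 2),
                 type = 7, names = FALSE)
  structure(list(name = m$name, point = point, ci_lo = ci[1], ci_hi = ci[2],
                 K = K_used, alpha = config$alpha, n_redraws = n_redraws,
                 degenerate = point < ci[1] || point > ci[2]),
            class = "metric_estimate")
}

#' @export
print.metric_estimate <- function(x, ...) {
  cat(sprintf("%s: %.3f (%.3f, %.3f)  [K=%d, alpha=%.2f]\n",
              x$name, x$point, x$ci_lo, x$ci_hi, x$K, x$alpha))
  invisible(x)
}

# Joint bootstrap of AUROC and AUPRC sharing one resampling stream: one
# ordering per resample serves both metrics. Single-class resamples are
# redrawn. Used by the per-group fairness panels where per-metric calls
# would double the sorting cost.
.boot_rank_metrics <- function(scores, labels, K, alpha, seed = NULL) {
  n <- length(scores)
  point_roc <- auroc(scores, labels)
  point_pr <- auprc(scores, labels)
  res <- with_seed(seed, {
    roc <- numeric(K); pr <- numeric(K)
    for (k in seq_len(K)) {
      repeat {
        idx <- sample.int(n, n, replace = TRUE)
        l <- labels[idx]
        n1 <- as.numeric(sum(l))
        if (n1 > 0 && n1 < n) break
      }
      s <- scores[idx]
      ord <- order(s, decreasing = TRUE)   # one sort serves both metrics
      ss <- s[ord]; ll <- l[ord]
      ends <- which(c(ss[-n] != ss[-1], TRUE))
      tp_cum <- cumsum(ll)[ends]
      tp_block <- diff(c(0L, tp_cum))
      pr[k] <- sum(tp_block * (tp_cum / ends)) / n1
      # AUROC from the same descending-order block structure: positives in a
      # tied block beat all negatives below it and tie half the block's own
      block_n <- diff(c(0L, ends))
      neg_below <- (n - ends) - (n1 - tp_cum)
      wins <- sum(tp_block * (neg_below + (block_n - tp_block) / 2))
      roc[k] <- wins / (n1 * (n - n1))
    }
    list(roc = roc, pr = pr)
  })
  qs <- c(alpha / 2, 1 - alpha / 2)
  ci_roc <- quantile(res$roc, qs, type = 7, names = FALSE)
  ci_pr <- quantile(res$pr, qs, type = 7, names = FALSE)
  list(
    auroc = structure(list(name = "auroc", point = point_roc,
                           ci_lo = ci_roc[1], ci_hi = ci_roc[2], K = K,
                           alpha = alpha, n_redraws = 0L,
                           degenerate = point_roc < ci_roc[1] || point_roc > ci_roc[2]),
                      class = "metric_estimate"),
    auprc = structure(list(name = "auprc", point = point_pr,
                           ci_lo = ci_pr[1], ci_hi = ci_pr[2], K = K,
                           alpha = alpha, n_redraws = 0L,
                           degenerate = point_pr < ci_pr[1] || point_pr > ci_pr[2]),
                      class = "metric_estimate")
  )
}
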