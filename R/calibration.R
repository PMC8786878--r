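#' Calibration assessment configuration
#'
#' @param n_bins number of risk groups (default 10).
#' @param exponent exponent of the quantile transform `f(q) = q^exponent`;
#'   the default 1/5 concentrates bin resolution in the sparse high-risk
#'   tail of a skewed score distribution. The exponent should be adapted to
#'   the skew of the data at hand; 1 recovers equal-count quantile groups.
#' @param lowess_span LOWESS smoother span (default 0.5).
#' @param alpha two-sided level for the Wilson score intervals (default 0.05).
#' @return object of class `calibration_config`.
#' @export
calibration_config <- function(n_bins = 10L, exponent = 1 / 5,
                               lowess_span = 0.5, alpha = 0.05) {
  if (n_bins < 1) config_error("n_bins must be at least 1")
  if (exponent <= 0) config_error("exponent must be positive")
  if (lowess_span <= 0 || lowess_span > 1)
    config_error("lowess_span must lie in (0,1]")
  if (alpha <= 0 || alpha >= 1) config_error("alpha must lie in (0,1)")
  structure(list(n_bins = as.integer(n_bins), exponent = exponent,
                 lowess_span = lowess_span, alpha = alpha),
            class = "calibration_config")
}

#' Exponential-quantile risk group edges
#'
#' Interior cut points are the empirical quantiles of the scores at the
#' transformed levels `(i/n_bins)^exponent`, `i = 1..n_bins-1` (linear
#' interpolation between order statistics, the common type-7 rule); the
#' outer edges are the score minimum and maximum. Bins are half-open
#' `[lo, hi)` with the last bin closed. Duplicate cut points on heavily tied
#' scores are tolerated here and resolved by leftward bin merging in
#' [validation_curve()].
#'
#' @param scores non-empty numeric vector of risk scores.
#' @param config a [calibration_config()].
#' @return numeric vector of `n_bins + 1` ordered edges.
#' @export
exponential_quantile_edges <- function(scores, config = calibration_config()) {
  if (!length(scores)) config_error("scores must be non-empty")
  nb <- config$n_bins
  if (nb == 1L) return(range(scores))
  levels <- (seq_len(nb - 1L) / nb)^config$exponent
  interior <- quantile(scores, probs = levels, type = 7, names = FALSE)
  c(min(scores), interior, max(scores))
}

#' Wilson score interval for a binomial proportion
#'
#' Closed-form Wilson score interval; bounds always lie in `[0,1]` and the
#' interval always contains `k/n`. Vectorized over `k` and `n`.
#'
#' @param k number of successes, `0 <= k <= n`.
#' @param n number of trials, `n >= 1`.
#' @param alpha two-sided miscoverage level (default 0.05).
#' @return list with numeric vectors `lo` and `hi`.
#' @export
wilson_interval <- function(k, n, alpha = 0.05) {
  if (any(n < 1)) fairicu_stop("Wilson interval undefined for n = 0",
                               "fairicu_undefined_interval")
  if (any(k < 0 | k > n)) config_error("k must satisfy 0 <= k <= n")
  z <- qnorm(1 - alpha / 2)
  p <- k / n
  denom <- 1 + z^2 / n
  center <- (p + z^2 / (2 * n)) / denom
  half <- (z / denom) * sqrt(p * (1 - p) / n + z^2 / (4 * n^2))
  list(lo = pmax(0, center - half), hi = pmin(1, center + half))
}

#' LOWESS smoother (tricube local linear regression)
#'
#' Locally weighted linear regression with the tricube kernel over the
#' `ceiling(span * n)` nearest neighbours of each evaluation point, zero
#' robustness iterations, evaluated at the sorted unique `x` values. For
#' large inputs (more than `max_eval` unique values) the fit is evaluated
#' exactly at `max_eval` quantile-spaced anchor points and linearly
#' interpolated in between, which is exact for locally linear signals.
#'
#' @param x,y paired numeric vectors, at least 3 points.
#' @param span fraction of points in each local neighbourhood (default 0.5).
#' @param max_eval maximum number of exact local fits (default 1000).
#' @return data frame with columns `x` (sorted unique input values) and
#'   `y_smooth`.
#' @export
lowess_curve <- function(x, y, span = 0.5, max_eval = 1000L) {
  if (length(x) != length(y)) schema_error("x and y must have equal length")
  if (length(x) < 3L) config_error("lowess_curve requires at least 3 points")
  grid <- sort(unique(x))
  if (length(grid) == 1L)
    return(data.frame(x = grid, y_smooth = mean(y)))
  n <- length(x)
  k <- max(2L, as.integer(ceiling(span * n)))

  fit_at <- function(x0) {
    d <- abs(x - x0)
    h <- sort(d, partial = k)[k]
    if (h == 0) return(mean(y[d == 0]))
    w <- (1 - pmin(d / h, 1)^3)^3
    sw <- sum(w)
    xw <- sum(w * x) / sw
    sxx <- sum(w * (x - xw)^2)
    if (length(unique(x[w > 0])) < 2L || sxx <= .Machine$double.eps * sw)
      return(sum(w * y) / sw)
    b <- sum(w * (x - xw) * (y - mean(y))) / sxx
    yw <- sum(w * y) / sw
    yw + b * (x0 - xw)
  }

  if (length(grid) <= max_eval) {
    ys <- vapply(grid, fit_at, numeric(1))
  } else {
    anchors <- unique(quantile(grid, probs = seq(0, 1, length.out = max_eval),
                               type = 7, names = FALSE))
    ya <- vapply(anchors, fit_at, numeric(1))
    ys <- stats::approx(anchors, ya, xout = grid, rule = 2)$y
  }
  data.frame(x = grid, y_smooth = ys)
}

#' Validation curve (calibration plot data)
#'
#' Partitions the scores into exponential-quantile risk groups and computes,
#' per group, the count, mean predicted risk, observed event proportion and
#' its Wilson score interval. Empty groups arising from duplicate cut points
#' are merged leftward (merge count recorded), preserving the partition of
#' the sample. A LOWESS smooth of the raw (score, label) pairs and per-class
#' score histograms (log-scale display intent) are attached.
#'
#' @inheritParams auroc
#' @param config a [calibration_config()].
#' @param threshold decision-threshold marker carried in the output
#'   (default 0.5).
#' @return object of class `validation_curve`: list with `bins` (data frame:
#'   `bin`, `lower`, `upper`, `n`, `mean_predicted`, `observed`,
#'   `wilson_lo`, `wilson_hi`), `lowess` (data frame `x`, `y_smooth`),
#'   `histogram` (data frame: `bin_lo`, `bin_hi`, `count_event`,
#'   `count_nonevent`), `threshold`, `n`, `n_merged`.
#' @export
validation_curve <- function(scores, labels, config = calibration_config(),
                             threshold = 0.5) {
  check_scores_labels(scores, labels)
  if (length(unique(labels)) < 2L)
    metric_undefined_error("validation_curve requires both classes")
  edges <- exponential_quantile_edges(scores, config)
  if (min(scores) == max(scores)) {
    bin_idx <- rep(1L, length(scores))
  } else {
    bin_idx <- findInterval(scores, edges, rightmost.closed = TRUE,
                            all.inside = TRUE)
  }
  present <- sort(unique(bin_idx))
  n_merged <- (length(edges) - 1L) - length(present)
  bins <- do.call(rbind, lapply(seq_along(present), function(j) {
    # leftward merge: bins between the previous occupied bin and this one
    # collapse into this row's [lower, upper) range
    b <- present[j]
    lower <- if (j == 1L) edges[1] else edges[present[j - 1L] + 1L]
    sel <- bin_idx == b
    k <- sum(labels[sel])
    nn <- sum(sel)
    wi <- wilson_interval(k, nn, config$alpha)
    data.frame(bin = j, lower = lower, upper = edges[b + 1L], n = nn,
               mean_predicted = mean(scores[sel]), observed = k / nn,
               wilson_lo = wi$lo, wilson_hi = wi$hi,
               stringsAsFactors = FALSE)
  }))
  lw <- lowess_curve(scores, labels, span = config$lowess_span)
  breaks <- seq(0, 1, by = 0.05)
  if (min(scores) < 0 || max(scores) > 1) breaks <- seq(min(scores), max(scores), length.out = 21)
  h1 <- graphics::hist(scores[labels == 1], breaks = breaks, plot = FALSE)
  h0 <- graphics::hist(scores[labels == 0], breaks = breaks, plot = FALSE)
  hist_df <- data.frame(bin_lo = head(breaks, -1), bin_hi = tail(breaks, -1),
                        count_event = h1$counts, count_nonevent = h0$counts)
  structure(list(bins = bins, lowess = lw, histogram = hist_df,
                 threshold = threshold, n = length(scores),
                 n_merged = n_merged),
            class = "validation_curve")
}

#' @export
print.validation_curve <- function(x, ...) {
  cat(sprintf("<validation_curve> %d stays in %d risk groups (%d merged)\n",
              x$n, nrow(x$bins), x$n_merged))
  print(x$bins, digits = 3)
  invisible(x)
}
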