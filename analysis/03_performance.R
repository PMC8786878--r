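#!/usr/bin/env Rscript
# Task B, performance evaluation of the audited risk model (the generator's
# emitted scores stand in for an externally trained predictor): bootstrap
# discrimination metrics and the calibration validation curve on the
# external test cohort. Cohorts are regenerated from the stored
# configurations, which reproduces them exactly (latent risks are never
# written to disk).

suppressPackageStartupMessages(library(fairicu))

dir.create("results/tables", recursive = TRUE, showWarnings = FALSE)
cfg <- read_generator_config("results/cohorts/starr_config.yml")
co <- apply_exclusions(generate_cohort(cfg))
preds <- emit_predictions(co, cfg)
scores <- preds$score[match(co$stays$stay_id, preds$stay_id)]
labels <- co$stays$label

message(sprintf("Audited cohort: %d stays, event rate %.2f%%",
                nrow(co$stays), 100 * mean(labels)))

boot <- bootstrap_config(K = 1000L, seed = 11L)
metrics <- do.call(rbind, lapply(
  c("auroc", "auprc", "accuracy", "precision_event", "precision_nonevent",
    "recall_event", "recall_nonevent"),
  function(m) {
    est <- tryCatch(bootstrap_ci(m, scores, labels, boot),
                    fairicu_metric_undefined = function(e) NULL)
    if (is.null(est))
      return(data.frame(metric = m, point = NA, ci_lo = NA, ci_hi = NA))
    message(sprintf("  %-18s %.3f (%.3f, %.3f)", m, est$point, est$ci_lo,
                    est$ci_hi))
    data.frame(metric = m, point = est$point, ci_lo = est$ci_lo,
               ci_hi = est$ci_hi)
  }))
write.table(metrics, "results/tables/performance_metrics.tsv", sep = "\t",
            row.names = FALSE, quote = FALSE)

vc <- validation_curve(scores, labels)
write.table(vc$bins, "results/tables/risk_bins.tsv", sep = "\t",
            row.names = FALSE, quote = FALSE)
write.table(vc$lowess, "results/tables/calibration_lowess.tsv", sep = "\t",
            row.names = FALSE, quote = FALSE)
write.table(vc$histogram, "results/tables/score_histogram.tsv", sep = "\t",
            row.names = FALSE, quote = FALSE)
contain <- sum(vc$bins$wilson_lo <= vc$bins$mean_predicted &
                 vc$bins$mean_predicted <= vc$bins$wilson_hi)
message(sprintf(
  "Calibration: %d of %d risk-group Wilson intervals cover the mean predicted risk.",
  contain, nrow(vc$bins)))
message("Performance tables written under results/tables")
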