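#!/usr/bin/env Rscript
# Task A, descriptive cohort screening: applies the benchmark exclusion
# rules, then tabulates demographics/outcome and per-variable missingness
# for both cohorts. Run analysis/01_simulate_cohorts.R first.

suppressPackageStartupMessages(library(fairicu))

dir.create("results/tables", recursive = TRUE, showWarnings = FALSE)

for (name in c("mimic", "starr")) {
  co <- read_cohort(file.path("results/cohorts", name))
  kept <- apply_exclusions(co)
  excl <- attr(kept, "exclusions")
  message(sprintf(
    "%s: %d of %d stays eligible (excluded: %d age, %d multi-stay, %d LOS, %d no observations)",
    name, excl["kept"], nrow(co$stays), excl["age"], excl["multi_stay"],
    excl["los"], excl["no_observations"]))

  demo <- demographics_table(kept)
  miss <- missingness_profile(kept)
  write.table(demo, file.path("results/tables", paste0(name, "_demographics.tsv")),
              sep = "\t", row.names = FALSE, quote = FALSE)
  write.table(miss, file.path("results/tables", paste0(name, "_missingness.tsv")),
              sep = "\t", row.names = FALSE, quote = FALSE)

  tot <- demo[demo$attribute == "total", ]
  message(sprintf("  %d patients, %d stays, event rate %.2f%%",
                  tot$patients, tot$stays, tot$event_rate_pct))
  worst <- miss[which.max(miss$pct_none), ]
  message(sprintf("  sparsest variable: %s (%.1f%% of stays without any data)",
                  worst$variable_id, worst$pct_none))
}
message("Demographics and missingness tables written under results/tables")
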