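#!/usr/bin/env Rscript
# Simulates the two synthetic study cohorts: a MIMIC-like development cohort
# and a STARR-like external cohort (smaller, different demographic mix,
# lower mortality, diagnosis histories available). Writes the cohorts and
# their generator configurations under results/cohorts/.

suppressPackageStartupMessages(library(fairicu))

seed <- as.integer(Sys.getenv("FAIRICU_SEED", "1"))
out_dir <- "results/cohorts"

cfg_mimic <- mimic_generator_config(n_stays = 12000L, seed = seed)
cfg_starr <- starr_generator_config(n_stays = 5000L, seed = seed + 1L)

message("Generating MIMIC-like development cohort (n = 12,000) ...")
mimic <- generate_cohort(cfg_mimic)
print(mimic)

message("Generating STARR-like external cohort (n = 5,000) ...")
starr <- generate_cohort(cfg_starr)
print(starr)

write_cohort(mimic, file.path(out_dir, "mimic"))
write_cohort(starr, file.path(out_dir, "starr"))
write_generator_config(cfg_mimic, file.path(out_dir, "mimic_config.yml"))
write_generator_config(cfg_starr, file.path(out_dir, "starr_config.yml"))

message(sprintf(
  "Pooled in-hospital mortality: %.2f%% (development) vs %.2f%% (external).",
  100 * mean(mimic$stays$label), 100 * mean(starr$stays$label)))
message("Cohort files written under ", out_dir)
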