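# Shared fixtures, all built in code at test time.

# Minimal stays row; override fields as needed.
make_stay <- function(stay_id, patient_id = stay_id, admission_id = stay_id,
                      age = 60, gender = "Female", ethnicity = "White",
                      insurance = "Medicare", label = 0L, los_hours = 100) {
  data.frame(stay_id = stay_id, patient_id = patient_id,
             admission_id = admission_id, age = age, gender = gender,
             ethnicity = ethnicity, insurance = insurance, label = label,
             los_hours = los_hours, stringsAsFactors = FALSE)
}

one_obs <- function(stay_id, variable_id = "heart_rate", hour = 0L,
                    value = 80) {
  data.frame(stay_id = stay_id, variable_id = variable_id, hour = hour,
             value = value, stringsAsFactors = FALSE)
}

# Six-stay toy cohort exercising all four exclusion rules:
# S1 under-age; S2/S3 share one admission; S4 short stay; S5 no
# observations; S6 eligible.
toy_exclusion_cohort <- function() {
  stays <- rbind(
    make_stay("S1", age = 16),
    make_stay("S2", patient_id = "P2", admission_id = "A23"),
    make_stay("S3", patient_id = "P2", admission_id = "A23"),
    make_stay("S4", los_hours = 40),
    make_stay("S5"),
    make_stay("S6")
  )
  obs <- do.call(rbind, lapply(c("S1", "S2", "S3", "S4", "S6"), one_obs))
  icu_cohort(stays, obs)
}

# Fast generator config: no observations, no diagnoses, demographics only.
fast_config <- function(n_stays, seed = 1L, ...) {
  generator_config(n_stays = n_stays, seed = seed,
                   missingness = no_observation_profile(),
                   multi_stay_fraction = 0, ...)
}

# Skewed but calibrated score/label pairs: scores from a logit-normal
# distribution, labels Bernoulli(score).
calibrated_sample <- function(n, seed, mu = -2, sd = 1.5) {
  withr::with_seed(seed, {
    s <- plogis(rnorm(n, mu, sd))
    list(scores = s, labels = rbinom(n, 1L, s))
  })
}

# Brute-force AUROC: average over all positive-negative pairs with ties = 1/2.
pair_count_auroc <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  tot <- 0
  for (p in pos) for (q in neg)
    tot <- tot + if (p > q) 1 else if (p == q) 0.5 else 0
  tot / (length(pos) * length(neg))
}

# Rank-enumeration AUPRC for tie-free scores: precision at each positive's
# rank, averaged over positives.
rank_enum_auprc <- function(scores, labels) {
  ord <- order(scores, decreasing = TRUE)
  l <- labels[ord]
  ranks_pos <- which(l == 1)
  mean(vapply(ranks_pos, function(r) sum(l[1:r]) / r, numeric(1)))
}
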