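boot_fast <- function(K = 300, seed = 1) bootstrap_config(K = K, seed = seed)

test_that("identical groups show no material difference", {
  dat <- calibrated_sample(4000, seed = 1)
  groups <- rep(c("Female", "Male"), each = 2000)
  # same generating distribution in both halves
  pa <- classification_parity(dat$scores, dat$labels,
                              data.frame(gender = groups), boot_fast())
  expect_true(all(pa$findings$verdict == "no_material_difference"))
  expect_equal(sum(pa$panels$n[pa$panels$metric == "auroc"]), 4000)
})

test_that("equal event rates with noise-degraded scores flag a scenario-1 violation", {
  cfg <- fast_config(
    20000, seed = 21, risk_heterogeneity_sd = 1.8,
    intercept = qlogis(0.084),
    marginals = list(
      gender = c(Female = 0.5, Male = 0.5),
      ethnicity = c(Asian = 0, Black = 0, Hispanic = 0, White = 1, Other = 0),
      insurance = c(Medicare = 0, Medicaid = 0.5, Private = 0.5, Other = 0),
      age_band = c(`18-29` = 0.2, `30-49` = 0.2, `50-69` = 0.2,
                   `70-89` = 0.2, `90+` = 0.2)),
    noise_degradation = list(insurance = c(Medicaid = 1.0)))
  co <- generate_cohort(cfg)
  p <- emit_predictions(co, cfg)
  pa <- classification_parity(p$score, co$stays$label,
                              data.frame(insurance = co$stays$insurance),
                              boot_fast(K = 400, seed = 2))
  f <- pa$findings[pa$findings$metric == "auroc", ]
  expect_equal(f$verdict, "parity_violation")
  expect_lte(abs(f$event_rate_gap_pp), 1.0)
})

test_that("converse event-rate/performance ordering flags a scenario-2 violation", {
  # group A: higher event rate AND higher performance; disjoint CIs
  a <- calibrated_sample(8000, seed = 31, mu = -1.6, sd = 2.0)
  b <- withr::with_seed(32, {
    s <- plogis(rnorm(8000, -2.4, 1.2))
    noisy <- plogis(qlogis(s) + rnorm(8000, 0, 1.6))
    list(scores = noisy, labels = rbinom(8000, 1, s))
  })
  scores <- c(a$scores, b$scores)
  labels <- c(a$labels, b$labels)
  groups <- rep(c("Medicare", "Private"), each = 8000)
  stopifnot(mean(a$labels) > mean(b$labels) + 0.011)
  pa <- classification_parity(scores, labels, data.frame(insurance = groups),
                              boot_fast(K = 400, seed = 3))
  f <- pa$findings[pa$findings$metric == "auroc", ]
  expect_equal(f$verdict, "parity_violation")
  expect_match(f$rationale, "converse")
})

test_that("parity verdicts are invariant under relabeling of the pair", {
  dat <- calibrated_sample(3000, seed = 41)
  g <- rep(c("Female", "Male"), length.out = 3000)
  p1 <- classification_parity(dat$scores, dat$labels, data.frame(gender = g),
                              boot_fast(seed = 7))
  g2 <- ifelse(g == "Female", "Male", "Female")
  p2 <- classification_parity(dat$scores, dat$labels, data.frame(gender = g2),
                              boot_fast(seed = 7))
  expect_equal(p1$findings$verdict, p2$findings$verdict)
})

test_that("degenerate levels are reported as not assessable", {
  scores <- c(0.2, 0.8, 0.4, 0.9)
  labels <- c(0, 1, 0, 1)
  g <- c("Female", "Female", "Male", "Male")
  labels[g == "Male"] <- 0          # single-class level
  pa <- classification_parity(scores, labels, data.frame(gender = g),
                              boot_fast(K = 20))
  male <- pa$panels[pa$panels$level == "Male", ]
  expect_false(any(male$assessable))
  expect_true(all(is.na(male$point)))
  expect_equal(nrow(pa$findings), 0L)
})

test_that("calibration-in-the-large: calibrated data is consistent with zero", {
  dat <- calibrated_sample(20000, seed = 51)
  g <- rep(c("Female", "Male"), each = 10000)
  citl <- calibration_in_the_large(dat$scores, dat$labels,
                                   data.frame(gender = g), boot_fast())
  expect_true(all(citl$consistent_with_calibration))
})

test_that("uniformly halved scores give a relative difference near -0.5", {
  dat <- calibrated_sample(30000, seed = 61)
  g <- rep(c("Female", "Male"), each = 15000)
  citl <- calibration_in_the_large(dat$scores / 2, dat$labels,
                                   data.frame(gender = g), boot_fast())
  expect_true(all(abs(citl$rel_diff + 0.5) < 0.05))
  expect_true(all(!citl$consistent_with_calibration))
})

test_that("a level without observed events is flagged, not divided", {
  scores <- runif(20, 0, 0.2)
  labels <- rep(0L, 20)
  labels[1:3] <- 1L
  g <- rep(c("Female", "Male"), each = 10)
  labels[g == "Male"] <- 0L
  citl <- calibration_in_the_large(scores, labels, data.frame(gender = g),
                                   boot_fast(K = 20))
  male <- citl[citl$level == "Male", ]
  expect_false(male$assessable)
  expect_true(is.na(male$rel_diff))
})

test_that("n-weighted pooling of group CITL equals the whole-cohort value", {
  dat <- calibrated_sample(5000, seed = 71)
  g <- sample(c("Medicare", "Medicaid", "Private"), 5000, replace = TRUE)
  citl <- calibration_in_the_large(dat$scores, dat$labels,
                                   data.frame(insurance = g), boot_fast(K = 10))
  # pool numerators and denominators with stay weights
  num <- sum(citl$n * (citl$mean_predicted - citl$observed_rate))
  den <- sum(citl$n * citl$observed_rate)
  whole <- (mean(dat$scores) - mean(dat$labels)) / mean(dat$labels)
  expect_equal(num / den, whole, tolerance = 1e-9)
})

test_that("Charlson score: empty, dedup, and lookback-window hand sums", {
  cfg <- charlson_config()
  expect_equal(as.integer(charlson_score(data.frame(
    code = character(), days_before_admission = integer()), cfg)), 0L)

  # one factor (weight 2) observed twice counts once
  dx <- data.frame(code = c("F07a", "F07b"),
                   days_before_admission = c(700L, 10L))
  expect_equal(as.integer(charlson_score(dx, cfg)), 2L)

  # weights (1,1,2,6); the weight-1 factor at 800 days is outside the window
  dx2 <- data.frame(code = c("F01a", "F02a", "F07a", "F11a"),
                    days_before_admission = c(800L, 100L, 10L, 400L))
  expect_equal(as.integer(charlson_score(dx2, cfg)), 1L + 2L + 6L)
})

test_that("unmapped codes are counted, never fatal; monotone in factors", {
  cfg <- charlson_config()
  dx <- data.frame(code = c("ICD_UNKNOWN", "F01a"),
                   days_before_admission = c(5L, 5L))
  sc <- charlson_score(dx, cfg)
  expect_equal(as.integer(sc), 1L)
  expect_equal(attr(sc, "unmapped"), 1L)

  # adding an in-window factor never decreases the score
  base <- data.frame(code = "F01a", days_before_admission = 5L)
  for (extra in c("F03a", "F10b", "F12a")) {
    more <- rbind(base, data.frame(code = extra, days_before_admission = 50L))
    expect_gte(as.integer(charlson_score(more, cfg)),
               as.integer(charlson_score(base, cfg)))
  }
})

test_that("cohort-level Charlson scores match the per-stay operation", {
  cfg <- starr_generator_config(n_stays = 300, seed = 81,
                                missingness = no_observation_profile())
  co <- generate_cohort(cfg)
  ch <- charlson_scores(co)
  for (sid in co$stays$stay_id[1:20]) {
    dx <- co$diagnoses[co$diagnoses$stay_id == sid, ]
    expect_equal(unname(ch[sid]), as.integer(charlson_score(dx)))
  }
})

test_that("comorbidity curves: constant burden gives flat curves", {
  withr::with_seed(91, scores <- runif(2000))
  g <- rep(c("Female", "Male"), each = 1000)
  cc <- comorbidity_risk_curve(scores, rep(3L, 2000), data.frame(gender = g))
  expect_true(all(cc$mean_charlson[!is.na(cc$mean_charlson)] == 3))
  expect_equal(sort(unique(cc$percentile)), 1:100)
})

test_that("burden correlated with risk yields a rising pooled curve", {
  withr::with_seed(92, {
    eta <- rnorm(50000, -2, 1.5)
    scores <- plogis(eta)
    charl <- rpois(50000, lambda = exp(0.8 + 0.4 * eta))
  })
  cc <- comorbidity_risk_curve(scores, charl,
                               data.frame(all = rep("pooled", 50000)))
  rho <- cor(cc$percentile, cc$mean_charlson, method = "spearman")
  expect_gt(rho, 0.9)
})

test_that("sparse percentile windows are flagged", {
  withr::with_seed(93, scores <- runif(60))
  cc <- comorbidity_risk_curve(scores, rep(1L, 60),
                               data.frame(all = rep("a", 60)))
  expect_true(any(cc$sparse))
})
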