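fast_fw_config <- function(seed = 1, K = 150, ...) {
  framework_config(seed = seed,
                   bootstrap = bootstrap_config(K = K, seed = seed), ...)
}

test_that("baseline predictor refits are identical and coefficients are exposed", {
  co <- generate_cohort(mimic_generator_config(n_stays = 1500, seed = 1))
  m1 <- fit_baseline_predictor(co, seed = 3)
  m2 <- fit_baseline_predictor(co, seed = 3)
  expect_identical(m1$coefficients, m2$coefficients)
  expect_true("(Intercept)" %in% names(m1$coefficients))
  expect_error(fit_baseline_predictor(
    icu_cohort(make_stay("S1", label = 0L))), class = "fairicu_fit_error")
})

test_that("null demographic effects are recovered as near-zero coefficients", {
  cfg <- fast_config(50000, seed = 5, intercept = qlogis(0.13))
  co <- generate_cohort(cfg)
  m <- fit_baseline_predictor(co)
  X <- fairicu:::.predictor_features(co)
  X$label <- co$stays$label
  fit <- suppressWarnings(glm(label ~ gender + ethnicity + insurance + age_band,
                              data = X, family = binomial()))
  cf <- summary(fit)$coefficients
  demo_rows <- setdiff(rownames(cf), "(Intercept)")
  expect_true(all(abs(cf[demo_rows, "Estimate"]) <
                    3 * cf[demo_rows, "Std. Error"]))
})

test_that("known logistic offsets are recovered within 3 SE", {
  cfg <- fast_config(
    50000, seed = 6, intercept = qlogis(0.10),
    offsets = list(gender = c(Female = 0.4),
                   insurance = c(Medicaid = -0.6)))
  co <- generate_cohort(cfg)
  X <- fairicu:::.predictor_features(co)
  X$label <- co$stays$label
  fit <- suppressWarnings(glm(label ~ gender + ethnicity + insurance + age_band,
                              data = X, family = binomial()))
  cf <- summary(fit)$coefficients
  # treatment contrasts: Male vs Female = -0.4, Medicaid vs Medicare = -0.6
  expect_lt(abs(cf["genderMale", "Estimate"] + 0.4),
            3 * cf["genderMale", "Std. Error"])
  expect_lt(abs(cf["insuranceMedicaid", "Estimate"] + 0.6),
            3 * cf["insuranceMedicaid", "Std. Error"])
})

test_that("stage reports are deterministic and comorbidity blocks conditional", {
  test_co <- generate_cohort(starr_generator_config(n_stays = 900, seed = 8))
  train_co <- generate_cohort(starr_generator_config(n_stays = 1200, seed = 9))
  cfg <- fast_fw_config(seed = 2, K = 100)
  r1 <- run_stage("internal", test_co, train = train_co, config = cfg)
  r2 <- run_stage("internal", test_co, train = train_co, config = cfg)
  r1$meta$timestamp <- r2$meta$timestamp <- NULL
  expect_identical(r1, r2)
  expect_true(r1$has_comorbidity_block)

  no_dx <- generate_cohort(mimic_generator_config(n_stays = 900, seed = 8))
  r3 <- run_stage("internal", no_dx, train = train_co, config = cfg)
  expect_false(r3$has_comorbidity_block)
  expect_null(r3$comorbidity)
})

test_that("stages 2 and 3 evaluate on the identical test partition", {
  a <- generate_cohort(mimic_generator_config(n_stays = 2500, seed = 10))
  b <- generate_cohort(starr_generator_config(n_stays = 1400, seed = 11))
  rep <- run_framework(a, b, fast_fw_config(seed = 3, K = 80))
  expect_identical(rep$stages$external$test_digest,
                   rep$stages$retrained_internal$test_digest)
  expect_equal(names(rep$stages),
               c("internal", "external", "retrained_internal"))
})

test_that("stage-2 test event rate tracks the external cohort's configured rate", {
  a <- generate_cohort(mimic_generator_config(n_stays = 3000, seed = 12,
                                              missingness = no_observation_profile()))
  bcfg <- starr_generator_config(n_stays = 12000, seed = 13,
                                 missingness = no_observation_profile())
  b <- generate_cohort(bcfg)
  # keep observation-based exclusion from firing on observation-free cohorts
  cfg <- fast_fw_config(seed = 4, K = 40)
  b$observations <- do.call(rbind, lapply(b$stays$stay_id, one_obs))
  a$observations <- do.call(rbind, lapply(a$stays$stay_id, one_obs))
  rep <- run_framework(a, b, cfg)
  rate <- rep$stages$external$event_rate_pct / 100
  se <- sqrt(0.1018 * (1 - 0.1018) / rep$stages$external$n)
  expect_lt(abs(rate - 0.1018), 3 * se)
})

test_that("end-to-end: external miscalibration appears at stage 2 and shrinks at stage 3", {
  # external cohort whose mortality runs above what its demographics imply:
  # a stage-1 model underestimates risk there; retraining recalibrates.
  acfg <- mimic_generator_config(n_stays = 9000, seed = 14,
                                 missingness = no_observation_profile(),
                                 risk_heterogeneity_sd = 0)
  bcfg <- mimic_generator_config(n_stays = 9000, seed = 15,
                                 missingness = no_observation_profile(),
                                 risk_heterogeneity_sd = 0)
  bcfg$outcome$intercept <- bcfg$outcome$intercept + 0.5
  a <- generate_cohort(acfg)
  b <- generate_cohort(bcfg)
  a$observations <- do.call(rbind, lapply(a$stays$stay_id, one_obs))
  b$observations <- do.call(rbind, lapply(b$stays$stay_id, one_obs))
  rep <- run_framework(a, b, fast_fw_config(seed = 5, K = 120))
  citl2 <- rep$stages$external$citl
  citl3 <- rep$stages$retrained_internal$citl
  pooled2 <- sum(citl2$n * (citl2$mean_predicted - citl2$observed_rate)) /
    sum(citl2$n * citl2$observed_rate)
  pooled3 <- sum(citl3$n * (citl3$mean_predicted - citl3$observed_rate)) /
    sum(citl3$n * citl3$observed_rate)
  expect_lt(pooled2, -0.05)                 # systematic underestimation
  expect_lt(abs(pooled3), abs(pooled2))     # retraining reduces |CITL|
})

test_that("reports serialize losslessly and export their delimited tables", {
  test_co <- generate_cohort(starr_generator_config(n_stays = 700, seed = 16))
  train_co <- generate_cohort(starr_generator_config(n_stays = 900, seed = 17))
  r <- run_stage("external", test_co, train = train_co,
                 config = fast_fw_config(seed = 6, K = 50))
  f1 <- withr::local_tempfile(fileext = ".json")
  f2 <- withr::local_tempfile(fileext = ".json")
  write_report(r, f1)
  write_report(read_report(f1), f2)
  expect_identical(readLines(f1), readLines(f2))

  dir <- withr::local_tempdir()
  files <- export_stage_tables(r, dir)
  expect_true(all(file.exists(file.path(
    dir, paste0("external_", c("demographics", "metrics", "risk_bins",
                               "citl", "comorbidity_curves"), ".tsv")))))
})

test_that("the oracle predictor reproduces the generator's emitted scores", {
  cfg <- fast_config(400, seed = 18, risk_heterogeneity_sd = 1.8)
  co <- generate_cohort(cfg)
  p1 <- predict(oracle_predictor(cfg), co)
  p2 <- emit_predictions(co, cfg)
  expect_equal(p1$score, p2$score)
})
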