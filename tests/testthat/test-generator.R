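test_that("identical config and seed give byte-identical cohorts; seeds differ", {
  cfg <- fast_config(500, seed = 42)
  c1 <- generate_cohort(cfg)
  c2 <- generate_cohort(cfg)
  expect_identical(c1, c2)
  c3 <- generate_cohort(fast_config(500, seed = 43))
  expect_false(identical(c1$stays$label, c3$stays$label))
})

test_that("pooled event rate matches the configured intercept", {
  cfg <- fast_config(50000, seed = 7, intercept = qlogis(0.13))
  co <- generate_cohort(cfg)
  rate <- mean(co$stays$label)
  se <- sqrt(0.13 * 0.87 / 50000)
  expect_lt(abs(rate - 0.13), 3 * se)
})

test_that("configured marginals are recovered (chi-square across seeds)", {
  for (seed in 1:10) {
    co <- generate_cohort(fast_config(50000, seed = seed))
    cfg <- fast_config(1)
    for (a in c("gender", "ethnicity", "insurance")) {
      p <- cfg$marginals[[a]]
      obs <- table(factor(co$stays[[a]], levels = names(p)))
      pval <- suppressWarnings(chisq.test(obs, p = p)$p.value)
      expect_gt(pval, 0.001)
    }
  }
})

test_that("ethnicity proportions at the published marginal are recovered", {
  co <- generate_cohort(fast_config(100000, seed = 3))
  target <- c(Asian = 0.024, Black = 0.082, Hispanic = 0.031, White = 0.710,
              Other = 0.152)
  target <- target / sum(target)
  obs <- prop.table(table(co$stays$ethnicity))[names(target)]
  se <- sqrt(target * (1 - target) / 100000)
  expect_true(all(abs(obs - target) < 3 * se))
})

test_that("per-group event rates converge to the logistic model's implied rates", {
  cfg <- mimic_generator_config(n_stays = 100000, seed = 11,
                                missingness = no_observation_profile())
  co <- generate_cohort(cfg)
  implied <- implied_event_rates(cfg)
  expect_equal(implied$overall, 0.1323, tolerance = 1e-6)
  st <- co$stays
  for (k in seq_len(nrow(implied$by_level))) {
    a <- implied$by_level$attribute[k]
    l <- implied$by_level$level[k]
    r <- implied$by_level$rate[k]
    sel <- if (a == "age_band") as.character(age_band(st$age)) == l else st[[a]] == l
    se <- sqrt(r * (1 - r) / sum(sel))
    expect_lt(abs(mean(st$label[sel]) - r), 4 * se)
  }
})

test_that("per-variable absence probability is recovered", {
  cfg <- mimic_generator_config(n_stays = 3000, seed = 5)
  co <- generate_cohort(cfg)
  prof <- missingness_profile(co)
  for (k in seq_len(nrow(cfg$missingness))) {
    p_none <- cfg$missingness$p_none[k]
    got <- prof$pct_none[prof$variable_id == cfg$missingness$variable_id[k]] / 100
    se <- sqrt(max(p_none * (1 - p_none), 1e-4) / 3000)
    expect_lt(abs(got - p_none), 4 * se)
  }
})

test_that("invalid probability vectors raise configuration errors naming the attribute", {
  bad <- fast_config(10)$marginals
  bad$ethnicity <- c(Asian = 0.5, Black = 0.6, Hispanic = 0, White = 0,
                     Other = 0)
  expect_error(generator_config(10, marginals = bad),
               "ethnicity", class = "fairicu_config_error")
  expect_error(generator_config(0), class = "fairicu_config_error")
})

test_that("emitted scores equal true risk when shifts and noise are zero", {
  cfg <- fast_config(200, seed = 9)
  co <- generate_cohort(cfg)
  p <- emit_predictions(co, cfg)
  expect_equal(p$score, co$stays$.true_risk, tolerance = 1e-12)
})

test_that("a negative log-odds shift pulls a group's mean score below its event rate", {
  cfg <- fast_config(
    40000, seed = 13, risk_heterogeneity_sd = 1.8,
    miscalibration_shifts = list(insurance = c(Medicaid = -0.5)))
  co <- generate_cohort(cfg)
  p <- emit_predictions(co, cfg)
  sel <- co$stays$insurance == "Medicaid"
  # analytic direction: plogis(logit(r) - 0.5) < r pointwise
  expect_lt(mean(p$score[sel]), mean(co$stays$label[sel]))
  other <- co$stays$insurance == "Medicare"
  expect_lt(abs(mean(p$score[other]) - mean(co$stays$.true_risk[other])), 0.005)
})

test_that("score noise for one group strictly lowers its AUROC", {
  cfg <- fast_config(
    20000, seed = 17, risk_heterogeneity_sd = 1.8,
    noise_degradation = list(gender = c(Female = 1.0)))
  co <- generate_cohort(cfg)
  p <- emit_predictions(co, cfg)
  f <- co$stays$gender == "Female"
  auc_f <- auroc(p$score[f], co$stays$label[f])
  auc_m <- auroc(p$score[!f], co$stays$label[!f])
  expect_lt(auc_f, auc_m)
})

test_that("cohort files round-trip and never leak the latent risk", {
  cfg <- mimic_generator_config(n_stays = 120, seed = 21,
                                charlson = default_charlson_model())
  co <- generate_cohort(cfg)
  dir <- withr::local_tempdir()
  write_cohort(co, dir)
  stays_file <- readLines(file.path(dir, "stays.tsv"), n = 1)
  expect_false(grepl("true_risk", stays_file))
  back <- read_cohort(dir)
  expect_equal(back$stays$stay_id, co$stays$stay_id)
  expect_equal(back$stays$label, co$stays$label)
  expect_equal(nrow(back$observations), nrow(co$observations))
  expect_equal(nrow(back$diagnoses), nrow(co$diagnoses))
  expect_identical(back$config_digest, "")
  expect_error(emit_predictions(back, cfg),
               class = "fairicu_unsupported_input")
})

test_that("generator configuration round-trips through YAML", {
  cfg <- starr_generator_config(n_stays = 50, seed = 2)
  f <- withr::local_tempfile(fileext = ".yml")
  write_generator_config(cfg, f)
  back <- read_generator_config(f)
  expect_equal(back$marginals, cfg$marginals, tolerance = 1e-12)
  expect_equal(back$outcome$intercept, cfg$outcome$intercept, tolerance = 1e-12)
  expect_equal(back$missingness$p_hour, cfg$missingness$p_hour, tolerance = 1e-12)
  expect_identical(generate_cohort(back)$stays$label,
                   generate_cohort(cfg)$stays$label)
})

test_that("multi-stay patients share demographics across separate admissions", {
  cfg <- generator_config(1000, seed = 31, multi_stay_fraction = 0.3,
                          missingness = no_observation_profile())
  co <- generate_cohort(cfg)
  st <- co$stays
  tab <- table(st$patient_id)
  expect_true(any(tab == 2))
  dup <- names(tab[tab == 2])
  for (p in dup[1:5]) {
    rows <- st[st$patient_id == p, ]
    expect_equal(length(unique(rows$admission_id)), 2L)
    expect_equal(rows$gender[1], rows$gender[2])
    expect_equal(rows$age[1], rows$age[2])
  }
})
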