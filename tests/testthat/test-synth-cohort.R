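test_that("configuration validation rejects invalid settings", {
  expect_error(synth_config(risk_prevalence = c(hypertension = 1.2,
                                                diabetes = .1,
                                                hypercholesterolemia = .1,
                                                obesity = .1, smoking = .1)),
               "prevalences")
  expect_error(synth_config(age_range = c(80, 60)), "age_range")
  expect_error(synth_config(grid_shape = c(0, 10, 10)), "grid_shape")
  expect_error(synth_config(longitudinal_fraction = 1.5), "longitudinal")
})

test_that("identical seed and configuration reproduce the cohort exactly", {
  a <- simulate_cohort(tiny_config())
  b <- simulate_cohort(tiny_config())
  expect_identical(a$records, b$records)
  expect_identical(a$truth, b$truth)
  c <- simulate_cohort(tiny_config(seed = 43))
  expect_false(identical(a$records, c$records))
})

test_that("no planted risk offsets gives a zero-mean latent gap", {
  cfg <- synth_config(n_participants = 2000,
                      risk_prevalence = setNames(rep(0, 5), RISK_FACTORS_T),
                      unhealthy_fraction = 0, seed = 9)
  co <- simulate_cohort(cfg)
  expect_true(all(co$truth[paste0("true_", RISK_FACTORS_T)] == 0))
  expect_lt(abs(mean(co$truth$true_gap)),
            3 * cfg$gap_noise_sd / sqrt(2000))
})

test_that("a forced single factor with zero noise plants its offset exactly", {
  cfg <- synth_config(n_participants = 50,
                      risk_prevalence = c(hypertension = 0, diabetes = 1,
                                          hypercholesterolemia = 0,
                                          obesity = 0, smoking = 0),
                      gap_noise_sd = 0, unhealthy_fraction = 0, seed = 5)
  co <- simulate_cohort(cfg)
  expect_equal(co$truth$true_gap, rep(1.39, 50), tolerance = 1e-12)
})

test_that("empirical prevalences match the configured rates", {
  co <- simulate_cohort(synth_config(n_participants = 2000, seed = 7))
  p_hat <- mean(co$records$hypertension)
  se <- sqrt(0.504 * (1 - 0.504) / 2000)
  expect_lt(abs(p_hat - 0.504), 3 * se)
  # ages stay inside the configured range
  expect_true(all(co$records$age >= 45 & co$records$age <= 83))
})

test_that("regression on the factor indicators recovers every planted offset", {
  cfg <- synth_config(n_participants = 5000, sex_obesity_interaction = 0,
                      unhealthy_fraction = 0, seed = 11)
  co <- simulate_cohort(cfg)
  d <- cbind(gap = co$truth$true_gap,
             setNames(co$truth[paste0("true_", RISK_FACTORS_T)],
                      RISK_FACTORS_T))
  fit <- ols_oracle(gap ~ hypertension + diabetes + hypercholesterolemia +
                      obesity + smoking, d)
  for (f in RISK_FACTORS_T) {
    i <- match(f, fit$term)
    expect_lt(abs(fit$beta[i] - cfg$risk_age_offsets[[f]]), 3 * fit$se[i])
  }
})

test_that("splits have exact proportions and quarantine unhealthy cases", {
  cfg <- synth_config(n_participants = 1000, unhealthy_fraction = 0,
                      seed = 2)
  co <- simulate_cohort(cfg)
  s <- make_splits(co$records, seed = 3)
  expect_equal(unname(table(s)[c("train", "validation", "test")]),
               c(600L, 200L, 200L), ignore_attr = TRUE)
  expect_identical(s, make_splits(co$records, seed = 3))

  cfg2 <- synth_config(n_participants = 300, unhealthy_fraction = 0.3,
                       seed = 2)
  co2 <- simulate_cohort(cfg2)
  s2 <- make_splits(co2$records, seed = 3)
  unhealthy <- co2$records$health_status == "unhealthy"
  expect_true(all(s2[unhealthy] == "test"))
  expect_error(make_splits(co$records, fractions = c(.5, .2, .2)),
               "sum to 1")
})

test_that("longitudinal subset honours fraction, interval and carry-forward", {
  cfg0 <- tiny_config(longitudinal_fraction = 0)
  co <- simulate_cohort(cfg0)
  fu0 <- make_longitudinal_subset(co$records, co$truth, cfg0)
  expect_equal(nrow(fu0$records), 0)

  cfg1 <- synth_config(n_participants = 2000, seed = 13,
                       interval_years = c(mean = 2.25, sd = 0))
  co1 <- simulate_cohort(cfg1)
  fu1 <- make_longitudinal_subset(co1$records, co1$truth, cfg1)
  expect_true(all(fu1$records$timepoint == "followup"))
  expect_equal(fu1$records$interval, rep(2.25, nrow(fu1$records)))
  nfu <- nrow(fu1$records)
  se <- sqrt(0.126 * (1 - 0.126) * 2000)
  expect_lt(abs(nfu - 0.126 * 2000), 3 * se)
  # risk factors carried forward, age advanced, gap drifted
  i <- match(fu1$records$participant_id, co1$records$participant_id)
  expect_identical(fu1$records$hypertension, co1$records$hypertension[i])
  expect_true(all(fu1$records$age > co1$records$age[i]))
  j <- match(fu1$truth$participant_id, co1$truth$participant_id)
  expect_equal(fu1$truth$true_gap,
               co1$truth$true_gap[j] + cfg1$followup_gap_drift)
})

test_that("cognition is independent of risk when all paths are zero", {
  paths <- list(b = c(processing_speed = 0, memory = 0, executive = 0),
                cprime = setNames(rep(0, 5), RISK_FACTORS_T),
                age_slope = 0, sex_effect = 0, education_effect = 0,
                domain_noise_sd = 0.6, test_noise_sd = 0.5,
                practice_effect = 0)
  cfg <- synth_config(n_participants = 2000, cognition_paths = paths,
                      seed = 17)
  co <- simulate_cohort(cfg)
  z <- standardise_cognition(co$records[cognition_test_table()$test])
  fit <- ols_oracle(speed ~ gap, data.frame(speed = z$processing_speed,
                                            gap = co$truth$true_gap))
  expect_lt(abs(fit$beta[2] / fit$se[2]), 2)
})

test_that("zero cognition noise makes raw scores exact affine transforms", {
  paths <- list(b = c(processing_speed = 0.025, memory = 0.008,
                      executive = 0.018),
                cprime = setNames(rep(0, 5), RISK_FACTORS_T),
                age_slope = -0.03, sex_effect = 0.05,
                education_effect = 0.2,
                domain_noise_sd = 0, test_noise_sd = 0,
                practice_effect = 0)
  cfg <- tiny_config(cognition_paths = paths)
  co <- simulate_cohort(cfg)
  cg <- simulate_cognition(co$records, co$truth, cfg)
  lat <- attr(cg, "latent")
  tab <- cognition_test_table()
  for (i in seq_len(nrow(tab))) {
    sgn <- if (tab$reversed[i]) -1 else 1
    expected <- tab$mean[i] + tab$sd[i] * sgn *
      lat[[paste0("true_cog_", tab$domain[i])]]
    expect_equal(cg[[tab$test[i]]], expected, tolerance = 1e-12)
  }
})
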