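test_that("every association model matches the normal-equations oracle", {
  d <- make_analysis_frame(n = 50, seed = 51)
  expect_matches_oracle(fit_model_1a(d),
                        wmbag ~ age + sex + scanner + apoe_e4 + vrs_1 +
                          vrs_2 + vrs_3, d)
  expect_matches_oracle(fit_model_1b(d),
                        wmbag ~ age + sex + scanner + apoe_e4 + vrs_1 +
                          vrs_2 + vrs_3 + sex:vrs_1 + sex:vrs_2 +
                          sex:vrs_3, d)
  expect_matches_oracle(fit_model_2a(d),
                        wmbag ~ age + sex + scanner + apoe_e4 +
                          hypertension + diabetes + hypercholesterolemia +
                          obesity + smoking, d)
  m2bf <- fit_models_2b_f(d)
  for (f in RISK_FACTORS_T) {
    fo <- stats::as.formula(paste("wmbag ~ age + sex + scanner + apoe_e4 +",
                                  f, "+ sex:", f))
    expect_matches_oracle(m2bf[[f]], fo, d)
  }
  cg <- cognition_regressions(d)
  for (oc in names(cg$models)) {
    fo <- stats::as.formula(paste(oc, "~ wmbag + age + sex + scanner +",
                                  "apoe_e4 + education_college"))
    expect_matches_oracle(cg$models[[oc]], fo, d)
  }
})

test_that("the ANCOVA recovers a planted group difference and degenerates to the t-test", {
  cfg <- synth_config(n_participants = 2000, unhealthy_fraction = 0.3,
                      unhealthy_gap_offset = 0.5, seed = 52)
  co <- simulate_cohort(cfg)
  d <- co$records
  d$wmbag <- co$truth$true_gap
  res <- ancova_group_difference(d)
  se <- (res$ci_upper - res$ci_lower) / (2 * qt(0.975, res$model$df_residual))
  expect_lt(abs(res$difference - 0.5), 3 * se)
  expect_lt(res$p, 0.05)

  # covariate-free ANCOVA equals the equal-variance two-sample t-test
  res0 <- ancova_group_difference(d, covariates = character(0))
  tt <- t.test(wmbag ~ health_status, data = d, var.equal = TRUE)
  expect_equal(abs(res0$difference), abs(diff(tt$estimate)),
               tolerance = 1e-10, ignore_attr = TRUE)
  expect_equal(res0$p, tt$p.value, tolerance = 1e-10)
})

test_that("label-shuffled groups show no adjusted difference", {
  d <- make_analysis_frame(n = 400, seed = 53)
  set.seed(53)
  d$health_status <- sample(rep(c("healthy", "unhealthy"), each = 200))
  res <- ancova_group_difference(d)
  expect_gt(res$p, 0.05)
})

test_that("a noise-free gap linear in the dummies is recovered exactly", {
  d <- make_analysis_frame(n = 300, seed = 54)
  d$wmbag <- 0.54 * d$vrs_1 + 1.23 * d$vrs_2 + 1.94 * d$vrs_3 -
    0.026 * d$age + 0.087 * d$sex
  fit <- suppressWarnings(fit_model_1a(d))  # perfect fit by construction
  b <- setNames(fit$terms$beta, fit$terms$term)
  expect_equal(unname(b[c("vrs_1", "vrs_2", "vrs_3")]),
               c(0.54, 1.23, 1.94), tolerance = 1e-10)
  expect_equal(unname(b["age"]), -0.026, tolerance = 1e-10)
})

test_that("degenerate model columns are rejected by name", {
  d <- make_analysis_frame(n = 120, seed = 55)
  d$diabetes <- 0                       # prevalence zero in sample
  expect_error(fit_model_2a(d), "diabetes")
  d2 <- make_analysis_frame(n = 120, seed = 56)
  d2$sex <- 1                           # interaction unidentifiable
  expect_error(fit_models_2b_f(d2), "sex")
})

test_that("sex recoding flips interaction betas without changing the fit", {
  d <- make_analysis_frame(n = 250, seed = 57)
  f1 <- fit_model_1b(d)
  d2 <- d; d2$sex <- 1 - d2$sex
  f2 <- fit_model_1b(d2)
  b1 <- setNames(f1$terms$beta, f1$terms$term)
  b2 <- setNames(f2$terms$beta, f2$terms$term)
  expect_equal(unname(b2["sex:vrs_3"]), -unname(b1["sex:vrs_3"]),
               tolerance = 1e-10)
  expect_equal(f1$sigma, f2$sigma, tolerance = 1e-10)
})

test_that("the within-level sex contrast matches its delta-method algebra", {
  d <- make_analysis_frame(n = 400, seed = 58)
  fit <- fit_model_1b(d)
  ct <- vrs_sex_contrast(fit, 3)
  b <- setNames(fit$terms$beta, fit$terms$term)
  expect_equal(ct$estimate, unname(b["sex"] + b["sex:vrs_3"]),
               tolerance = 1e-12)
  i <- match(c("sex", "sex:vrs_3"), fit$terms$term)
  v <- fit$vcov[i, i]
  expect_equal(ct$se, sqrt(sum(v)), tolerance = 1e-12)
})

test_that("Bonferroni control uses 0.05/4 and flags accordingly", {
  expect_equal(bonferroni_alpha(), 0.0125)
  d <- make_analysis_frame(n = 800, seed = 59)
  cg <- cognition_regressions(d)
  tab <- cg$table
  expect_equal(cg$alpha_corrected, 0.0125)
  # the planted gap effect on speed is strongly negative and survives;
  # the null memory outcome does not
  expect_lt(tab$beta[tab$outcome == "processing_speed"], 0)
  expect_true(tab$significant_bonferroni[tab$outcome == "processing_speed"])
  expect_false(tab$significant_bonferroni[tab$outcome == "memory"])
  expect_identical(tab$significant_bonferroni, tab$p < 0.0125)
})

test_that("entirely missing outcomes are skipped with a warning", {
  d <- make_analysis_frame(n = 100, seed = 60)
  d$memory <- NA_real_
  expect_warning(cg <- cognition_regressions(d), "memory")
  expect_false("memory" %in% cg$table$outcome)
})
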