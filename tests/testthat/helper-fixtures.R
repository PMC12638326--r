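# Shared fixtures and the independent normal-equations oracle.

# Small, fast generator configuration used across tests unless a test
# needs the published-scale defaults.
tiny_config <- function(...) {
  args <- utils::modifyList(list(n_participants = 60,
                                 grid_shape = c(12L, 12L, 12L),
                                 seed = 42L), list(...))
  do.call(synth_config, args)
}

# Tiny network specification for structural tests.
tiny_spec <- function(...) {
  network_spec(input_shape = c(12L, 12L, 12L),
               conv_channels = c(2L, 3L, 3L, 3L, 3L, 4L),
               feature_dim = 5L, ...)
}

# Independent OLS oracle: explicit normal equations, no call into lm().
# Returns per-term estimates, classical t-based 95% CIs and p-values.
ols_oracle <- function(formula, data) {
  mf <- stats::model.frame(formula, data, na.action = stats::na.omit)
  y <- stats::model.response(mf)
  X <- stats::model.matrix(formula, mf)
  beta <- solve(crossprod(X), crossprod(X, y))
  res <- y - X %*% beta
  df <- nrow(X) - ncol(X)
  s2 <- sum(res^2) / df
  V <- s2 * solve(crossprod(X))
  se <- sqrt(diag(V))
  tq <- stats::qt(0.975, df)
  b <- drop(beta)
  list(term = colnames(X), beta = b, se = se,
       ci_lower = b - tq * se, ci_upper = b + tq * se,
       p = 2 * stats::pt(-abs(b / se), df), vcov = V, n = nrow(X))
}

expect_matches_oracle <- function(fit, formula, data, tol = 1e-8) {
  oc <- ols_oracle(formula, data)
  expect_equal(fit$terms$term, oc$term)
  expect_equal(fit$terms$beta, oc$beta, tolerance = tol,
               ignore_attr = TRUE)
  expect_equal(fit$terms$ci_lower, oc$ci_lower, tolerance = tol,
               ignore_attr = TRUE)
  expect_equal(fit$terms$ci_upper, oc$ci_upper, tolerance = tol,
               ignore_attr = TRUE)
  expect_equal(fit$terms$p, oc$p, tolerance = tol, ignore_attr = TRUE)
  expect_equal(fit$n_used, oc$n)
}

# Synthetic analysis table with every column the association models need,
# built directly (not via the cohort generator) so tests control the truth.
make_analysis_frame <- function(n = 200, seed = 1,
                                gap_fun = NULL, noise_sd = 1) {
  set.seed(seed)
  d <- data.frame(
    age = runif(n, 45, 83),
    sex = rbinom(n, 1, 0.46),
    scanner = sample(0:2, n, replace = TRUE),
    apoe_e4 = sample(0:2, n, replace = TRUE, prob = c(.72, .25, .03)),
    education_college = rbinom(n, 1, 0.5),
    hypertension = rbinom(n, 1, 0.5),
    diabetes = rbinom(n, 1, 0.2),
    hypercholesterolemia = rbinom(n, 1, 0.25),
    obesity = rbinom(n, 1, 0.2),
    smoking = rbinom(n, 1, 0.38))
  d <- cbind(d, compute_vrs(d[RISK_FACTORS_T]))
  if (is.null(gap_fun))
    gap_fun <- function(d) 0.9 * d$hypertension + 1.4 * d$diabetes +
      0.7 * d$smoking
  d$wmbag <- gap_fun(d) + rnorm(n, 0, noise_sd)
  d$processing_speed <- -0.12 * d$wmbag - 0.02 * (d$age - 64) +
    rnorm(n, 0, 0.5)
  d$executive <- -0.08 * d$wmbag + rnorm(n, 0, 0.5)
  d$memory <- rnorm(n, 0, 0.5)
  d$global <- rowMeans(d[c("processing_speed", "executive", "memory")])
  d
}

RISK_FACTORS_T <- c("hypertension", "diabetes", "hypercholesterolemia",
                    "obesity", "smoking")
MAPS_T <- c("FA", "MD", "AxD", "RD", "MO")
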