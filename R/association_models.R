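# Cross-sectional inferential models: ANCOVA group comparison, VRS
# main-effect and sex-interaction models (1a/1b), individual-factor models
# (2a, 2b-f), WMBAG-cognition regressions, and Bonferroni control.  All
# are ordinary least squares with classical t-based 95% intervals and
# complete-case handling; scanner and APOE enter as single numeric codes
# by default (categorical coding available via `as_factors`).

#' Bonferroni-corrected alpha level
#'
#' @param n_tests number of outcomes in the family (default 4: processing
#'   speed, memory, executive, global).
#' @param alpha nominal level.
#' @return corrected threshold (0.05/4 = 0.0125 at the defaults).
#' @export
bonferroni_alpha <- function(n_tests = 4, alpha = 0.05) alpha / n_tests

# OLS with complete-case handling and degenerate-column detection.
ols_model <- function(formula, data, conf_level = 0.95) {
  mf <- model.frame(formula, data, na.action = na.omit)
  X <- model.matrix(formula, mf)
  keep <- setdiff(colnames(X), "(Intercept)")
  const <- keep[apply(X[, keep, drop = FALSE], 2, function(v)
    length(unique(v)) < 2)]
  if (length(const))
    stop_wm("degenerate (constant) model term(s): %s",
            paste(const, collapse = ", "))
  fit <- lm(formula, data = data, na.action = na.omit)
  sm <- summary(fit)
  co <- sm$coefficients
  tq <- qt(1 - (1 - conf_level) / 2, df = fit$df.residual)
  res <- data.frame(term = rownames(co), beta = co[, 1],
                    se = co[, 2],
                    ci_lower = co[, 1] - tq * co[, 2],
                    ci_upper = co[, 1] + tq * co[, 2],
                    p = co[, 4], row.names = NULL,
                    stringsAsFactors = FALSE)
  structure(list(terms = res, n_used = nrow(mf),
                 formula = formula, vcov = sm$sigma^2 * sm$cov.unscaled,
                 sigma = sm$sigma, df_residual = fit$df.residual),
            class = "regression_result")
}

#' @export
print.regression_result <- function(x, ...) {
  cat(sprintf("OLS: %s  (n = %d)\n", deparse(x$formula), x$n_used))
  print(x$terms, digits = 4)
  invisible(x)
}

term_row <- function(result, term) {
  i <- match(term, result$terms$term)
  if (is.na(i)) stop_wm("term %s not in model", term)
  result$terms[i, ]
}

covariate_rhs <- function(covariates) {
  if (!length(covariates)) "1" else paste(covariates, collapse = " + ")
}

#' ANCOVA-adjusted group difference in WMBAG
#'
#' Compares the gap between two groups (e.g. healthy vs unhealthy)
#' adjusting for covariates, via the linear-model formulation of ANCOVA:
#' the adjusted difference is the group-indicator coefficient.
#'
#' @param data data.frame with the gap, group and covariate columns.
#' @param gap,group column names; `group` must have exactly two levels
#'   after complete-case filtering.
#' @param covariates character vector of adjustment columns (default
#'   chronological age, sex, scanner, APOE).
#' @return list with `difference`, `ci_lower`, `ci_upper`, `p`, the group
#'   level contrasted against the reference, and the full
#'   `regression_result`.
#' @export
ancova_group_difference <- function(data, gap = "wmbag",
                                    group = "health_status",
                                    covariates = c("age", "sex", "scanner",
                                                   "apoe_e4")) {
  data[[group]] <- factor(data[[group]])
  cc <- complete.cases(data[c(gap, group, covariates)])
  lv <- unique(droplevels(data[[group]][cc]))
  if (length(lv) != 2)
    stop_wm("group must have exactly two non-empty levels after complete-case filtering (got %d)",
            length(lv))
  f <- stats::as.formula(paste(gap, "~", group, "+",
                               covariate_rhs(covariates)))
  fit <- ols_model(f, data)
  gterm <- grep(paste0("^", group), fit$terms$term, value = TRUE)[1]
  row <- term_row(fit, gterm)
  list(difference = row$beta, ci_lower = row$ci_lower,
       ci_upper = row$ci_upper, p = row$p,
       contrast = sub(paste0("^", group), "", gterm), model = fit)
}

#' Model 1a: main effect of the vascular risk score on WMBAG
#'
#' OLS of the gap on the three VRS dummies (reference: no risk factors),
#' controlling for chronological age, sex, scanner and APOE status.
#'
#' @param data data.frame with `wmbag`, `vrs_1`, `vrs_2`, `vrs_3` (e.g.
#'   from [compute_vrs()]) and the covariates.
#' @param covariates adjustment columns.
#' @return a `regression_result`.
#' @export
fit_model_1a <- function(data, covariates = c("age", "sex", "scanner",
                                              "apoe_e4")) {
  f <- stats::as.formula(paste("wmbag ~", covariate_rhs(covariates),
                               "+ vrs_1 + vrs_2 + vrs_3"))
  ols_model(f, data)
}

#' Model 1b: sex-by-VRS interactions
#'
#' Adds `sex x vrs_k` terms to model 1a.  The within-level sex contrast
#' (male minus female at VRS level k) is available via
#' [vrs_sex_contrast()].
#'
#' @inheritParams fit_model_1a
#' @return a `regression_result`.
#' @export
fit_model_1b <- function(data, covariates = c("age", "sex", "scanner",
                                              "apoe_e4")) {
  f <- stats::as.formula(paste("wmbag ~", covariate_rhs(covariates),
                               "+ vrs_1 + vrs_2 + vrs_3",
                               "+ sex:vrs_1 + sex:vrs_2 + sex:vrs_3"))
  ols_model(f, data)
}

#' Within-VRS-level sex contrast from model 1b
#'
#' The male-minus-female adjusted difference at VRS level `level` is the
#' linear combination `beta_sex + beta_{sex x vrs_level}` (just
#' `beta_sex` at level 0), with a delta-method standard error from the
#' coefficient covariance.
#'
#' @param result a [fit_model_1b()] result.
#' @param level VRS level: `0`, `1`, `2` or `3`.
#' @return list with `estimate`, `se`, `p` (two-sided, residual-t).
#' @export
vrs_sex_contrast <- function(result, level) {
  stopifnot(inherits(result, "regression_result"))
  terms <- result$terms$term
  w <- setNames(numeric(length(terms)), terms)
  w["sex"] <- 1
  if (level > 0) {
    it <- grep(paste0("vrs_", level), terms, value = TRUE)
    it <- it[grepl("sex", it)]
    if (!length(it)) stop_wm("no sex interaction for VRS level %s", level)
    w[it] <- 1
  }
  est <- sum(w * result$terms$beta)
  se <- sqrt(drop(t(w) %*% result$vcov %*% w))
  tstat <- est / se
  list(estimate = est, se = se,
       p = 2 * pt(-abs(tstat), df = result$df_residual))
}

#' Model 2a: simultaneous contributions of the five risk factors
#'
#' Replaces the VRS dummies with all five binary factors, yielding each
#' factor's unique contribution to the gap.
#'
#' @inheritParams fit_model_1a
#' @return a `regression_result`.
#' @export
fit_model_2a <- function(data, covariates = c("age", "sex", "scanner",
                                              "apoe_e4")) {
  f <- stats::as.formula(paste("wmbag ~", covariate_rhs(covariates), "+",
                               paste(RISK_FACTORS, collapse = " + ")))
  ols_model(f, data)
}

#' Models 2b-f: sex moderation of each individual risk factor
#'
#' One model per factor: the factor, its interaction with sex, and the
#' covariates.
#'
#' @inheritParams fit_model_1a
#' @param factors which risk factors to model (default all five).
#' @return named list of `regression_result`s, one per factor.
#' @export
fit_models_2b_f <- function(data, covariates = c("age", "sex", "scanner",
                                                 "apoe_e4"),
                            factors = RISK_FACTORS) {
  out <- lapply(factors, function(fac) {
    f <- stats::as.formula(paste("wmbag ~", covariate_rhs(covariates), "+",
                                 fac, "+ sex:", fac))
    ols_model(f, data)
  })
  setNames(out, factors)
}

#' WMBAG-cognition regressions with Bonferroni control
#'
#' For each of the four cognitive outcomes (processing speed, executive,
#' memory, global), OLS of the outcome on the gap adjusting for age, sex,
#' scanner, APOE and education; the gap coefficient is flagged against the
#' Bonferroni-corrected threshold 0.05/4.
#'
#' @param data data.frame with `wmbag`, the outcome columns and
#'   covariates.
#' @param outcomes outcome column names.
#' @param covariates adjustment columns.
#' @param alpha nominal family level.
#' @return list with `table` (one row per outcome: beta, CI, p,
#'   `significant_bonferroni`), `alpha_corrected`, and the per-outcome
#'   `regression_result`s in `models`.  Outcomes entirely missing are
#'   skipped with a warning.
#' @export
cognition_regressions <- function(data,
                                  outcomes = c("processing_speed",
                                               "executive", "memory",
                                               "global"),
                                  covariates = c("age", "sex", "scanner",
                                                 "apoe_e4",
                                                 "education_college"),
                                  alpha = 0.05) {
  a_corr <- bonferroni_alpha(length(outcomes), alpha)
  models <- list()
  rows <- list()
  for (oc in outcomes) {
    if (!oc %in% names(data) || all(is.na(data[[oc]]))) {
      warning(sprintf("outcome %s entirely missing; skipped", oc),
              call. = FALSE)
      next
    }
    f <- stats::as.formula(paste(oc, "~ wmbag +",
                                 covariate_rhs(covariates)))
    fit <- ols_model(f, data)
    models[[oc]] <- fit
    row <- term_row(fit, "wmbag")
    rows[[oc]] <- data.frame(outcome = oc, beta = row$beta,
                             ci_lower = row$ci_lower,
                             ci_upper = row$ci_upper, p = row$p,
                             n_used = fit$n_used,
                             significant_bonferroni = row$p < a_corr,
                             stringsAsFactors = FALSE)
  }
  list(table = do.call(rbind, c(rows, list(make.row.names = FALSE))),
       alpha_corrected = a_corr, models = models)
}
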