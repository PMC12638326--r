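# Product-of-coefficients mediation with a nonparametric case-resampling
# bootstrap, implemented natively.  The decomposition is linear with no
# exposure-mediator interaction: fit M ~ X + C (coefficient a) and
# Y ~ X + M + C (coefficients c', b); the indirect effect (ACME) is a*b,
# the direct effect (ADE) is c', and the total effect is their sum.

mediation_points <- function(X1, X2, m, y, rows) {
  f1 <- .lm.fit(X1[rows, , drop = FALSE], m[rows])
  a <- f1$coefficients[2]
  f2 <- .lm.fit(X2[rows, , drop = FALSE], y[rows])
  cprime <- f2$coefficients[2]
  b <- f2$coefficients[3]
  c(acme = a * b, ade = cprime, total = a * b + cprime, a = a, b = b)
}

boot_p <- function(draws) {
  # twice the smaller tail proportion of the bootstrap distribution
  # crossing zero, floored at 1/n_boot
  pl <- mean(draws <= 0)
  pu <- mean(draws >= 0)
  max(min(2 * min(pl, pu), 1), 1 / length(draws))
}

#' Mediation analysis with bootstrap confidence intervals
#'
#' Estimates the indirect (ACME), direct (ADE) and total effects of an
#' exposure on an outcome through a mediator, with percentile bootstrap
#' confidence intervals from nonparametric case resampling.  The ACME
#' point estimate is exactly the product of the two OLS coefficients; the
#' total effect is exactly ACME + ADE.
#'
#' @param x exposure (numeric vector; typically a binary risk factor).
#' @param m mediator (e.g. the white matter brain age gap).
#' @param y outcome (e.g. a cognition composite).
#' @param covariates optional data.frame/matrix of adjustment variables.
#' @param n_boot bootstrap samples (default 5000).
#' @param seed integer seed; identical seeds give identical intervals.
#' @param conf_level confidence level for the percentile intervals.
#' @return object of class `mediation_result`: per-effect point estimate,
#'   CI bounds and bootstrap p-value, plus `n_used`, `n_boot`, `seed` and
#'   `n_redrawn` (bootstrap resamples redrawn because the exposure was
#'   constant).
#' @export
mediate <- function(x, m, y, covariates = NULL, n_boot = 5000, seed = 1L,
                    conf_level = 0.95) {
  if (n_boot < 1) stop_wm("n_boot must be at least 1")
  C <- if (is.null(covariates)) NULL else as.matrix(covariates)
  cc <- complete.cases(cbind(x, m, y, C))
  x <- x[cc]; m <- m[cc]; y <- y[cc]
  if (!is.null(C)) C <- C[cc, , drop = FALSE]
  n <- length(x)
  ncov <- if (is.null(C)) 0L else ncol(C)
  if (n < 10 * max(1L, ncov))
    stop_wm("too few complete cases (%d) for %d covariate(s)", n, ncov)
  if (var(x) == 0) stop_wm("exposure has zero variance")
  if (var(m) == 0) stop_wm("mediator has zero variance")
  X1 <- cbind(1, x, C)
  X2 <- cbind(1, x, m, C)
  pt_est <- mediation_points(X1, X2, m, y, seq_len(n))
  draws <- matrix(NA_real_, n_boot, 3)
  n_redrawn <- 0L
  with_seed(seed, "mediate", {
    for (i in seq_len(n_boot)) {
      repeat {
        rows <- sample.int(n, n, replace = TRUE)
        if (var(x[rows]) > 0) break
        n_redrawn <- n_redrawn + 1L
      }
      draws[i, ] <- mediation_points(X1, X2, m, y, rows)[1:3]
    }
  })
  alpha <- 1 - conf_level
  ci <- apply(draws, 2, quantile, probs = c(alpha / 2, 1 - alpha / 2))
  eff <- c("acme", "ade", "total")
  ci_df <- data.frame(lower = ci[1, ], upper = ci[2, ], row.names = eff)
  structure(list(
    acme = unname(pt_est["acme"]), ade = unname(pt_est["ade"]),
    total = unname(pt_est["total"]),
    a = unname(pt_est["a"]), b = unname(pt_est["b"]),
    ci = ci_df,
    p_values = setNames(apply(draws, 2, boot_p), eff),
    n_used = n, n_boot = n_boot, seed = seed, n_redrawn = n_redrawn,
    conf_level = conf_level), class = "mediation_result")
}

#' @export
print.mediation_result <- function(x, ...) {
  cat(sprintf("Mediation (n = %d, %d bootstrap samples)\n",
              x$n_used, x$n_boot))
  df <- data.frame(estimate = c(x$acme, x$ade, x$total),
                   lower = x$ci$lower, upper = x$ci$upper,
                   p = x$p_values,
                   row.names = c("ACME (indirect)", "ADE (direct)",
                                 "Total"))
  print(df, digits = 4)
  invisible(x)
}

#' Mediation battery over risk factors and cognitive outcomes
#'
#' One mediation model per (factor, outcome) pair with the gap as
#' mediator, in deterministic (factor, outcome) order, with Bonferroni
#' flags at `0.05 / n_outcomes` within each outcome family.
#'
#' @param data data.frame holding the factors, mediator, outcomes and
#'   covariates.
#' @param factors exposure column names (default the five risk factors).
#' @param outcomes outcome column names.
#' @param mediator mediator column name.
#' @param covariates adjustment column names.
#' @param n_boot,seed,conf_level passed to [mediate()]; each pair gets a
#'   seed derived deterministically from `seed`.
#' @return long-format data.frame: one row per pair with ACME/ADE/total
#'   estimates, CIs, p-values and Bonferroni flags.
#' @export
mediation_battery <- function(data, factors = RISK_FACTORS,
                              outcomes = c("processing_speed", "executive",
                                           "memory", "global"),
                              mediator = "wmbag",
                              covariates = c("age", "sex", "scanner",
                                             "apoe_e4",
                                             "education_college"),
                              n_boot = 1000, seed = 1L,
                              conf_level = 0.95) {
  a_corr <- bonferroni_alpha(length(outcomes))
  rows <- list()
  for (fac in factors) {
    for (oc in outcomes) {
      res <- mediate(data[[fac]], data[[mediator]], data[[oc]],
                     covariates = data[covariates], n_boot = n_boot,
                     seed = derive_seed(seed, paste(fac, oc)),
                     conf_level = conf_level)
      rows[[paste(fac, oc)]] <- data.frame(
        factor = fac, outcome = oc,
        acme = res$acme, acme_lower = res$ci["acme", "lower"],
        acme_upper = res$ci["acme", "upper"],
        acme_p = res$p_values[["acme"]],
        ade = res$ade, ade_lower = res$ci["ade", "lower"],
        ade_upper = res$ci["ade", "upper"],
        ade_p = res$p_values[["ade"]],
        total = res$total, n_used = res$n_used,
        acme_significant = res$p_values[["acme"]] < a_corr,
        ade_significant = res$p_values[["ade"]] < a_corr,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  attr(out, "alpha_corrected") <- a_corr
  out
}
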