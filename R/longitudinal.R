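# Two-timepoint change analysis: change scores (follow-up minus
# baseline), the dependent t-test on the gap, and change regressions /
# change mediation reusing the cross-sectional machinery.

#' Change scores between baseline and follow-up
#'
#' Matches participants across the two timepoints and computes follow-up
#' minus baseline differences for the requested value columns (the gap,
#' predicted age, cognition composites).  Baseline covariates are carried
#' into the output for the change regressions; unmatched follow-up rows
#' are excluded with a message.
#'
#' @param baseline,followup data.frames with `participant_id` and the
#'   value columns; `followup` may carry an `interval` column (years).
#' @param value_cols columns to difference.
#' @param carry_cols baseline columns to carry forward unchanged (only
#'   those present are used).
#' @return data.frame with `participant_id`, `interval`, one
#'   `delta_<col>` per value column, and the carried baseline columns.
#' @export
change_scores <- function(baseline, followup,
                          value_cols = c("wmbag", "y_hat_co",
                                         "processing_speed", "memory",
                                         "executive", "global"),
                          carry_cols = c("age", "sex", "scanner", "icv",
                                         "apoe_e4", "education_college",
                                         RISK_FACTORS,
                                         "vrs_1", "vrs_2", "vrs_3")) {
  value_cols <- intersect(value_cols, intersect(names(baseline),
                                                names(followup)))
  unmatched <- setdiff(followup$participant_id, baseline$participant_id)
  if (length(unmatched))
    message(sprintf("change_scores: %d follow-up row(s) without baseline excluded",
                    length(unmatched)))
  fu <- followup[followup$participant_id %in% baseline$participant_id, ,
                 drop = FALSE]
  i <- match(fu$participant_id, baseline$participant_id)
  out <- data.frame(participant_id = fu$participant_id,
                    interval = if ("interval" %in% names(fu))
                      fu$interval else fu$age - baseline$age[i],
                    stringsAsFactors = FALSE)
  for (cl in value_cols)
    out[[paste0("delta_", cl)]] <- fu[[cl]] - baseline[[cl]][i]
  for (cl in intersect(carry_cols, names(baseline)))
    out[[cl]] <- baseline[[cl]][i]
  out
}

#' Dependent (paired) t-test
#'
#' Classical two-tailed paired t-test.  Pass either the vector of paired
#' differences, or both timepoints (differences are `followup -
#' baseline`).  Equals the one-sample t-test on the differences.
#'
#' @param x differences, or the baseline values when `y` is given.
#' @param y optional follow-up values.
#' @return list with `t`, `df`, `p`, `mean_change`, `n`.
#' @export
paired_t <- function(x, y = NULL) {
  d <- if (is.null(y)) x else y - x
  d <- d[is.finite(d)]
  n <- length(d)
  if (n < 2) stop_wm("paired t-test needs at least 2 pairs")
  s <- sd(d)
  if (s == 0)
    stop_wm("paired t-test undefined: differences have zero variance")
  tstat <- mean(d) / (s / sqrt(n))
  list(t = tstat, df = n - 1, p = 2 * pt(-abs(tstat), n - 1),
       mean_change = mean(d), n = n)
}

#' Change regressions and change mediation
#'
#' Prospective analysis on the longitudinal subset: (1) baseline risk
#' factors against change in the gap (model-2a-style simultaneous OLS);
#' (2) change in each cognition composite against change in the gap; and
#' (3) mediation of factor effects on cognition change through gap
#' change.  Returns empty tables cleanly when the subset is empty.
#'
#' @param changes data.frame from [change_scores()].
#' @param factors exposure columns.
#' @param outcomes delta-cognition columns.
#' @param covariates baseline adjustment columns.
#' @param n_boot,seed mediation bootstrap settings.
#' @param adjust_interval include the follow-up interval as a covariate
#'   (off by default).
#' @return list with `gap_model` (regression of delta gap on factors; NULL
#'   when empty), `cognition_table`, `mediation_table`, and
#'   `pct_increased` (share of participants whose predicted age rose).
#' @export
change_regressions_and_mediation <- function(changes,
                                             factors = RISK_FACTORS,
                                             outcomes = c("delta_processing_speed",
                                                          "delta_memory",
                                                          "delta_executive",
                                                          "delta_global"),
                                             covariates = c("age", "sex",
                                                            "scanner",
                                                            "apoe_e4",
                                                            "education_college"),
                                             n_boot = 1000, seed = 1L,
                                             adjust_interval = FALSE) {
  empty <- list(gap_model = NULL,
                cognition_table = data.frame(),
                mediation_table = data.frame(),
                pct_increased = NA_real_)
  if (is.null(changes) || nrow(changes) == 0) return(empty)
  covs <- intersect(covariates, names(changes))
  if (adjust_interval) covs <- union(covs, "interval")
  outcomes <- intersect(outcomes, names(changes))
  min_n <- 2 * (length(factors) + length(covs) + 2)
  if (nrow(changes) < min_n) {
    message(sprintf("longitudinal subset too small for change models (%d < %d); returning empty tables",
                    nrow(changes), min_n))
    empty$pct_increased <- if ("delta_y_hat_co" %in% names(changes))
      100 * mean(changes$delta_y_hat_co > 0, na.rm = TRUE) else NA_real_
    return(empty)
  }
  gm_data <- changes
  gm_data$wmbag <- changes$delta_wmbag
  gap_model <- fit_model_2a(gm_data, covariates = covs)
  cog <- cognition_regressions(gm_data, outcomes = outcomes,
                               covariates = covs)
  med <- mediation_battery(gm_data, factors = factors,
                           outcomes = outcomes, mediator = "delta_wmbag",
                           covariates = covs, n_boot = n_boot, seed = seed)
  pct <- if ("delta_y_hat_co" %in% names(changes))
    100 * mean(changes$delta_y_hat_co > 0, na.rm = TRUE) else NA_real_
  list(gap_model = gap_model, cognition_table = cog$table,
       mediation_table = med, pct_increased = pct)
}
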