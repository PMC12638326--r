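#' Fit the validation-set age-bias model
#'
#' Raw brain-age predictions suffer regression dilution: older people are
#' predicted too young and younger people too old.  The bias model is the
#' ordinary least squares fit `yhat = alpha * y + beta` on a held-out
#' validation set; its inversion is applied unchanged to test data.
#'
#' @param y chronological ages (years) of the validation set.
#' @param yhat raw predicted ages (years).
#' @return object of class `bias_model` with `alpha`, `beta`, `n_fit` and
#'   `fit_r2`.
#' @export
fit_bias <- function(y, yhat) {
  if (length(y) != length(yhat)) stop_wm("y and yhat differ in length")
  ok <- is.finite(y) & is.finite(yhat)
  y <- y[ok]; yhat <- yhat[ok]
  if (length(y) < 3) stop_wm("bias fit needs at least 3 observations")
  if (var(y) == 0) stop_wm("bias fit undefined: zero variance in age")
  fit <- lm.fit(cbind(1, y), yhat)
  alpha <- unname(fit$coefficients[2])
  beta <- unname(fit$coefficients[1])
  if (abs(alpha) < 1e-6)
    stop_wm("bias slope alpha is numerically zero; correction undefined")
  r2 <- 1 - sum(fit$residuals^2) / sum((yhat - mean(yhat))^2)
  structure(list(alpha = alpha, beta = beta, n_fit = length(y),
                 fit_r2 = r2), class = "bias_model")
}

#' Apply the bias correction to raw predictions
#'
#' Computes `yhat_co = (yhat - beta) / alpha` elementwise, assuming the
#' validation-set coefficients generalise to the data at hand.
#'
#' @param yhat raw predicted ages.
#' @param model a [fit_bias()] object.
#' @return corrected predicted ages (years).
#' @export
apply_bias <- function(yhat, model) {
  stopifnot(inherits(model, "bias_model"))
  (yhat - model$beta) / model$alpha
}

#' White matter brain age gap
#'
#' The gap is the corrected predicted age minus the chronological age;
#' positive values indicate apparently accelerated white matter ageing.
#'
#' @param y chronological ages.
#' @param yhat_co corrected predicted ages.
#' @return numeric vector of gaps (years).
#' @export
compute_gap <- function(y, yhat_co) {
  if (length(y) != length(yhat_co))
    stop_wm("y and yhat_co differ in length (%d vs %d)",
            length(y), length(yhat_co))
  yhat_co - y
}

#' Prediction performance report
#'
#' Mean absolute error, Pearson correlation between chronological and
#' predicted age, and the Spearman correlation between the gap
#' (prediction minus age) and age — the quantity that bias correction
#' should drive towards zero.
#'
#' @param y chronological ages.
#' @param predictions predicted ages (raw or corrected).
#' @return list with `mae`, `pearson_r`, `spearman_gap_age`, `n`.
#' @export
performance <- function(y, predictions) {
  if (length(y) != length(predictions))
    stop_wm("y and predictions differ in length")
  ok <- is.finite(y) & is.finite(predictions)
  y <- y[ok]; predictions <- predictions[ok]
  if (length(y) < 2) stop_wm("performance needs at least 2 observations")
  gap <- predictions - y
  list(mae = mean(abs(gap)),
       pearson_r = cor(y, predictions),
       spearman_gap_age = if (var(gap) > 0)
         cor(gap, y, method = "spearman") else NA_real_,
       n = length(y))
}
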