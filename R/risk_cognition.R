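#' Composite vascular risk score
#'
#' Counts the five binary vascular risk factors (hypertension, diabetes,
#' hypercholesterolemia, obesity, smoking), collapses counts of three or
#' more into one category, and dummy-codes the categories with 0 as the
#' reference.  Scoring is complete-case: any missing factor makes the
#' whole score missing.
#'
#' @param risk_factors data.frame (or matrix) with the five factor columns
#'   in `{0, 1, NA}`.
#' @return data.frame with `factor_count`, `category` (factor with levels
#'   `0`, `1`, `2`, `3plus`) and dummies `vrs_1`, `vrs_2`, `vrs_3`.
#' @export
compute_vrs <- function(risk_factors) {
  rf <- as.data.frame(risk_factors)[RISK_FACTORS]
  if (any(vapply(rf, function(x) any(!x %in% c(0, 1, NA)), TRUE)))
    stop_wm("risk factors must be 0, 1 or missing")
  m <- as.matrix(rf)
  count <- ifelse(rowSums(is.na(m)) > 0, NA, rowSums(m))
  category <- cut(count, breaks = c(-1, 0, 1, 2, 5),
                  labels = c("0", "1", "2", "3plus"))
  data.frame(factor_count = count, category = category,
             vrs_1 = as.numeric(count == 1),
             vrs_2 = as.numeric(count == 2),
             vrs_3 = as.numeric(count >= 3))
}

#' APOE epsilon-4 carrier status
#'
#' Classifies the epsilon-4 allele count into three categories; missing
#' counts stay missing (and are excluded from adjusted models downstream).
#'
#' @param e4_count integer vector in `{0, 1, 2, NA}`.
#' @return factor with levels `noncarrier`, `one_allele`, `two_alleles`.
#' @export
encode_apoe <- function(e4_count) {
  if (any(!e4_count %in% c(0L, 1L, 2L, NA)))
    stop_wm("APOE e4 allele count must be 0, 1, 2 or missing")
  factor(c("noncarrier", "one_allele", "two_alleles")[e4_count + 1L],
         levels = c("noncarrier", "one_allele", "two_alleles"))
}

#' Standardised cognition domain and global composites
#'
#' Each raw test is z-scored against the reference sample, sign-flipped
#' where a lower raw score means better performance (reaction time, both
#' trail-making tests, pairs-matching errors), so that higher always means
#' better.  Domains are available-case means of their constituent tests
#' (processing speed: reaction time, trail making A, symbol digit; memory:
#' numeric memory, pairs matching; executive: trail making B, fluid
#' intelligence); the global composite is the mean of the three domains.
#'
#' @param raw data.frame of raw test scores (columns named as in
#'   [cognition_test_table()]).
#' @param reference data.frame supplying the reference means/sds (default:
#'   `raw` itself, i.e. the full analysis sample at baseline).
#' @return data.frame with `processing_speed`, `memory`, `executive`,
#'   `global` and a logical `incomplete` flag marking rows where a domain
#'   used fewer than all of its tests.
#' @export
standardise_cognition <- function(raw, reference = raw) {
  tab <- cognition_test_table()
  missing_tests <- setdiff(tab$test, names(raw))
  if (length(missing_tests))
    stop_wm("raw scores lack test column(s): %s",
            paste(missing_tests, collapse = ", "))
  z <- sapply(seq_len(nrow(tab)), function(i) {
    t <- tab$test[i]
    mu <- mean(reference[[t]], na.rm = TRUE)
    sdv <- sd(reference[[t]], na.rm = TRUE)
    if (!is.finite(sdv) || sdv == 0)
      stop_wm("reference sd for %s is zero or undefined", t)
    (if (tab$reversed[i]) -1 else 1) * (raw[[t]] - mu) / sdv
  })
  z <- matrix(z, nrow = nrow(raw), dimnames = list(NULL, tab$test))
  domains <- c("processing_speed", "memory", "executive")
  dm <- sapply(domains, function(d)
    rowMeans(z[, tab$test[tab$domain == d], drop = FALSE], na.rm = TRUE))
  dm <- matrix(dm, nrow = nrow(raw), dimnames = list(NULL, domains))
  dm[is.nan(dm)] <- NA  # all constituents of a domain missing
  out <- as.data.frame(dm)
  out$global <- rowMeans(dm)
  out$incomplete <- rowSums(is.na(z)) > 0
  out
}
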