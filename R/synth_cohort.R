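#' Configuration for the synthetic DWI cohort generator
#'
#' Builds the configuration object governing the synthetic cohort: sample
#' size, age range, voxel grid, vascular-risk prevalences and planted
#' brain-age offsets, map rendering parameters, cognition path
#' coefficients, and the longitudinal follow-up design.  Defaults emulate
#' a large population imaging cohort of middle-aged and older adults:
#' risk prevalences of 50.4% (hypertension), 5.5% (diabetes), 24.5%
#' (hypercholesterolemia), 19.0% (obesity) and 38.1% (smoking); 45.8%
#' male; ages 45-83 centred near 64; and planted accelerated-ageing
#' offsets of 1.390 y (diabetes), 0.871 y (hypertension), 0.689 y
#' (smoking), 0.311 y (hypercholesterolemia) and 0 for obesity, whose
#' effect is male-only (interaction 1.023 y).  The male excess in the
#' VRS >= 3 tier is not planted separately: it emerges from the
#' male-obesity mechanism.
#'
#' @param n_participants number of baseline participants.
#' @param age_range two ages in years, low < high.
#' @param grid_shape three positive voxel counts; the default 24 x 28 x 24
#'   is the full 91 x 109 x 91 grid scaled by roughly one quarter per axis.
#' @param male_fraction,college_fraction,scanner_probs,apoe_probs
#'   demographic sampling probabilities.
#' @param icv_mean,icv_sd,icv_sex_shift intracranial volume distribution
#'   (arbitrary units); males are shifted upward by `icv_sex_shift`.
#' @param risk_prevalence named probabilities for the five binary vascular
#'   risk factors.
#' @param risk_age_offsets named planted brain-age accelerations, in years,
#'   per present risk factor.
#' @param sex_obesity_interaction extra years of gap for obese males.
#' @param vrs3plus_male_offset optional explicit extra gap for males with
#'   three or more risk factors (default 0; the high-tier sex effect then
#'   arises from the obesity mechanism alone).
#' @param unhealthy_fraction,unhealthy_gap_offset probability of the
#'   "unhealthy" label and its planted extra gap in years.
#' @param gap_noise_sd standard deviation of the individual gap noise.
#' @param missing_rate missing-at-random rate applied to observed risk
#'   factors and APOE (the truth keeps complete values).
#' @param map_baselines,map_age_slopes,map_quads,noise_sd_map,map_ref_age,
#'   subject_field_sd map rendering model: per-map baseline intensity,
#'   linear age slope per year (voxel-mean scale), quadratic age term (the
#'   MO analogue is non-monotone), i.i.d. voxel noise, the reference age at
#'   which age terms vanish, and the scale of the participant-level shared
#'   field that correlates the five maps.
#' @param cognition_paths list of cognition path coefficients: `b` (gap ->
#'   cognition, per domain, positive = a larger gap lowers cognition),
#'   `cprime` (direct factor -> cognition), `age_slope`, `sex_effect`,
#'   `education_effect`, `domain_noise_sd`, `test_noise_sd`,
#'   `practice_effect` (follow-up improvement).
#' @param longitudinal_fraction fraction of records given a follow-up.
#' @param interval_years mean and sd of the follow-up interval in years.
#' @param followup_gap_drift extra gap drift (years) beyond ageing at
#'   follow-up.
#' @param seed integer seed; identical seed and configuration reproduce
#'   the cohort exactly.
#' @return an object of class `synth_config`.
#' @export
synth_config <- function(n_participants = 500,
                         age_range = c(45, 83),
                         grid_shape = c(24L, 28L, 24L),
                         male_fraction = 0.458,
                         college_fraction = 0.491,
                         scanner_probs = c(1, 1, 1) / 3,
                         apoe_probs = c(0.722, 0.255, 0.023),
                         icv_mean = 1500, icv_sd = 130, icv_sex_shift = 120,
                         risk_prevalence = c(hypertension = 0.504,
                                             diabetes = 0.055,
                                             hypercholesterolemia = 0.245,
                                             obesity = 0.190,
                                             smoking = 0.381),
                         risk_age_offsets = c(hypertension = 0.871,
                                              diabetes = 1.390,
                                              hypercholesterolemia = 0.311,
                                              obesity = 0,
                                              smoking = 0.689),
                         sex_obesity_interaction = 1.023,
                         vrs3plus_male_offset = 0,
                         unhealthy_fraction = 0.091,
                         unhealthy_gap_offset = 0.51,
                         gap_noise_sd = 1,
                         missing_rate = 0,
                         map_baselines = c(FA = 0.42, MD = 0.80, AxD = 1.20,
                                           RD = 0.60, MO = 0.30),
                         map_age_slopes = c(FA = -0.0030, MD = 0.0050,
                                            AxD = 0.0045, RD = 0.0055,
                                            MO = 0),
                         map_quads = c(FA = 0, MD = 0, AxD = 0, RD = 0,
                                       MO = -4e-4),
                         noise_sd_map = c(FA = 0.02, MD = 0.02, AxD = 0.02,
                                          RD = 0.02, MO = 0.02),
                         map_ref_age = 64,
                         subject_field_sd = 0.02,
                         cognition_paths = list(
                           b = c(processing_speed = 0.025, memory = 0.008,
                                 executive = 0.018),
                           cprime = c(hypertension = 0, diabetes = 0,
                                      hypercholesterolemia = 0,
                                      obesity = 0.103, smoking = 0.03),
                           age_slope = -0.03, sex_effect = 0.05,
                           education_effect = 0.2,
                           domain_noise_sd = 0.6, test_noise_sd = 0.5,
                           practice_effect = 0.1),
                         longitudinal_fraction = 0.126,
                         interval_years = c(mean = 2.25, sd = 0.12),
                         followup_gap_drift = 0.1,
                         seed = 1L) {
  named_or <- function(x, nms) {
    x <- unlist(x)
    if (is.null(names(x)) && length(x) == length(nms)) names(x) <- nms
    x
  }
  risk_prevalence <- named_or(risk_prevalence, RISK_FACTORS)
  risk_age_offsets <- named_or(risk_age_offsets, RISK_FACTORS)
  map_baselines <- named_or(map_baselines, MAP_LABELS)
  map_age_slopes <- named_or(map_age_slopes, MAP_LABELS)
  map_quads <- named_or(map_quads, MAP_LABELS)
  noise_sd_map <- named_or(noise_sd_map, MAP_LABELS)
  cfg <- list(n_participants = as.integer(n_participants),
              age_range = as.numeric(age_range),
              grid_shape = as.integer(grid_shape),
              male_fraction = male_fraction,
              college_fraction = college_fraction,
              scanner_probs = scanner_probs / sum(scanner_probs),
              apoe_probs = apoe_probs / sum(apoe_probs),
              icv_mean = icv_mean, icv_sd = icv_sd,
              icv_sex_shift = icv_sex_shift,
              risk_prevalence = risk_prevalence[RISK_FACTORS],
              risk_age_offsets = risk_age_offsets[RISK_FACTORS],
              sex_obesity_interaction = sex_obesity_interaction,
              vrs3plus_male_offset = vrs3plus_male_offset,
              unhealthy_fraction = unhealthy_fraction,
              unhealthy_gap_offset = unhealthy_gap_offset,
              gap_noise_sd = gap_noise_sd,
              missing_rate = missing_rate,
              map_baselines = map_baselines[MAP_LABELS],
              map_age_slopes = map_age_slopes[MAP_LABELS],
              map_quads = map_quads[MAP_LABELS],
              noise_sd_map = noise_sd_map[MAP_LABELS],
              map_ref_age = map_ref_age,
              subject_field_sd = subject_field_sd,
              cognition_paths = cognition_paths,
              longitudinal_fraction = longitudinal_fraction,
              interval_years = as.numeric(interval_years),
              followup_gap_drift = followup_gap_drift,
              seed = as.integer(seed))
  validate_synth_config(cfg)
  class(cfg) <- "synth_config"
  cfg
}

validate_synth_config <- function(cfg) {
  if (cfg$n_participants < 1) stop_wm("n_participants must be positive")
  if (length(cfg$age_range) != 2 || !(cfg$age_range[1] < cfg$age_range[2]))
    stop_wm("age_range must satisfy low < high")
  if (length(cfg$grid_shape) != 3 || any(cfg$grid_shape < 1))
    stop_wm("grid_shape must be three positive voxel counts")
  pr <- cfg$risk_prevalence
  if (anyNA(pr) || any(pr < 0 | pr > 1))
    stop_wm("risk prevalences must all lie in [0, 1]")
  if (anyNA(cfg$risk_age_offsets))
    stop_wm("risk_age_offsets must name all five factors: %s",
            paste(RISK_FACTORS, collapse = ", "))
  if (cfg$missing_rate < 0 || cfg$missing_rate > 1)
    stop_wm("missing_rate must lie in [0, 1]")
  if (cfg$longitudinal_fraction < 0 || cfg$longitudinal_fraction > 1)
    stop_wm("longitudinal_fraction must lie in [0, 1]")
  if (cfg$gap_noise_sd < 0) stop_wm("gap_noise_sd must be non-negative")
  invisible(cfg)
}

#' Names of the seven synthetic cognitive tests
#'
#' Returns the sign-convention table used throughout the package: each test
#' with its domain and whether a higher raw score means worse performance
#' (reaction time, both trail-making tests, and pairs-matching errors are
#' reversed; symbol digit, numeric memory and fluid intelligence are not).
#'
#' @return data.frame with columns `test`, `domain`, `reversed`, `mean`,
#'   `sd` (the raw-score scale used by the generator).
#' @export
cognition_test_table <- function() {
  data.frame(
    test = COG_TESTS,
    domain = c("processing_speed", "processing_speed", "processing_speed",
               "memory", "memory", "executive", "executive"),
    reversed = c(TRUE, TRUE, FALSE, FALSE, TRUE, TRUE, FALSE),
    mean = c(550, 230, 19, 6.8, 4.0, 590, 6.2),
    sd = c(110, 80, 5, 1.5, 2.5, 200, 2.1),
    stringsAsFactors = FALSE)
}

#' Simulate a synthetic baseline cohort with known ground truth
#'
#' Draws demographics, the five binary vascular risk factors (independent
#' Bernoulli at the configured prevalences), APOE, health status, and the
#' latent true brain-age gap: the sum of the active risk offsets, the
#' male-obesity interaction, any explicit male-by-VRS>=3 offset, the
#' unhealthy-group offset, and Gaussian individual noise.  Cognition raw
#' scores are generated with the configured mediation structure.
#'
#' @param config a [synth_config()] object.
#' @return list with `records` (one row per participant-timepoint, the
#'   observable data including any missingness) and `truth` (the latent
#'   ground truth: `true_gap`, complete risk factors, noise-free domain
#'   cognition).
#' @export
simulate_cohort <- function(config) {
  validate_synth_config(config)
  n <- config$n_participants
  with_seed(config$seed, "cohort", {
    id <- sprintf("P%05d", seq_len(n))
    # truncated normal ages centred near the published test-sample mean
    age <- config$age_range[1] - 1
    bad <- rep(TRUE, n)
    while (any(bad)) {
      age[bad] <- rnorm(sum(bad), mean = 64, sd = 7.5)
      bad <- age < config$age_range[1] | age > config$age_range[2]
    }
    sex <- rbinom(n, 1, config$male_fraction)
    scanner <- sample(0:2, n, replace = TRUE, prob = config$scanner_probs)
    icv <- rnorm(n, config$icv_mean, config$icv_sd) +
      sex * config$icv_sex_shift
    education <- rbinom(n, 1, config$college_fraction)
    apoe <- sample(0:2, n, replace = TRUE, prob = config$apoe_probs)
    health <- ifelse(rbinom(n, 1, config$unhealthy_fraction) == 1,
                     "unhealthy", "healthy")
    risk <- sapply(RISK_FACTORS, function(f)
      rbinom(n, 1, config$risk_prevalence[[f]]))
    risk <- matrix(risk, nrow = n,
                   dimnames = list(NULL, RISK_FACTORS))
    count <- rowSums(risk)
    true_gap <- as.numeric(risk %*% config$risk_age_offsets) +
      sex * risk[, "obesity"] * config$sex_obesity_interaction +
      sex * (count >= 3) * config$vrs3plus_male_offset +
      (health == "unhealthy") * config$unhealthy_gap_offset +
      rnorm(n, 0, config$gap_noise_sd)

    records <- data.frame(participant_id = id, timepoint = "baseline",
                          age = age, sex = sex, scanner = scanner,
                          icv = icv, education_college = education,
                          apoe_e4 = apoe, health_status = health,
                          stringsAsFactors = FALSE)
    records <- cbind(records, as.data.frame(risk))
    truth <- data.frame(participant_id = id, true_gap = true_gap,
                        stringsAsFactors = FALSE)
    truth <- cbind(truth,
                   setNames(as.data.frame(risk), paste0("true_", RISK_FACTORS)))

    # observation-level missingness; the truth keeps complete values
    if (config$missing_rate > 0) {
      for (f in c(RISK_FACTORS, "apoe_e4")) {
        miss <- rbinom(n, 1, config$missing_rate) == 1
        records[[f]][miss] <- NA
      }
    }

    cog <- simulate_cognition(records, truth, config, .seeded = TRUE)
    records <- cbind(records, cog)
    truth <- cbind(truth, attr(cog, "latent"))
    list(records = records, truth = truth)
  })
}

#' Simulate raw cognition scores with a planted mediation structure
#'
#' Each latent domain score is `-b * true_gap - sum(c'_k x_k) +
#' age/sex/education terms + noise`, oriented so that higher means better;
#' the seven raw test scores are affine transforms of their domain latent
#' (with per-test noise), sign-flipped for tests where a lower raw score is
#' better.
#'
#' @param records data.frame of participant records (true risk factors are
#'   taken from `truth` so observation missingness does not leak into the
#'   generative model).
#' @param truth matching ground-truth data.frame from [simulate_cohort()].
#' @param config a [synth_config()].
#' @param followup logical: apply the configured practice effect.
#' @param .seeded internal; set when the caller already manages the RNG.
#' @return data.frame of seven raw test scores with attribute `latent`
#'   (noise-free per-domain values).
#' @export
simulate_cognition <- function(records, truth, config, followup = FALSE,
                               .seeded = FALSE) {
  if (!identical(records$participant_id, truth$participant_id))
    stop_wm("records and truth must refer to the same participants, in order")
  run <- function() {
    p <- config$cognition_paths
    n <- nrow(records)
    risk <- as.matrix(truth[paste0("true_", RISK_FACTORS)])
    direct <- as.numeric(risk %*% p$cprime[RISK_FACTORS])
    base <- p$age_slope * (records$age - 64) +
      p$sex_effect * records$sex +
      p$education_effect * records$education_college +
      if (followup) p$practice_effect else 0
    tab <- cognition_test_table()
    domains <- unique(tab$domain)
    latent_free <- sapply(domains, function(d)
      base - p$b[[d]] * truth$true_gap - direct)
    latent_free <- matrix(latent_free, nrow = n,
                          dimnames = list(NULL, paste0("true_cog_", domains)))
    latent <- latent_free +
      matrix(rnorm(n * length(domains), 0, p$domain_noise_sd),
             nrow = n)
    raw <- lapply(seq_len(nrow(tab)), function(i) {
      d <- match(tab$domain[i], domains)
      z <- latent[, d] + rnorm(n, 0, p$test_noise_sd)
      sgn <- if (tab$reversed[i]) -1 else 1
      tab$mean[i] + tab$sd[i] * sgn * z
    })
    raw <- as.data.frame(setNames(raw, tab$test))
    attr(raw, "latent") <- as.data.frame(latent_free)
    raw
  }
  if (.seeded) run()
  else with_seed(config$seed, paste0("cognition", if (followup) ":fu"), run())
}

#' Assign train / validation / test split labels
#'
#' Healthy participants are divided into the three sets at the requested
#' fractions (exact counts, randomised assignment); participants flagged
#' unhealthy are always placed in the test set, mirroring a design where
#' the age model is trained only on healthy individuals.
#'
#' @param records data.frame with `health_status`.
#' @param fractions named numeric (train, validation, test) summing to 1.
#' @param seed integer seed.
#' @return character vector of labels aligned with `records` rows.
#' @export
make_splits <- function(records,
                        fractions = c(train = 0.6, validation = 0.2,
                                      test = 0.2),
                        seed = 1L) {
  if (abs(sum(fractions) - 1) > 1e-9)
    stop_wm("split fractions must sum to 1 (got %.12f)", sum(fractions))
  if (is.null(names(fractions)))
    names(fractions) <- c("train", "validation", "test")
  lab <- rep("test", nrow(records))
  healthy <- which(records$health_status == "healthy")
  nh <- length(healthy)
  counts <- diff(c(0, floor(cumsum(fractions) * nh)))
  with_seed(seed, "splits", {
    perm <- sample(healthy)
    lab[perm] <- rep(names(fractions), counts)
  })
  lab
}

#' Create the longitudinal follow-up subset
#'
#' A configured fraction of the supplied baseline records receives a
#' follow-up visit: age advances by a truncated-positive normal interval
#' (default 2.25 +/- 0.12 years), the true gap additionally drifts by
#' `followup_gap_drift`, risk factors are carried forward, and cognition is
#' re-simulated at the new age and gap with the practice effect applied.
#'
#' @param records,truth baseline cohort (typically the test subset).
#' @param config a [synth_config()].
#' @return list with follow-up `records` and `truth` (possibly zero rows);
#'   `timepoint` is `"followup"`.
#' @export
make_longitudinal_subset <- function(records, truth, config) {
  if (config$longitudinal_fraction < 0 || config$longitudinal_fraction > 1)
    stop_wm("longitudinal_fraction must lie in [0, 1]")
  base <- which(records$timepoint == "baseline")
  with_seed(config$seed, "longitudinal", {
    take <- base[runif(length(base)) < config$longitudinal_fraction]
    rec <- records[take, , drop = FALSE]
    tru <- truth[take, , drop = FALSE]
    if (nrow(rec) == 0) {
      return(list(records = rec[0, ], truth = tru[0, ]))
    }
    iv <- rnorm(nrow(rec), config$interval_years[1], config$interval_years[2])
    while (any(iv <= 0))
      iv[iv <= 0] <- rnorm(sum(iv <= 0), config$interval_years[1],
                           config$interval_years[2])
    rec$timepoint <- "followup"
    rec$age <- rec$age + iv
    rec$interval <- iv
    tru$true_gap <- tru$true_gap + config$followup_gap_drift
    cog <- simulate_cognition(rec, tru, config, followup = TRUE,
                              .seeded = TRUE)
    rec[names(cog)] <- cog
    tru[names(attr(cog, "latent"))] <- attr(cog, "latent")
    rownames(rec) <- rownames(tru) <- NULL
    list(records = rec, truth = tru)
  })
}
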