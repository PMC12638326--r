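# End-to-end orchestration: simulate -> split -> train -> predict ->
# correct -> analyse, with every stage runnable in isolation from its
# persisted intermediates.  One configuration object governs everything;
# all randomness is derived from its single seed.  Tables are written as
# CSV, the configuration as YAML, and the run summary as JSON.

#' Pipeline run configuration
#'
#' @param synth a [synth_config()].
#' @param network a [network_spec()] (its grid must match the synthetic
#'   grid).
#' @param train list of training hyperparameters: `epochs`, `batch_size`,
#'   `lr`, `loss`.
#' @param fractions train/validation/test fractions.
#' @param n_boot mediation bootstrap samples.
#' @param run_longitudinal toggle for the longitudinal stage.
#' @param seed global seed; every stage derives its stream from it.
#' @return object of class `run_config`.
#' @export
run_config <- function(synth = synth_config(),
                       network = desk_network_spec(input_shape = synth$grid_shape),
                       train = list(epochs = 12, batch_size = 16,
                                    lr = 0.01, loss = "l1"),
                       fractions = c(train = 0.6, validation = 0.2,
                                     test = 0.2),
                       n_boot = 1000,
                       run_longitudinal = TRUE,
                       seed = 1L) {
  if (!identical(as.integer(network$input_shape),
                 as.integer(synth$grid_shape)))
    stop_wm("network input shape must match the synthetic grid")
  structure(list(synth = synth, network = network, train = train,
                 fractions = fractions, n_boot = n_boot,
                 run_longitudinal = isTRUE(run_longitudinal),
                 seed = as.integer(seed)),
            class = "run_config")
}

#' Small smoke-test preset of the pipeline configuration
#'
#' @param n_participants,grid_shape,epochs reduced problem sizes.
#' @param seed global seed.
#' @return a [run_config()].
#' @export
smoke_run_config <- function(n_participants = 120,
                             grid_shape = c(16L, 16L, 16L),
                             epochs = 2, seed = 1L) {
  sc <- synth_config(n_participants = n_participants,
                     grid_shape = grid_shape, seed = seed)
  run_config(synth = sc,
             network = network_spec(input_shape = grid_shape,
                                    conv_channels = c(4L, 8L, 8L, 8L, 8L, 8L),
                                    feature_dim = 8L),
             train = list(epochs = epochs, batch_size = 16, lr = 0.01,
                          loss = "l1"),
             fractions = c(train = 0.4, validation = 0.2, test = 0.4),
             n_boot = 200, seed = seed)
}

config_hash <- function(config) {
  s <- yaml::as.yaml(unclass_deep(config))
  h <- 0
  for (k in utf8ToInt(s)) h <- (h * 131 + k) %% 2147483647
  sprintf("%08x", as.integer(h))
}

unclass_deep <- function(x) {
  if (is.list(x)) lapply(unclass(x), unclass_deep)
  else if (!is.null(names(x)) && length(x) > 1) as.list(x)  # keep names in YAML
  else x
}

#' Write / read a run configuration as YAML
#'
#' @param config a [run_config()].
#' @param path YAML file path.
#' @return `read_run_config` returns the reconstructed `run_config`.
#' @export
write_run_config <- function(config, path) {
  yaml::write_yaml(unclass_deep(config), path)
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  raw <- yaml::read_yaml(path)
  # YAML maps come back as lists; named numeric vectors must be restored
  vecify <- function(x) {
    if (is.list(x) && length(x) &&
        all(vapply(x, function(e) is.numeric(e) && length(e) == 1, TRUE)))
      unlist(x) else x
  }
  sargs <- lapply(raw$synth, vecify)
  sargs$cognition_paths <- lapply(raw$synth$cognition_paths, vecify)
  sargs <- sargs[names(sargs) %in% names(formals(synth_config))]
  sy <- do.call(synth_config, sargs)
  nw <- network_spec(input_shape = unlist(raw$network$input_shape),
                     conv_channels = unlist(raw$network$conv_channels),
                     feature_dim = raw$network$feature_dim,
                     dropout_rate = raw$network$dropout_rate,
                     normalise_input = raw$network$normalise_input)
  run_config(synth = sy, network = nw, train = raw$train,
             fractions = unlist(raw$fractions), n_boot = raw$n_boot,
             run_longitudinal = raw$run_longitudinal, seed = raw$seed)
}

log_stage <- function(out_dir, stage, msg = "done") {
  line <- sprintf("[%s] %s: %s", format(Sys.time(), "%H:%M:%S"), stage, msg)
  message(line)
  cat(line, "\n", file = file.path(out_dir, "run.log"), append = TRUE)
}

#' Stage 1: simulate the cohort and write maps + manifest
#'
#' @param config a [run_config()].
#' @param out_dir run directory (created if needed).
#' @return path of the written manifest, invisibly.
#' @export
pipeline_simulate <- function(config, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  write_run_config(config, file.path(out_dir, "config.yaml"))
  cohort <- simulate_cohort(config$synth)
  records <- cohort$records
  records$split <- make_splits(records, config$fractions,
                               seed = derive_seed(config$seed, "split"))
  truth <- cohort$truth
  if (config$run_longitudinal) {
    test_rows <- records$split == "test"
    fu <- make_longitudinal_subset(records[test_rows, ],
                                   truth[test_rows, ], config$synth)
    if (nrow(fu$records)) {
      fu$records$split <- "test"
      records$interval <- NA_real_
      records <- rbind(records, fu$records[names(records)])
      truth <- rbind(truth, fu$truth)
    }
  }
  manifest <- render_cohort_maps(records, truth, config$synth,
                                 file.path(out_dir, "maps"))
  write_manifest(manifest, file.path(out_dir, "manifest.csv"))
  write.csv(truth, file.path(out_dir, "truth.csv"), row.names = FALSE)
  log_stage(out_dir, "simulate",
            sprintf("%d records (%d follow-up)", nrow(manifest),
                    sum(manifest$timepoint == "followup")))
  invisible(file.path(out_dir, "manifest.csv"))
}

load_split_volumes <- function(manifest, map) {
  lapply(seq_len(nrow(manifest)), function(i)
    as.array(RNifti::readNifti(manifest[[paste0("path_", map)]][i])))
}

#' Stage 2: train the five single-map networks
#'
#' @param config a [run_config()].
#' @param out_dir run directory containing `manifest.csv`.
#' @return invisible path of the checkpoint directory.
#' @export
pipeline_train <- function(config, out_dir) {
  mpath <- file.path(out_dir, "manifest.csv")
  if (!file.exists(mpath)) stop_wm("expected manifest not found: %s", mpath)
  manifest <- read_manifest(mpath)
  tr <- manifest[manifest$split == "train" &
                   manifest$timepoint == "baseline", ]
  ck_dir <- file.path(out_dir, "checkpoints")
  dir.create(ck_dir, showWarnings = FALSE)
  for (m in MAP_LABELS) {
    vols <- load_split_volumes(tr, m)
    model <- train_single_map(config$network, vols, tr$age, tr$sex,
                              tr$scanner,
                              epochs = config$train$epochs,
                              batch_size = config$train$batch_size,
                              lr = config$train$lr,
                              loss = config$train$loss,
                              seed = derive_seed(config$seed,
                                                 paste0("train:", m)))
    model$map_label <- m
    saveRDS(model, file.path(ck_dir, paste0(m, ".rds")))
    jsonlite::write_json(list(map = m, spec = unclass_deep(model$spec),
                              train = config$train,
                              final_loss = tail(model$training_log$loss, 1),
                              config_hash = config_hash(config)),
                         file.path(ck_dir, paste0(m, ".json")),
                         auto_unbox = TRUE)
    log_stage(out_dir, "train",
              sprintf("%s final loss %.3f", m,
                      tail(model$training_log$loss, 1)))
  }
  invisible(ck_dir)
}

#' Stage 3: extract features, fit the fusion head, predict raw ages
#'
#' @param config a [run_config()].
#' @param out_dir run directory with checkpoints.
#' @return invisible path of the predictions table.
#' @export
pipeline_predict <- function(config, out_dir) {
  ck_dir <- file.path(out_dir, "checkpoints")
  models <- lapply(MAP_LABELS, function(m) {
    p <- file.path(ck_dir, paste0(m, ".rds"))
    if (!file.exists(p)) stop_wm("expected checkpoint not found: %s", p)
    readRDS(p)
  })
  names(models) <- MAP_LABELS
  manifest <- read_manifest(file.path(out_dir, "manifest.csv"))
  feats <- list()
  single <- list()
  for (m in MAP_LABELS) {
    vols <- load_split_volumes(manifest, m)
    ev <- sfcn_eval(models[[m]], vols, manifest$sex, manifest$scanner)
    feats[[m]] <- t(ev$features)
    single[[paste0("y_hat_", m)]] <- ev$yhat
  }
  tr <- manifest$split == "train" & manifest$timepoint == "baseline"
  head <- fit_fusion_head(lapply(feats, function(f) f[tr, , drop = FALSE]),
                          manifest[tr, c("sex", "scanner", "icv")],
                          manifest$age[tr])
  saveRDS(head, file.path(ck_dir, "fusion_head.rds"))
  preds <- data.frame(participant_id = manifest$participant_id,
                      timepoint = manifest$timepoint,
                      split = manifest$split, y = manifest$age,
                      y_hat = predict_fused(head, feats,
                                            manifest[c("sex", "scanner",
                                                       "icv")]))
  preds <- cbind(preds, as.data.frame(single))
  write.csv(preds, file.path(out_dir, "predictions_raw.csv"),
            row.names = FALSE)
  log_stage(out_dir, "predict", sprintf("%d predictions", nrow(preds)))
  invisible(file.path(out_dir, "predictions_raw.csv"))
}

#' Stage 4: bias correction and WMBAG
#'
#' Fits the bias model on baseline validation predictions only and applies
#' it unchanged to every row (including follow-up scans).
#'
#' @param out_dir run directory with `predictions_raw.csv`.
#' @return invisible path of the corrected prediction table.
#' @export
pipeline_correct <- function(out_dir) {
  ppath <- file.path(out_dir, "predictions_raw.csv")
  if (!file.exists(ppath))
    stop_wm("expected raw predictions not found: %s", ppath)
  preds <- read.csv(ppath, stringsAsFactors = FALSE,
                    colClasses = c(participant_id = "character"))
  val <- preds$split == "validation" & preds$timepoint == "baseline"
  bm <- fit_bias(preds$y[val], preds$y_hat[val])
  preds$y_hat_co <- apply_bias(preds$y_hat, bm)
  preds$wmbag <- compute_gap(preds$y, preds$y_hat_co)
  write.csv(preds, file.path(out_dir, "age_predictions.csv"),
            row.names = FALSE)
  jsonlite::write_json(list(alpha = bm$alpha, beta = bm$beta,
                            n_fit = bm$n_fit, fit_r2 = bm$fit_r2),
                       file.path(out_dir, "bias_model.json"),
                       auto_unbox = TRUE, digits = NA)
  log_stage(out_dir, "correct",
            sprintf("alpha %.3f beta %.1f", bm$alpha, bm$beta))
  invisible(file.path(out_dir, "age_predictions.csv"))
}

#' Stage 5: statistical analyses
#'
#' Merges corrected predictions with the manifest, derives the VRS and
#' cognition composites, and runs the ANCOVA, the association models
#' (1a/1b, 2a, 2b-f), the WMBAG-cognition regressions, the mediation
#' battery and (optionally) the longitudinal change analyses; writes all
#' result tables and a machine-readable summary.
#'
#' @param config a [run_config()].
#' @param out_dir run directory with `age_predictions.csv`.
#' @return the summary list, invisibly.
#' @export
pipeline_analyse <- function(config, out_dir) {
  apath <- file.path(out_dir, "age_predictions.csv")
  if (!file.exists(apath))
    stop_wm("expected corrected predictions not found: %s", apath)
  preds <- read.csv(apath, stringsAsFactors = FALSE,
                    colClasses = c(participant_id = "character"))
  manifest <- read_manifest(file.path(out_dir, "manifest.csv"))
  df <- merge(manifest, preds[c("participant_id", "timepoint", "y_hat",
                                "y_hat_co", "wmbag")],
              by = c("participant_id", "timepoint"))
  df <- cbind(df, compute_vrs(df[RISK_FACTORS]))
  base <- df[df$timepoint == "baseline", ]
  cg <- standardise_cognition(base[cognition_test_table()$test])
  base <- cbind(base, cg)
  test <- base[base$split == "test", ]

  perf <- performance(test$age, test$y_hat_co)
  anc <- ancova_group_difference(test)
  m1a <- fit_model_1a(test); m1b <- fit_model_1b(test)
  m2a <- fit_model_2a(test)
  # per-factor sex-moderation models and the mediation battery can be
  # degenerate in very small runs (e.g. no male diabetics); record the
  # failure instead of halting the stage
  m2bf <- list()
  for (fac in RISK_FACTORS) {
    m2bf[[fac]] <- tryCatch(fit_models_2b_f(test, factors = fac)[[1]],
                            error = function(e) {
                              log_stage(out_dir, "analyse",
                                        sprintf("model 2b-f %s skipped: %s",
                                                fac, conditionMessage(e)))
                              NULL
                            })
  }
  m2bf <- Filter(Negate(is.null), m2bf)
  cog <- cognition_regressions(test)
  med <- tryCatch(
    mediation_battery(test, n_boot = config$n_boot,
                      seed = derive_seed(config$seed, "mediation")),
    error = function(e) {
      log_stage(out_dir, "analyse",
                sprintf("mediation battery skipped: %s",
                        conditionMessage(e)))
      data.frame()
    })
  tab_dir <- file.path(out_dir, "tables")
  dir.create(tab_dir, showWarnings = FALSE)
  wr <- function(x, nm) write.csv(x, file.path(tab_dir, nm),
                                  row.names = FALSE)
  wr(m1a$terms, "model_1a.csv"); wr(m1b$terms, "model_1b.csv")
  wr(m2a$terms, "model_2a.csv")
  wr(do.call(rbind, lapply(names(m2bf), function(f)
    cbind(factor = f, m2bf[[f]]$terms))), "models_2b_f.csv")
  wr(cog$table, "cognition_regressions.csv")
  wr(med, "mediation_battery.csv")

  longi <- NULL
  if (config$run_longitudinal &&
      any(df$timepoint == "followup")) {
    fu <- df[df$timepoint == "followup", ]
    fu <- cbind(fu, standardise_cognition(fu[cognition_test_table()$test],
                                          base[cognition_test_table()$test]))
    chg <- change_scores(base, fu)
    pt <- paired_t(chg$delta_y_hat_co)
    longi <- change_regressions_and_mediation(
      chg, n_boot = config$n_boot,
      seed = derive_seed(config$seed, "long-mediation"))
    wr(chg, "change_scores.csv")
    wr(longi$mediation_table, "change_mediation.csv")
    longi$paired_t <- pt
  }
  summary <- list(
    config_hash = config_hash(config), seed = config$seed,
    n_records = nrow(df), n_test = nrow(test),
    performance = perf,
    bias = jsonlite::read_json(file.path(out_dir, "bias_model.json")),
    ancova = anc[c("difference", "ci_lower", "ci_upper", "p")],
    bonferroni_alpha = cog$alpha_corrected,
    longitudinal = if (!is.null(longi))
      list(paired_t = longi$paired_t,
           pct_increased = longi$pct_increased) else NULL,
    versions = list(package = as.character(utils::packageVersion("wmbrainage")),
                    r = paste(R.version$major, R.version$minor, sep = ".")))
  summary <- Filter(Negate(is.null), summary)
  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = 10, pretty = TRUE)
  log_stage(out_dir, "analyse", "summary written")
  invisible(summary)
}

#' Run the full pipeline
#'
#' Executes simulate, train, predict, correct and analyse in order; a
#' stage failure halts the run with the stage name while earlier partial
#' outputs remain on disk.
#'
#' @param config a [run_config()].
#' @param out_dir run directory.
#' @return the run summary list, invisibly.
#' @export
run_pipeline <- function(config, out_dir) {
  stages <- list(simulate = function() pipeline_simulate(config, out_dir),
                 train = function() pipeline_train(config, out_dir),
                 predict = function() pipeline_predict(config, out_dir),
                 correct = function() pipeline_correct(out_dir),
                 analyse = function() pipeline_analyse(config, out_dir))
  out <- NULL
  for (nm in names(stages)) {
    out <- tryCatch(stages[[nm]](),
                    error = function(e)
                      stop_wm("pipeline stage '%s' failed: %s", nm,
                              conditionMessage(e)))
  }
  invisible(out)
}
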