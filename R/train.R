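#' Train a single-map age-regression network
#'
#' Minibatch training with Adam; the default L1 loss directly optimises
#' mean absolute error (squared error is available as an alternative).
#' The block-8 intercept is initialised to the training-mean age so the
#' network starts from the no-information prediction.  Training is
#' deterministic for a fixed seed under single-threaded execution.
#'
#' @param model an untrained [build_network()] model, or a [network_spec()]
#'   (a model is then built with `seed`).
#' @param volumes list of 3D arrays (or a voxel-by-participant matrix) on
#'   the spec grid.
#' @param age,sex,scanner numeric vectors, one entry per volume.
#' @param epochs,batch_size,lr training hyperparameters.
#' @param loss `"l1"` (default) or `"l2"`.
#' @param seed integer seed for shuffling and dropout.
#' @param verbose print the per-epoch loss.
#' @return the trained `sfcn_model`, with `training_log` (mean epoch loss).
#' @export
train_single_map <- function(model, volumes, age, sex, scanner,
                             epochs = 12, batch_size = 16, lr = 0.01,
                             loss = c("l1", "l2"), seed = 1L,
                             verbose = FALSE) {
  loss <- match.arg(loss)
  if (inherits(model, "network_spec"))
    model <- build_network(model, seed = seed)
  stopifnot(inherits(model, "sfcn_model"))
  spec <- model$spec
  n <- if (is.list(volumes)) length(volumes) else ncol(volumes)
  if (n < 2)
    stop_wm("training requires at least two participants (got %d)", n)
  if (!all(is.finite(age)) || length(age) != n)
    stop_wm("ages must be finite, one per volume")
  X <- stack_volumes(volumes, spec)          # 1 x (V*n)
  V <- prod(spec$input_shape)
  cov <- rbind(sex = as.numeric(sex), scanner = as.numeric(scanner))
  model$params$b8 <- mean(age)
  st <- adam_init(model$params)
  log_loss <- numeric(epochs)
  with_seed(seed, "train", {
    for (ep in seq_len(epochs)) {
      ord <- sample.int(n)
      tot <- 0
      for (b in split(ord, ceiling(seq_along(ord) / batch_size))) {
        N <- length(b)
        idx <- as.numeric(outer(seq_len(V), (b - 1) * V, "+"))
        xb <- X[, idx, drop = FALSE]
        fw <- sfcn_forward(model, xb, cov[, b, drop = FALSE], N,
                           training = TRUE, keep_cache = TRUE)
        model$params <- fw$params      # running BN stats
        r <- fw$yhat - age[b]
        lb <- if (loss == "l1") mean(abs(r)) else mean(r^2)
        if (!is.finite(lb))
          stop_wm("training aborted: non-finite loss at epoch %d (lr too high or degenerate input)", ep)
        dy <- if (loss == "l1") sign(r) / N else 2 * r / N
        gr <- sfcn_backward(model, fw, dy, N)
        up <- adam_step(model$params, gr, st, lr)
        model$params <- up$params
        st <- up$state
        tot <- tot + lb * N
      }
      log_loss[ep] <- tot / n
      if (verbose)
        message(sprintf("epoch %d/%d  %s loss %.3f", ep, epochs, loss,
                        log_loss[ep]))
    }
  })
  model$trained <- TRUE
  model$training_log <- data.frame(epoch = seq_len(epochs), loss = log_loss)
  model$loss <- loss
  model
}

# Internal batched evaluation-mode forward (running BN stats, no dropout).
sfcn_eval <- function(model, volumes, sex = NULL, scanner = NULL,
                      chunk = 64L) {
  spec <- model$spec
  X <- stack_volumes(volumes, spec)
  V <- prod(spec$input_shape)
  n <- ncol(X) / V
  if (is.null(sex)) sex <- numeric(n)
  if (is.null(scanner)) scanner <- numeric(n)
  cov <- rbind(sex = as.numeric(sex), scanner = as.numeric(scanner))
  yhat <- numeric(n)
  feats <- matrix(NA_real_, spec$feature_dim, n)
  for (b in split(seq_len(n), ceiling(seq_len(n) / chunk))) {
    idx <- as.numeric(outer(seq_len(V), (b - 1) * V, "+"))
    fw <- sfcn_forward(model, X[, idx, drop = FALSE],
                       cov[, b, drop = FALSE], length(b), training = FALSE)
    yhat[b] <- fw$yhat
    feats[, b] <- fw$features
  }
  list(yhat = yhat, features = feats)
}

#' Extract the block-7 feature vector for one map
#'
#' Runs blocks 1-7 in evaluation mode (dropout disabled, running
#' batch-norm statistics): deterministic for fixed parameters and input.
#' Covariates are not part of this vector; they are concatenated later by
#' the fusion head.
#'
#' @param model a trained (or built) `sfcn_model`.
#' @param volume a 3D array on the spec grid, or a `dwi_map_set` (the
#'   model's `map_label` selects the volume).
#' @return numeric vector of length `spec$feature_dim`.
#' @export
extract_features <- function(model, volume) {
  stopifnot(inherits(model, "sfcn_model"))
  if (inherits(volume, "dwi_map_set")) {
    if (is.na(model$map_label))
      stop_wm("model has no map_label; pass the volume array directly")
    volume <- volume$volumes[[model$map_label]]
  }
  if (!identical(dim(volume), as.integer(model$spec$input_shape)))
    stop_wm("volume grid %s does not match the network input shape %s",
            paste(dim(volume), collapse = "x"),
            paste(model$spec$input_shape, collapse = "x"))
  as.numeric(sfcn_eval(model, list(volume))$features)
}

#' Predict ages with a single-map network
#'
#' @param model trained `sfcn_model`.
#' @param volumes list of 3D arrays or voxel-by-participant matrix.
#' @param sex,scanner covariates, one per volume.
#' @return numeric vector of raw predicted ages (years).
#' @export
predict_single_map <- function(model, volumes, sex, scanner) {
  sfcn_eval(model, volumes, sex, scanner)$yhat
}

#' Fit the block-8 fusion head over five feature sets
#'
#' Ordinary least squares of age on the concatenated
#' `feature_dim * 5 + 3` vector (five per-map block-7 feature vectors plus
#' sex, scanner and ICV).  The per-map networks are left untouched.  If
#' the design is rank deficient (possible when the feature count exceeds
#' the sample size), a ridge fallback is used and the regularisation
#' strength is recorded on the returned object.
#'
#' @param features list of five participant-by-`feature_dim` matrices, in
#'   FA/MD/AxD/RD/MO order.
#' @param covariates data.frame with columns `sex`, `scanner`, `icv`.
#' @param age numeric vector of chronological ages.
#' @param ridge_lambda ridge strength used only on rank deficiency.
#' @return object of class `fusion_head` with `coef` (length
#'   `feature_dim*5 + 3`), `intercept`, `feature_dim` and `ridge_lambda`
#'   (NA when plain OLS was used).
#' @export
fit_fusion_head <- function(features, covariates, age, ridge_lambda = 1e-2) {
  if (length(features) != 5)
    stop_wm("five feature matrices are required (got %d)", length(features))
  fd <- unique(vapply(features, ncol, 1L))
  if (length(fd) != 1)
    stop_wm("feature matrices disagree on feature_dim")
  need <- c("sex", "scanner", "icv")
  if (!all(need %in% names(covariates)))
    stop_wm("fusion covariates must include sex, scanner and icv")
  X <- cbind(do.call(cbind, features),
             sex = covariates$sex, scanner = covariates$scanner,
             icv = covariates$icv)
  if (ncol(X) != 5 * fd + 3)
    stop_wm("fused input has %d entries but feature_dim*5 + 3 = %d",
            ncol(X), 5 * fd + 3)
  Xi <- cbind(1, X)
  qrX <- qr(Xi)
  if (qrX$rank == ncol(Xi)) {
    beta <- qr.coef(qrX, age)
    lambda <- NA_real_
  } else {
    # ridge on the slopes only; intercept left unpenalised via centring
    xm <- colMeans(X)
    Xc <- sweep(X, 2, xm)
    lambda <- ridge_lambda * mean(colSums(Xc^2)) / nrow(X)
    if (!is.finite(lambda) || lambda <= 0) lambda <- ridge_lambda
    A <- crossprod(Xc) + diag(lambda * nrow(X), ncol(X))
    bs <- solve(A, crossprod(Xc, age - mean(age)))
    beta <- c(mean(age) - sum(xm * bs), bs)
  }
  structure(list(coef = beta[-1], intercept = beta[1], feature_dim = fd,
                 ridge_lambda = lambda, n_fit = nrow(X)),
            class = "fusion_head")
}

#' Predict the fused white matter brain age
#'
#' Extracts the five block-7 feature vectors from the per-map networks and
#' applies the linear fusion head with the three covariates.
#'
#' @param models named list of five trained `sfcn_model`s (FA..MO).
#' @param head a [fit_fusion_head()] object.
#' @param map_set a `dwi_map_set`, or a named list of five 3D arrays.
#' @param sex,scanner,icv scalar covariates.
#' @return scalar raw predicted age in years.
#' @export
predict_age <- function(models, head, map_set, sex, scanner, icv) {
  vols <- if (inherits(map_set, "dwi_map_set")) map_set$volumes else map_set
  missing_maps <- setdiff(MAP_LABELS, names(vols))
  if (length(missing_maps))
    stop_wm("map set is missing: %s", paste(missing_maps, collapse = ", "))
  if (!all(MAP_LABELS %in% names(models)))
    stop_wm("models must be a named list covering %s",
            paste(MAP_LABELS, collapse = ", "))
  feats <- lapply(MAP_LABELS, function(m)
    matrix(extract_features(models[[m]], vols[[m]]), nrow = 1))
  predict_fused(head, feats,
                data.frame(sex = sex, scanner = scanner, icv = icv))
}

#' Apply a fusion head to precomputed feature matrices
#'
#' @param head a [fit_fusion_head()] object.
#' @param features list of five participant-by-`feature_dim` matrices.
#' @param covariates data.frame with `sex`, `scanner`, `icv`.
#' @return numeric vector of raw predicted ages.
#' @export
predict_fused <- function(head, features, covariates) {
  stopifnot(inherits(head, "fusion_head"))
  X <- cbind(do.call(cbind, features),
             covariates$sex, covariates$scanner, covariates$icv)
  if (ncol(X) != length(head$coef))
    stop_wm("fused input has %d entries but the head expects %d",
            ncol(X), length(head$coef))
  as.numeric(X %*% head$coef + head$intercept)
}
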