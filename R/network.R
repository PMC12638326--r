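# Construction, forward and backward passes of the eight-block network.
#
# Feature maps are C x (V*N) matrices (see src/conv3d_kernels.cpp).
# Convolutions are im2col + GEMM; batch normalisation uses batch
# statistics in training mode and running statistics in evaluation mode.

BN_EPS <- 1e-5
BN_MOMENTUM <- 0.1

#' Build an untrained single-map network
#'
#' Initialises all eight blocks: He-scaled convolution and FC weights,
#' unit-gamma/zero-beta batch-norm parameters, and a zero block-8 head
#' (its intercept is set to the training-mean age when training starts).
#'
#' @param spec a [network_spec()].
#' @param seed integer seed for the weight initialisation.
#' @param map_label optional label of the map this network will model.
#' @return object of class `sfcn_model`.
#' @export
build_network <- function(spec, seed = 1L, map_label = NA_character_) {
  stopifnot(inherits(spec, "network_spec"))
  tr <- shape_trace(spec)
  flat <- attr(tr, "flat_dim")
  n_cov <- length(spec$covariates_single)
  with_seed(seed, "init", {
    params <- list()
    cin <- 1L
    for (k in 1:6) {
      cout <- spec$conv_channels[k]
      fan <- if (k < 6) 27L * cin else cin
      params[[paste0("W", k)]] <- matrix(rnorm(fan * cout, 0, sqrt(2 / fan)),
                                         fan, cout)
      params[[paste0("bb", k)]] <- numeric(cout)
      params[[paste0("g", k)]] <- rep(1, cout)
      params[[paste0("be", k)]] <- numeric(cout)
      params[[paste0("rm", k)]] <- numeric(cout)
      params[[paste0("rv", k)]] <- rep(1, cout)
      cin <- cout
    }
    params$W7 <- matrix(rnorm(flat * spec$feature_dim, 0, sqrt(2 / flat)),
                        flat, spec$feature_dim)
    params$b7 <- numeric(spec$feature_dim)
    params$w8 <- matrix(0, spec$feature_dim + n_cov, 1)
    params$b8 <- 0
    structure(list(spec = spec, params = params, map_label = map_label,
                   trained = FALSE, training_log = NULL),
              class = "sfcn_model")
  })
}

# volumes -> 1 x (V*N) input matrix, with optional per-volume z-scoring
stack_volumes <- function(vols, spec) {
  if (is.list(vols)) {
    V <- prod(spec$input_shape)
    vols <- vapply(vols, function(v) {
      if (!identical(dim(v), as.integer(spec$input_shape)))
        stop_wm("volume grid %s does not match the network input shape %s",
                paste(dim(v), collapse = "x"),
                paste(spec$input_shape, collapse = "x"))
      as.numeric(v)
    }, numeric(V))
    vols <- matrix(vols, nrow = V)
  }
  if (nrow(vols) != prod(spec$input_shape))
    stop_wm("volume matrix has %d voxels but the spec implies %d",
            nrow(vols), prod(spec$input_shape))
  if (spec$normalise_input) {
    mu <- colMeans(vols)
    sdv <- sqrt(pmax(colMeans(vols^2) - mu^2, 1e-12))
    vols <- sweep(sweep(vols, 2, mu), 2, sdv, "/")
  }
  matrix(as.numeric(vols), nrow = 1)
}

bn_forward <- function(Z, g, be, rm, rv, training) {
  if (training) {
    mu <- rowMeans(Z)
    va <- rowMeans(Z^2) - mu^2
  } else {
    mu <- rm; va <- rv
  }
  inv <- 1 / sqrt(va + BN_EPS)
  xhat <- (Z - mu) * inv
  list(out = g * xhat + be, xhat = xhat, inv = inv, mu = mu, va = va)
}

bn_backward <- function(dY, xhat, inv, g) {
  list(dZ = (g * inv) * (dY - rowMeans(dY) - xhat * rowMeans(dY * xhat)),
       dg = rowSums(dY * xhat), dbe = rowSums(dY))
}

# Forward pass through blocks 1-8 for a batch.
# x1: 1 x (V*N) stacked input; cov: n_cov x N covariate matrix.
# Returns yhat, features, updated running stats and (optionally) caches.
sfcn_forward <- function(model, x1, cov, N, training = FALSE,
                         keep_cache = FALSE, dropout_mask = NULL) {
  p <- model$params
  spec <- model$spec
  x <- x1
  dims <- c(1L, spec$input_shape, N)
  caches <- if (keep_cache) vector("list", 6) else NULL
  for (k in 1:6) {
    Wk <- p[[paste0("W", k)]]
    if (k < 6) {
      cols <- cpp_im2col3(x, dims)
      Z <- crossprod(Wk, cols) + p[[paste0("bb", k)]]
    } else {
      cols <- x
      Z <- crossprod(Wk, x) + p[[paste0("bb", k)]]
    }
    dims_c <- c(ncol(Wk), dims[2:4], N)
    bn <- bn_forward(Z, p[[paste0("g", k)]], p[[paste0("be", k)]],
                     p[[paste0("rm", k)]], p[[paste0("rv", k)]], training)
    if (training) {
      p[[paste0("rm", k)]] <- (1 - BN_MOMENTUM) * p[[paste0("rm", k)]] +
        BN_MOMENTUM * bn$mu
      p[[paste0("rv", k)]] <- (1 - BN_MOMENTUM) * p[[paste0("rv", k)]] +
        BN_MOMENTUM * bn$va
    }
    if (k < 6) {
      pl <- cpp_maxpool3(bn$out, dims_c)
      pre <- pl$out
      dims_next <- pl$dims
      idx <- pl$idx
    } else {
      pre <- bn$out
      dims_next <- dims_c
      idx <- NULL
    }
    act <- pre * (pre > 0)
    if (keep_cache)
      caches[[k]] <- list(cols = cols, xhat = bn$xhat, inv = bn$inv,
                          pre = pre, idx = idx, dims_in = dims,
                          dims_conv = dims_c)
    x <- act
    dims <- dims_next
  }
  flat <- matrix(as.numeric(x), ncol = N)   # (C6*V6) x N, per-sample columns
  drop_p <- spec$dropout_rate
  if (training && drop_p > 0) {
    if (is.null(dropout_mask))
      dropout_mask <- matrix(rbinom(length(flat), 1, 1 - drop_p),
                             nrow(flat), N)
    flat_d <- flat * dropout_mask / (1 - drop_p)
  } else {
    dropout_mask <- NULL
    flat_d <- flat
  }
  f7 <- crossprod(p$W7, flat_d) + p$b7          # feature_dim x N
  u <- rbind(f7, cov)
  yhat <- as.numeric(crossprod(p$w8, u) + p$b8)
  list(yhat = yhat, features = f7, params = p,
       cache = if (keep_cache) list(blocks = caches, flat = flat,
                                    flat_d = flat_d, mask = dropout_mask,
                                    u = u, dims6 = dims) else NULL)
}

# Backward pass; returns gradients named like the trainable parameters.
sfcn_backward <- function(model, fw, dyhat, N) {
  p <- fw$params
  spec <- model$spec
  grads <- list()
  dyhat <- matrix(dyhat, nrow = 1)
  u <- fw$cache$u
  grads$w8 <- u %*% t(dyhat)
  grads$b8 <- sum(dyhat)
  du <- p$w8 %*% dyhat
  df7 <- du[seq_len(spec$feature_dim), , drop = FALSE]
  grads$W7 <- fw$cache$flat_d %*% t(df7)
  grads$b7 <- rowSums(df7)
  dflat <- p$W7 %*% df7
  if (!is.null(fw$cache$mask))
    dflat <- dflat * fw$cache$mask / (1 - spec$dropout_rate)
  ck <- fw$cache$blocks
  dx <- matrix(as.numeric(dflat), nrow = spec$conv_channels[6])
  for (k in 6:1) {
    c <- ck[[k]]
    dact <- dx * (c$pre > 0)
    dY <- if (k < 6) cpp_maxpool3_bwd(dact, c$idx, c$dims_conv) else dact
    bnb <- bn_backward(dY, c$xhat, c$inv, p[[paste0("g", k)]])
    grads[[paste0("g", k)]] <- bnb$dg
    grads[[paste0("be", k)]] <- bnb$dbe
    grads[[paste0("W", k)]] <- c$cols %*% t(bnb$dZ)
    grads[[paste0("bb", k)]] <- rowSums(bnb$dZ)
    if (k > 1) {
      dcols <- p[[paste0("W", k)]] %*% bnb$dZ
      dx <- if (k <= 5) cpp_col2im3(dcols, c$dims_in) else dcols
    }
  }
  grads
}

TRAINABLE <- c(paste0("W", 1:7), paste0("bb", 1:6), "b7",
               paste0("g", 1:6), paste0("be", 1:6), "w8", "b8")

adam_init <- function(params) {
  st <- list(t = 0)
  for (nm in TRAINABLE) {
    st[[paste0("m.", nm)]] <- params[[nm]] * 0
    st[[paste0("v.", nm)]] <- params[[nm]] * 0
  }
  st
}

adam_step <- function(params, grads, st, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  st$t <- st$t + 1
  bc1 <- 1 - beta1^st$t
  bc2 <- 1 - beta2^st$t
  for (nm in TRAINABLE) {
    g <- grads[[nm]]
    m <- st[[paste0("m.", nm)]] <- beta1 * st[[paste0("m.", nm)]] +
      (1 - beta1) * g
    v <- st[[paste0("v.", nm)]] <- beta2 * st[[paste0("v.", nm)]] +
      (1 - beta2) * g^2
    params[[nm]] <- params[[nm]] - lr * (m / bc1) / (sqrt(v / bc2) + eps)
  }
  list(params = params, state = st)
}
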