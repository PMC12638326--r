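test_that("the default architecture reproduces the published shape trace", {
  spec <- network_spec()
  tr <- shape_trace(spec)
  expect_equal(unlist(tr[tr$block == 6, c("d1", "d2", "d3")]),
               c(d1 = 2, d2 = 3, d3 = 2))
  expect_equal(tr$vector_length[tr$block == 7], 100)
  expect_equal(tr$channels[tr$block == 6], 64)
  expect_equal(attr(tr, "flat_dim"), 64 * 2 * 3 * 2)
  expect_equal(spec$feature_dim * 5 + length(spec$covariates_fusion), 503)
  expect_equal(spec$dropout_rate, 0.5)
})

test_that("pooling arithmetic is floor halving with singleton pass-through", {
  tr32 <- shape_trace(network_spec(input_shape = c(32, 32, 32)))
  expect_equal(unlist(tr32[tr32$block == 6, c("d1", "d2", "d3")]),
               c(d1 = 1, d2 = 1, d3 = 1))
  # desk grid: axes bottom out at one voxel instead of vanishing
  tr24 <- shape_trace(desk_network_spec())
  expect_equal(unlist(tr24[tr24$block == 6, c("d1", "d2", "d3")]),
               c(d1 = 1, d2 = 1, d3 = 1))
  expect_true(all(tr24[1:5, c("d1", "d2", "d3")] >= 1))
})

test_that("invalid specifications are rejected", {
  expect_error(network_spec(conv_channels = c(8, 8, 8)), "six")
  expect_error(network_spec(dropout_rate = 1), "dropout")
  expect_error(network_spec(feature_dim = 0), "feature_dim")
  expect_error(network_spec(input_shape = c(1, 10, 10)), "at least 2")
})

test_that("built parameters have the shapes the spec implies", {
  spec <- tiny_spec()
  m <- build_network(spec, seed = 1)
  expect_equal(dim(m$params$W1), c(27, 2))
  expect_equal(dim(m$params$W2), c(27 * 2, 3))
  expect_equal(dim(m$params$W6), c(3, 4))   # 1x1x1 convolution
  expect_equal(dim(m$params$W7),
               c(attr(shape_trace(spec), "flat_dim"), 5))
  expect_equal(dim(m$params$w8), c(5 + 2, 1))
})

test_that("feature extraction is deterministic and spatially sensitive", {
  spec <- tiny_spec()
  m <- build_network(spec, seed = 2)
  set.seed(7)
  v <- array(rnorm(12^3), c(12, 12, 12))
  f1 <- extract_features(m, v)
  f2 <- extract_features(m, v)
  expect_identical(f1, f2)
  expect_length(f1, spec$feature_dim)
  vp <- array(sample(as.numeric(v)), dim(v))
  expect_false(isTRUE(all.equal(extract_features(m, vp), f1)))
  expect_error(extract_features(m, array(0, c(8, 8, 8))), "input shape")
})

test_that("analytic gradients match numerical differentiation", {
  wm <- asNamespace("wmbrainage")
  spec <- network_spec(input_shape = c(8, 8, 8),
                       conv_channels = c(2, 2, 2, 2, 2, 3),
                       feature_dim = 4, dropout_rate = 0)
  model <- build_network(spec, seed = 3)
  set.seed(4)
  N <- 2
  vols <- replicate(N, array(rnorm(8^3), c(8, 8, 8)), simplify = FALSE)
  age <- c(55, 70)
  cov <- rbind(sex = c(0, 1), scanner = c(1, 2))
  X <- wm$stack_volumes(vols, spec)
  loss_fn <- function(params) {
    mm <- model; mm$params <- params
    fw <- wm$sfcn_forward(mm, X, cov, N, training = TRUE)
    mean((fw$yhat - age)^2)
  }
  fw <- wm$sfcn_forward(model, X, cov, N, training = TRUE,
                        keep_cache = TRUE)
  gr <- wm$sfcn_backward(model, fw, 2 * (fw$yhat - age) / N, N)
  eps <- 1e-5
  for (nm in c("W1", "g2", "be3", "W6", "W7", "w8", "b8")) {
    p <- model$params[[nm]]
    for (i in sample(length(p), min(3, length(p)))) {
      pp <- model$params
      pp[[nm]][i] <- pp[[nm]][i] + eps; up <- loss_fn(pp)
      pp[[nm]][i] <- pp[[nm]][i] - 2 * eps; dn <- loss_fn(pp)
      num <- (up - dn) / (2 * eps)
      expect_equal(gr[[nm]][i], num, tolerance = 1e-4,
                   ignore_attr = TRUE)
    }
  }
})

test_that("dropout only perturbs training mode; evaluation is deterministic", {
  wm <- asNamespace("wmbrainage")
  spec <- network_spec(input_shape = c(12, 12, 12),
                       conv_channels = c(2, 3, 3, 3, 3, 8),
                       feature_dim = 5, dropout_rate = 0.5)
  m <- build_network(spec, seed = 5)
  set.seed(5)
  m$params$w8 <- matrix(rnorm(nrow(m$params$w8)), ncol = 1)
  m$params$b8 <- 60
  set.seed(8)
  vols <- replicate(3, array(rnorm(12^3), c(12, 12, 12)),
                    simplify = FALSE)
  X <- wm$stack_volumes(vols, spec)
  cov <- rbind(sex = c(0, 1, 0), scanner = c(0, 1, 2))
  set.seed(1); a <- wm$sfcn_forward(m, X, cov, 3, training = TRUE)$yhat
  set.seed(2); b <- wm$sfcn_forward(m, X, cov, 3, training = TRUE)$yhat
  expect_false(isTRUE(all.equal(a, b)))
  e1 <- wm$sfcn_forward(m, X, cov, 3, training = FALSE)$yhat
  e2 <- wm$sfcn_forward(m, X, cov, 3, training = FALSE)$yhat
  expect_identical(e1, e2)
})

test_that("batch and single-item evaluation agree", {
  spec <- tiny_spec()
  m <- build_network(spec, seed = 6)
  set.seed(9)
  vols <- replicate(3, array(rnorm(12^3), c(12, 12, 12)),
                    simplify = FALSE)
  sex <- c(0, 1, 0); sc <- c(0, 1, 2)
  batch <- predict_single_map(m, vols, sex, sc)
  single <- vapply(1:3, function(i)
    predict_single_map(m, vols[i], sex[i], sc[i]), numeric(1))
  expect_equal(batch, single, tolerance = 1e-12)
})
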