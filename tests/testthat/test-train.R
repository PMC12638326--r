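test_that("a constant-age training set is fitted to that constant", {
  spec <- network_spec(input_shape = c(8, 8, 8),
                       conv_channels = c(2, 2, 2, 2, 2, 2),
                       feature_dim = 4)
  set.seed(11)
  vols <- replicate(12, array(rnorm(8^3), c(8, 8, 8)), simplify = FALSE)
  m <- train_single_map(spec, vols, rep(60, 12), rbinom(12, 1, .5),
                        sample(0:2, 12, TRUE), epochs = 4, seed = 1)
  expect_lt(tail(m$training_log$loss, 1), 1)
  yh <- predict_single_map(m, vols, rep(0, 12), rep(0, 12))
  expect_lt(mean(abs(yh - 60)), 2)
})

test_that("training is deterministic under a fixed seed", {
  spec <- tiny_spec()
  set.seed(12)
  vols <- replicate(10, array(rnorm(12^3), c(12, 12, 12)),
                    simplify = FALSE)
  age <- runif(10, 50, 80); sex <- rbinom(10, 1, .5)
  sc <- sample(0:2, 10, TRUE)
  m1 <- train_single_map(spec, vols, age, sex, sc, epochs = 2, seed = 77)
  m2 <- train_single_map(spec, vols, age, sex, sc, epochs = 2, seed = 77)
  expect_equal(m1$params, m2$params, tolerance = 1e-14)
  m3 <- train_single_map(spec, vols, age, sex, sc, epochs = 2, seed = 78)
  expect_false(isTRUE(all.equal(m1$params$W1, m3$params$W1)))
})

test_that("degenerate training inputs are rejected", {
  spec <- tiny_spec()
  v <- list(array(0, c(12, 12, 12)))
  expect_error(train_single_map(spec, v, 60, 0, 0), "at least two")
  expect_error(train_single_map(spec, c(v, v), c(60, NA), c(0, 0),
                                c(0, 0)), "finite")
})

test_that("the fusion head solves an embedded exact linear problem", {
  set.seed(13)
  n <- 60; fd <- 4
  age <- runif(n, 45, 83)
  feats <- replicate(5, matrix(rnorm(n * fd, 0, 0.1), n, fd),
                     simplify = FALSE)
  feats[[2]][, 3] <- age            # one coordinate carries age exactly
  cov <- data.frame(sex = rbinom(n, 1, .5), scanner = sample(0:2, n, TRUE),
                    icv = rnorm(n, 1500, 100))
  head8 <- fit_fusion_head(feats, cov, age)
  expect_true(is.na(head8$ridge_lambda))
  w <- head8$coef
  expect_equal(unname(w[fd + 3]), 1, tolerance = 1e-8)
  expect_lt(max(abs(w[-(fd + 3)])), 1e-8)
  expect_equal(predict_fused(head8, feats, cov), age, tolerance = 1e-8)
})

test_that("the fusion head validates its input length and falls back to ridge", {
  set.seed(14)
  n <- 20; fd <- 8                   # 5*8 + 3 = 43 > n: rank deficient
  age <- runif(n, 45, 83)
  feats <- replicate(5, matrix(rnorm(n * fd), n, fd), simplify = FALSE)
  cov <- data.frame(sex = rbinom(n, 1, .5), scanner = sample(0:2, n, TRUE),
                    icv = rnorm(n))
  head8 <- fit_fusion_head(feats, cov, age)
  expect_false(is.na(head8$ridge_lambda))
  expect_gt(head8$ridge_lambda, 0)

  bad <- replicate(4, matrix(rnorm(n * fd), n, fd), simplify = FALSE)
  expect_error(fit_fusion_head(bad, cov, age), "five")
  head4 <- fit_fusion_head(replicate(5, matrix(rnorm(n * 2), n, 2),
                                     simplify = FALSE), cov, age)
  expect_error(predict_fused(head4, feats, cov), "expects")
})

test_that("fitting the fusion head leaves the per-map networks untouched", {
  spec <- tiny_spec()
  models <- lapply(MAPS_T, function(m) build_network(spec, seed = 20,
                                                     map_label = m))
  names(models) <- MAPS_T
  before <- lapply(models, function(m) m$params)
  set.seed(15)
  n <- 30
  feats <- lapply(models, function(m)
    matrix(rnorm(n * spec$feature_dim), n, spec$feature_dim))
  cov <- data.frame(sex = rbinom(n, 1, .5), scanner = sample(0:2, n, TRUE),
                    icv = rnorm(n))
  fit_fusion_head(unname(feats), cov, runif(n, 45, 83))
  expect_identical(lapply(models, function(m) m$params), before)
})

test_that("predict_age requires all five maps and models", {
  spec <- tiny_spec()
  models <- setNames(lapply(MAPS_T, function(m)
    build_network(spec, seed = 21, map_label = m)), MAPS_T)
  set.seed(16)
  vols <- setNames(replicate(5, array(rnorm(12^3), c(12, 12, 12)),
                             simplify = FALSE), MAPS_T)
  train_feats <- replicate(5, matrix(rnorm(30 * spec$feature_dim), 30),
                           simplify = FALSE)
  train_cov <- data.frame(sex = rbinom(30, 1, .5),
                          scanner = sample(0:2, 30, TRUE),
                          icv = rnorm(30, 1500, 100))
  head8 <- fit_fusion_head(train_feats, train_cov, runif(30, 50, 70))
  y1 <- predict_age(models, head8, vols, sex = 1, scanner = 0, icv = 1500)
  expect_length(y1, 1)
  expect_true(is.finite(y1))
  expect_error(predict_age(models, head8, vols[-3], 1, 0, 1500), "AxD")
})
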