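test_that("VRS counting, categorisation and dummy coding follow the scheme", {
  rf <- data.frame(hypertension = c(0, 1, 1, 1, NA),
                   diabetes = c(0, 1, 0, 1, 0),
                   hypercholesterolemia = c(0, 1, 0, 1, 0),
                   obesity = c(0, 1, 0, 1, 0),
                   smoking = c(0, 0, 1, 1, 0))
  v <- compute_vrs(rf)
  expect_equal(v$factor_count, c(0, 4, 2, 5, NA))
  expect_equal(as.character(v$category), c("0", "3plus", "2", "3plus", NA))
  expect_equal(unlist(v[1, c("vrs_1", "vrs_2", "vrs_3")]),
               c(vrs_1 = 0, vrs_2 = 0, vrs_3 = 0))
  expect_equal(unlist(v[2, c("vrs_1", "vrs_2", "vrs_3")]),
               c(vrs_1 = 0, vrs_2 = 0, vrs_3 = 1))
  expect_true(all(is.na(unlist(v[5, c("vrs_1", "vrs_2", "vrs_3")]))))
  expect_error(compute_vrs(data.frame(hypertension = 2, diabetes = 0,
                                      hypercholesterolemia = 0,
                                      obesity = 0, smoking = 0)),
               "0, 1 or missing")
})

test_that("VRS category is reconstructable from the dummies", {
  set.seed(41)
  rf <- as.data.frame(matrix(rbinom(5 * 300, 1, 0.4), ncol = 5,
                             dimnames = list(NULL, RISK_FACTORS_T)))
  v <- compute_vrs(rf)
  rebuilt <- ifelse(v$vrs_3 == 1, "3plus",
                    ifelse(v$vrs_2 == 1, "2",
                           ifelse(v$vrs_1 == 1, "1", "0")))
  expect_equal(rebuilt, as.character(v$category))
  # exactly one dummy set unless at reference
  expect_true(all(rowSums(v[c("vrs_1", "vrs_2", "vrs_3")]) %in% 0:1))
})

test_that("APOE coding maps allele counts to carrier categories", {
  expect_equal(as.character(encode_apoe(c(0, 1, 2, NA))),
               c("noncarrier", "one_allele", "two_alleles", NA))
  expect_error(encode_apoe(3), "0, 1, 2")
})

test_that("cognition standardisation centres, flips signs and averages", {
  tab <- cognition_test_table()
  ref <- as.data.frame(lapply(seq_len(nrow(tab)), function(i)
    rnorm(500, tab$mean[i], tab$sd[i])))
  names(ref) <- tab$test
  at_mean <- as.data.frame(lapply(tab$test, function(t)
    mean(ref[[t]])))
  names(at_mean) <- tab$test
  z0 <- standardise_cognition(at_mean, ref)
  expect_equal(unlist(z0[c("processing_speed", "memory", "executive",
                           "global")]),
               c(processing_speed = 0, memory = 0, executive = 0,
                 global = 0), tolerance = 1e-12)

  # reaction time one reference sd slower, everything else at the mean:
  # speed domain = mean(-1, 0, 0) = -1/3, others 0
  slow <- at_mean
  slow$reaction_time <- slow$reaction_time + sd(ref$reaction_time)
  z1 <- standardise_cognition(slow, ref)
  expect_equal(z1$processing_speed, -1 / 3, tolerance = 1e-12)
  expect_equal(z1$memory, 0, tolerance = 1e-12)

  # doubling raw scales and reference together leaves z-scores unchanged
  doubled <- as.data.frame(lapply(ref, function(x) 2 * x))
  z_ref <- standardise_cognition(ref, ref)
  z_dbl <- standardise_cognition(doubled, doubled)
  expect_equal(z_ref, z_dbl, tolerance = 1e-10)
})

test_that("every test's worse direction lowers its domain composite", {
  tab <- cognition_test_table()
  set.seed(42)
  ref <- as.data.frame(lapply(seq_len(nrow(tab)), function(i)
    rnorm(300, tab$mean[i], tab$sd[i])))
  names(ref) <- tab$test
  base <- ref[1, ]
  z_base <- standardise_cognition(base, ref)
  for (i in seq_len(nrow(tab))) {
    worse <- base
    step <- sd(ref[[tab$test[i]]]) * (if (tab$reversed[i]) 1 else -1)
    worse[[tab$test[i]]] <- worse[[tab$test[i]]] + step
    z_w <- standardise_cognition(worse, ref)
    expect_lt(z_w[[tab$domain[i]]], z_base[[tab$domain[i]]])
    expect_lt(z_w$global, z_base$global)
  }
})

test_that("domains degrade gracefully under missing tests", {
  tab <- cognition_test_table()
  ref <- as.data.frame(lapply(seq_len(nrow(tab)), function(i)
    rnorm(200, tab$mean[i], tab$sd[i])))
  names(ref) <- tab$test
  row <- ref[1, ]
  row$numeric_memory <- NA
  z <- standardise_cognition(row, ref)
  expect_false(is.na(z$memory))    # available-case mean of pairs only
  expect_true(z$incomplete)
  row$pairs_matching <- NA
  z2 <- standardise_cognition(row, ref)
  expect_true(is.na(z2$memory))    # whole domain missing
})
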