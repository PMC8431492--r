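test_that("difference: direct cases and inverse identity", {
  expect_equal(difference(c(5, 2, 7)), c(-3, 5))
  expect_equal(difference(rep(3.5, 4)), rep(0, 3))
  set.seed(21)
  s <- stats::rnorm(50)
  expect_equal(c(s[1], s[1] + cumsum(difference(s))), s)
  expect_error(difference(1), class = "skelquant_series_too_short_error")
})

test_that("acf_lag: exact analytic cases", {
  expect_identical(acf_lag(as.numeric(1:100)), 1)
  expect_identical(acf_lag(rep(c(1, -1), 50)), -1)
  expect_error(acf_lag(rep(2, 10)), class = "skelquant_undefined_acf_error")
  expect_error(acf_lag(c(1, 2), tau = 1),
               class = "skelquant_series_too_short_error")
  # length-2 overlap degeneracy: correlation of two points is +/-1
  expect_equal(abs(acf_lag(c(1, 5, 2))), 1)
})

test_that("acf_lag matches a naive two-pass Pearson oracle to 1e-12", {
  set.seed(77)
  for (k in 1:200) {
    n <- sample(5:200, 1)
    s <- stats::rnorm(n)
    tau <- sample(1:min(3, n - 2), 1)
    expect_equal(acf_lag(s, tau),
                 naive_pearson(s[1:(n - tau)], s[(tau + 1):n]),
                 tolerance = 1e-12)
  }
})

test_that("acf_lag output lies in [-1, 1] and respects affine maps", {
  set.seed(88)
  for (k in 1:200) {
    s <- stats::rnorm(sample(5:80, 1))
    r <- acf_lag(s)
    expect_gte(r, -1); expect_lte(r, 1)
    expect_equal(acf_lag(3 * s + 7), r)       # positive affine: unchanged
    expect_equal(acf_lag(-2 * s + 1), r)      # lag-1 correlation is a > 0 or < 0 invariant
  }
})

test_that("white noise and AR(1) recover their theoretical lag-1 ACF", {
  set.seed(404)
  wn <- stats::rnorm(10000)
  expect_lt(abs(first_acf_original(wn)), 0.05)
  expect_lt(abs(first_acf_differenced(wn) - (-0.5)), 0.05)

  phi <- 0.8
  ar <- as.numeric(stats::filter(stats::rnorm(10000, 0, sqrt(1 - phi^2)),
                                 phi, method = "recursive",
                                 init = stats::rnorm(1)))
  expect_lt(abs(first_acf_original(ar) - phi), 3 / sqrt(10000) * 3)
  expect_lt(abs(first_acf_differenced(ar) - (-(1 - phi) / 2)), 0.05)
})

test_that("stationary estimator agrees with stats::acf and with pairwise at large T", {
  set.seed(11)
  s <- stats::rnorm(500)
  expect_equal(acf_lag(s, 1, method = "stationary"),
               stats::acf(s, lag.max = 1, plot = FALSE,
                          demean = TRUE)$acf[2, 1, 1],
               tolerance = 1e-12)
  expect_lt(abs(acf_lag(s, 1, method = "stationary") - acf_lag(s, 1)), 0.02)
})

test_that("first_acf_differenced: ramp degenerates, short series rejected", {
  expect_error(first_acf_differenced(as.numeric(1:50)),
               class = "skelquant_undefined_acf_error")
  expect_error(first_acf_differenced(c(1, 2, 4)),
               class = "skelquant_series_too_short_error")
})

test_that("averaged_variance: windowing, remainder drop, affine scaling", {
  expect_equal(averaged_variance(c(0, 2, 0, 2), 2), 1)
  expect_equal(averaged_variance(c(1, 1, 2, 2, 9), 2), 0)  # 9 discarded
  set.seed(5)
  s <- stats::rnorm(100)
  expect_equal(averaged_variance(3 * s + 7, 10), 9 * averaged_variance(s, 10))
  # W = T: population variance of the whole series
  expect_equal(averaged_variance(s, 100), mean((s - mean(s))^2))
  expect_error(averaged_variance(s, 101),
               class = "skelquant_series_too_short_error")
  expect_error(averaged_variance(s, 1), class = "skelquant_input_error")
})

test_that("extract_features assembles 33 named features in canonical order", {
  sq <- generate_sequence(motion_config(T = 300, seed = 8))
  fv <- extract_features(compute_parameter_series(sq))
  expect_length(fv, 33L)
  expect_named(fv, feature_names())
  expect_equal(sum(grepl("^acf_", names(fv))), 22L)
  expect_true(all(fv[grepl("^acf_", names(fv))] >= -1 &
                    fv[grepl("^acf_", names(fv))] <= 1))
  expect_true(all(fv[grepl("^avgvar_", names(fv))] >= 0))
  expect_identical(attr(fv, "window_size"), 30L)
})

test_that("a static recording gives zero variances and missing ACFs", {
  ps <- compute_parameter_series(static_axis_sequence(T = 60))
  w <- capture_warnings(fv <- extract_features(ps))
  expect_length(w, 22)  # one per undefined acf feature
  expect_true(all(grepl("undefined", w)))
  expect_true(all(fv[grepl("^avgvar_", names(fv))] == 0))
  expect_true(all(is.na(fv[grepl("^acf_", names(fv))])))
})

test_that("extract_features rejects a wrong number of series", {
  m <- matrix(stats::rnorm(200), 50, 4)
  expect_error(extract_features(m), class = "skelquant_input_error")
})

test_that("doubling motion amplitude quadruples avgvar, leaves ACF stable", {
  # joints move along fixed directions: amplitude scaling is exact for
  # lengths; angles respond nonlinearly, so only length features are checked
  base_res <- lapply(c(1, 2) , function(k) {
    sq <- generate_sequence(motion_config(T = 2000, jitter_sd = 1.5 * k,
                                          sway_amplitude = 0,
                                          swivel_amplitude = 0, seed = 50))
    extract_features(compute_parameter_series(sq))
  })
  len <- paste0("avgvar_", grep("_length$", parameter_names(), value = TRUE))
  ratio <- as.numeric(base_res[[2]][len]) / as.numeric(base_res[[1]][len])
  expect_true(all(abs(ratio - 4) < 1))  # Monte-Carlo, not exact: new draws
  acf_len <- paste0("acf_orig_", grep("_length$", parameter_names(),
                                      value = TRUE))
  expect_true(all(abs(as.numeric(base_res[[2]][acf_len]) -
                        as.numeric(base_res[[1]][acf_len])) < 0.1))
})
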