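# Feature construction: logMUA, gamma-variance envelope, z-scored feature
# matrix, and the first-principal-component projection.

test_that("logMUA of an out-of-band sinusoid sits at the floor", {
  fs <- 5000
  x <- 100 * sin(2 * pi * 10 * seq(0, 5, by = 1 / fs))
  mu <- compute_log_mua(x, fs = fs)
  # away from the filter's edge transients the estimate sits at the floor
  interior <- mu$values[mu$time_s > 0.5 & mu$time_s < 4.5]
  expect_true(all(interior < log(1e-3)))            # no 200-1500 Hz content
  expect_lt(stats::sd(interior), 1e-6)              # ~constant
})

test_that("doubling white-noise amplitude raises logMUA by log(4)", {
  fs <- 5000
  set.seed(100)
  x <- c(stats::rnorm(10 * fs), 2 * stats::rnorm(10 * fs))
  mu <- compute_log_mua(x, fs = fs)
  half <- mu$time_s < 10
  # trim a second around the amplitude step and the record edges
  first <- mu$values[half & mu$time_s > 1 & mu$time_s < 9]
  second <- mu$values[!half & mu$time_s > 11 & mu$time_s < 19]
  expect_lt(abs((mean(second) - mean(first)) - log(4)), 0.05)
})

test_that("logMUA band must fit under Nyquist", {
  expect_error(compute_log_mua(stats::rnorm(5000), band = c(200, 2600),
                               fs = 5000), "Nyquist")
})

test_that("gamma-variance envelope: DC input gives a ~zero envelope", {
  env <- compute_gamma_variance_envelope(rep(3.5, 25000), fs = 5000)
  interior <- env$values[env$time_s > 0.5 & env$time_s < 4.5]
  expect_true(all(interior < 1e-10))                # zero away from edges
  expect_true(all(env$values >= 0))
})

test_that("gamma-variance envelope of a 50 Hz sinusoid approaches A^2/2", {
  fs <- 5000; A <- 40
  x <- A * sin(2 * pi * 50 * seq(0, 10, by = 1 / fs))
  env <- compute_gamma_variance_envelope(x, fs = fs)
  steady <- env$values[env$time_s > 2 & env$time_s < 8]
  expect_lt(max(abs(steady - A^2 / 2)) / (A^2 / 2), 0.05)
})

test_that("a variance window shorter than 3 gamma cycles is rejected", {
  expect_error(compute_gamma_variance_envelope(stats::rnorm(5000),
                                               var_window_s = 0.05, fs = 5000),
               "3 cycles")
})

test_that("feature matrix columns are z-scored and affine-invariant", {
  fs <- 5000
  set.seed(7)
  x <- stats::rnorm(5 * fs)
  mu <- compute_log_mua(x, fs = fs)
  gv <- compute_gamma_variance_envelope(x, fs = fs)
  fm <- build_feature_matrix(x, mu, gv, fs = fs)
  expect_true(all(abs(colMeans(fm$z)) < 1e-6))
  expect_true(all(abs(apply(fm$z, 2, stats::sd) - 1) < 1e-6))
  fm2 <- build_feature_matrix(3.7 * x + 11, mu, gv, fs = fs)
  expect_equal(fm2$z[, "z_lfp"], fm$z[, "z_lfp"])
})

test_that("z-scores match hand computation on a 5-sample column", {
  v <- c(1, 2, 3, 4, 10)
  z <- (v - mean(v)) / stats::sd(v)
  fs <- 5
  toy <- slowosc:::new_feature_series(v, list(fs = fs, time_s = (0:4) / fs))
  fm <- build_feature_matrix(v, toy, toy, feature_step_s = 1 / fs, fs = fs)
  expect_equal(unname(fm$z[, "z_logmua"]), z)
  expect_equal(unname(fm$z[, "z_lfp"]), z)
})

test_that("a zero-variance feature column is rejected by name", {
  fs <- 5
  toy <- slowosc:::new_feature_series(c(1, 2, 3, 4, 5),
                                      list(fs = fs, time_s = (0:4) / fs))
  flat <- slowosc:::new_feature_series(rep(2, 5),
                                       list(fs = fs, time_s = (0:4) / fs))
  expect_error(build_feature_matrix(c(1, 2, 3, 4, 5), toy, flat,
                                    feature_step_s = 1 / fs, fs = fs),
               "z_gammavar")
})

test_that("PC1 of three identical columns is the shared column", {
  fs <- 10
  set.seed(2)
  v <- stats::rnorm(400)
  toy <- slowosc:::new_feature_series(v, list(fs = fs,
                                              time_s = seq_along(v) / fs))
  fm <- build_feature_matrix(v, toy, toy, feature_step_s = 1 / fs, fs = fs)
  expect_warning(pr <- project_first_pc(fm), "rank deficient")
  expect_equal(pr$explained_variance_fraction, 1)
  expect_equal(pr$pc1, unname(fm$z[, "z_logmua"]), tolerance = 1e-8)
})

test_that("PC1 loadings match a power-iteration oracle and are sign-fixed", {
  fs <- 100
  set.seed(5)
  n <- 2000
  base <- stats::rnorm(n)
  z <- cbind(z_lfp = 0.8 * base + 0.6 * stats::rnorm(n),
             z_logmua = base + 0.3 * stats::rnorm(n),
             z_gammavar = 0.5 * base + stats::rnorm(n))
  z <- scale(z)
  fm <- structure(list(z = z, fs = fs, time_s = seq_len(n) / fs),
                  class = "feature_matrix")
  pr <- project_first_pc(fm)
  v_oracle <- power_iteration(stats::cov(z))
  if (sum(v_oracle * pr$loadings) < 0) v_oracle <- -v_oracle
  expect_equal(unname(pr$loadings), v_oracle, tolerance = 1e-6)
  expect_equal(sqrt(sum(pr$loadings^2)), 1)
  expect_gte(stats::cor(pr$pc1, z[, "z_logmua"]), 0)
  expect_gt(pr$explained_variance_fraction, 1 / 3)
})

test_that("features separate true Up from true Down on a simulation", {
  sim <- simulate_slow_oscillation(slow_osc_params(duration = 20, seed = 13))
  rec <- sim$recording
  mu <- compute_log_mua(rec)
  gv <- compute_gamma_variance_envelope(rec)
  grid_idx <- round(mu$time_s * rec$sampling_rate) + 1
  truth <- sim$truth$state_labels[grid_idx]
  expect_gt(mean(mu$values[truth == 1]), mean(mu$values[truth == 0]))
  expect_gt(mean(gv$values[truth == 1]), mean(gv$values[truth == 0]))
  fm <- build_feature_matrix(rec, mu, gv)
  pr <- project_first_pc(fm)
  expect_gt(pr$explained_variance_fraction, 1 / 3)
})
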