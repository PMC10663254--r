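# Simulator contracts: determinism, ground-truth consistency, degenerate
# cases, and the statistical structure the detector relies on.

test_that("slow-oscillation simulation is a pure function of params and seed", {
  p <- slow_osc_params(duration = 5, seed = 42)
  a <- simulate_slow_oscillation(p)
  b <- simulate_slow_oscillation(p)
  expect_identical(a$recording$samples, b$recording$samples)
  expect_identical(a$truth$state_labels, b$truth$state_labels)
  c2 <- simulate_slow_oscillation(slow_osc_params(duration = 5, seed = 43))
  expect_false(identical(a$recording$samples, c2$recording$samples))
})

test_that("ground-truth labels and intervals are mutually consistent and tile", {
  sim <- simulate_slow_oscillation(slow_osc_params(duration = 20, seed = 3))
  iv <- sim$truth$intervals
  fs <- sim$recording$sampling_rate
  expect_identical(labels_to_intervals(sim$truth$state_labels, fs), iv)
  expect_identical(
    intervals_to_labels(iv, fs, length(sim$truth$state_labels)),
    sim$truth$state_labels)
  expect_equal(iv$start_s[-1], iv$end_s[-nrow(iv)])  # no gaps, no overlap
  expect_equal(iv$start_s[1], 0)
  expect_true(all(diff(iv$state) != 0))
})

test_that("an absent Up state yields an all-Down recording", {
  p <- slow_osc_params(duration = 5, up_dur_mean = 0, up_dur_sd = 0, seed = 1)
  sim <- simulate_slow_oscillation(p)
  expect_true(all(sim$truth$state_labels == 0))
  expect_equal(nrow(sim$truth$intervals), 1L)
})

test_that("realized Up durations match the requested truncated-normal mean", {
  p <- slow_osc_params(duration = 200, up_dur_mean = 1.0, up_dur_sd = 0.2,
                       down_dur_mean = 1.0, seed = 9)
  sim <- simulate_slow_oscillation(p)
  iv <- sim$truth$intervals
  iv <- iv[2:(nrow(iv) - 1), ]                      # drop edge-truncated
  d <- (iv$end_s - iv$start_s)[iv$state == 1]
  expect_gt(length(d), 50)
  se <- stats::sd(d) / sqrt(length(d))
  expect_lt(abs(mean(d) - 1.0), 3 * se + 1e-3)      # truncation bias ~1e-4
})

test_that("a too-short record raises the warning flag", {
  p <- slow_osc_params(duration = 0.5, up_dur_mean = 1, down_dur_mean = 1,
                       seed = 1)
  expect_warning(sim <- simulate_slow_oscillation(p), "shorter")
  expect_true(sim$truth$warning_short_record)
})

test_that("simulator parameters are validated", {
  expect_error(slow_osc_params(noise_sd = -1), "noise_sd")
  expect_error(slow_osc_params(duration = Inf), "duration")
  expect_error(slow_osc_params(sampling_rate = 2000), "sampling_rate")
  expect_error(stim_protocol(intensities_ua = c(80, 40)), "increasing")
  expect_error(evoked_shape(components = data.frame(
    polarity = 1, peak_latency_ms = -2, peak_amplitude_uv = 10,
    width_ms = 5)), "positive")
})

test_that("evoked trials: null template gives identically zero epochs", {
  sh <- evoked_shape(components = data.frame(
    polarity = 1, peak_latency_ms = 10, peak_amplitude_uv = 0, width_ms = 5),
    trial_noise_sd = 0, seed = 1)
  tr <- simulate_evoked_trials(stim_protocol(intensities_ua = 80), sh)
  expect_true(all(tr$epochs[[1]] == 0))
})

test_that("evoked trials: default protocol emits 50 epochs per intensity", {
  tr <- simulate_evoked_trials(stim_protocol(), evoked_shape(seed = 2))
  expect_length(tr$epochs, 8)                       # 40-320 uA step 40
  expect_true(all(vapply(tr$epochs, function(a) dim(a)[1], 0) == 50))
  expect_gte(max(tr$time_ms), 600)
  expect_lt(min(tr$time_ms), 0)
})

test_that("trial averaging obeys the standard-error law", {
  sigma <- 8
  sh <- evoked_shape(trial_noise_sd = sigma, seed = 11)
  tr <- simulate_evoked_trials(stim_protocol(intensities_ua = 80), sh)
  avg <- epoch_and_average(tr, 1)
  rms <- sqrt(mean((avg$waveform[1, ] - tr$templates[1, ])^2))
  expect_lt(abs(rms - sigma / sqrt(50)) / (sigma / sqrt(50)), 0.2)
})

test_that("epoch window larger than the inter-stimulus interval errors", {
  expect_error(
    simulate_evoked_trials(stim_protocol(rate_hz = 2, intensities_ua = 80),
                           evoked_shape(seed = 1)),
    "inter-stimulus")
})

test_that("intensity gain is monotone, saturating, and anchored at 1", {
  sh <- evoked_shape(seed = 1)
  g <- intensity_gain(seq(20, 320, by = 20), sh)
  expect_true(all(diff(g) > 0))
  expect_equal(intensity_gain(sh$ref_intensity_ua, sh), 1)
  expect_lt(diff(intensity_gain(c(280, 320), sh)),
            diff(intensity_gain(c(40, 80), sh)))   # saturation
})

test_that("array recording decays with distance and respects limits", {
  geo <- array_geometry()
  expect_equal(geo$n_channels, 32L)
  base <- simulate_evoked_trials(stim_protocol(n_pulses = 3,
                                               intensities_ua = 80),
                                 evoked_shape(trial_noise_sd = 0, seed = 5))
  arr <- simulate_array_recording(geo, 1, 800, base)
  expect_equal(dim(arr$epochs[[1]])[2], 32L)
  d <- sqrt(rowSums((geo$layout -
                       matrix(geo$layout[1, ], 32, 2, byrow = TRUE))^2))
  o <- order(d)
  expect_true(all(diff(arr$decay_gains[o]) <= 0))
  peak_amp <- apply(arr$epochs[[1]][1, , ], 1, function(w) max(abs(w)))
  expect_true(all(diff(peak_amp[o][!duplicated(round(d[o]))]) < 0))
  far <- simulate_array_recording(geo, 1, 1e12, base)
  expect_equal(far$decay_gains, rep(1, 32))
  expect_error(simulate_array_recording(geo, 1, -5, base), "decay_length")
  expect_error(simulate_array_recording(geo, 40, 500, base), "source_channel")
})

test_that("Up-state broadband power exceeds Down-state power by ~gain^2", {
  gain <- 4
  up_only <- simulate_slow_oscillation(slow_osc_params(
    duration = 20, down_dur_mean = 0, down_dur_sd = 0, up_mua_gain = gain,
    up_gamma_amp = 0, lfp_up_offset = 0, noise_sd = 0,
    background_1f_amp = 0, seed = 21))
  down_only <- simulate_slow_oscillation(slow_osc_params(
    duration = 20, up_dur_mean = 0, up_dur_sd = 0, up_mua_gain = gain,
    up_gamma_amp = 0, lfp_up_offset = 0, noise_sd = 0,
    background_1f_amp = 0, seed = 21))
  spec <- band_power_spec(list(mua = c(200, 1500)))
  bp_up <- band_power(welch_psd(up_only$recording, zscore = FALSE), spec)
  bp_dn <- band_power(welch_psd(down_only$recording, zscore = FALSE), spec)
  expect_lt(abs(bp_up$power / bp_dn$power - gain^2) / gain^2, 0.2)
})
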