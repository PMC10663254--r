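# Evoked-response quantification: averaging, baseline normalization,
# transitions, peaks, amplitude/AUC, long-lasting metrics, intensity curves.

make_trials <- function(epochs_list, time_ms, intensities, fs = 5000) {
  structure(list(epochs = epochs_list, time_ms = time_ms,
                 intensities_ua = intensities, sampling_rate = fs),
            class = "evoked_trial_set")
}

test_that("averaging: a single trial is its own average; symmetric noise cancels", {
  tms <- default_time_ms()
  tpl <- triangle_waveform(tms)
  one <- array(tpl, dim = c(1, 1, length(tms)))
  tr <- make_trials(list(one), tms, 80)
  expect_equal(epoch_and_average(tr, 1)$waveform[1, ], tpl)

  eps <- array(0, dim = c(4, 1, length(tms)))
  for (k in 1:4) eps[k, 1, ] <- tpl + c(-3, 3)[k %% 2 + 1]
  avg <- epoch_and_average(make_trials(list(eps), tms, 80), 1)
  expect_equal(avg$waveform[1, ], tpl)
  expect_equal(avg$n_trials, 4L)
})

test_that("mismatched epoch lengths are rejected", {
  tms <- default_time_ms()
  bad <- make_trials(list(array(0, dim = c(2, 1, 10))), tms, 80)
  expect_error(epoch_and_average(bad, 1), "time axis")
})

test_that("baseline normalization removes a constant offset and is idempotent", {
  tms <- default_time_ms()
  w <- triangle_waveform(tms)
  a0 <- baseline_normalize(make_avg(w, tms))
  a13 <- baseline_normalize(make_avg(w + 13, tms))
  expect_equal(a13$waveform, a0$waveform)
  expect_equal(baseline_normalize(a0)$waveform, a0$waveform)
  sel <- tms >= -100 & tms < 0
  expect_lt(abs(mean(a13$waveform[1, sel])), 1e-9)
})

test_that("baseline subtraction matches hand arithmetic on 10 samples", {
  tms <- seq(-5, 4)                                  # fs = 1000, 1 ms steps
  w <- c(2, 3, 2, 3, 2.5, 10, 20, 10, 5, 0)          # baseline mean 2.5
  avg <- baseline_normalize(make_avg(w, tms, fs = 1000),
                            baseline_window_ms = c(-5, 0))
  expect_equal(avg$waveform[1, ], w - 2.5)
  expect_error(baseline_normalize(make_avg(w, tms, fs = 1000),
                                  baseline_window_ms = c(-20, -10)), "empty")
  expect_error(baseline_normalize(make_avg(w, tms, fs = 1000),
                                  baseline_window_ms = c(-2, 2)),
               "pre-stimulus")
})

test_that("transitions: flat waveform yields none; noiseless ramp onset exact", {
  tms <- default_time_ms()
  flat <- baseline_normalize(make_avg(numeric(length(tms)), tms))
  expect_equal(nrow(detect_transitions(flat)), 0L)

  avg <- baseline_normalize(make_avg(triangle_waveform(tms), tms))
  tr <- detect_transitions(avg)
  expect_equal(nrow(tr), 1L)
  expect_lt(abs(tr$onset_ms - 5), 0.2 + 1e-9)        # within one sample
  expect_lt(abs(tr$offset_ms - 25), 0.2 + 1e-9)
})

test_that("transitions survive additive noise to within 2 ms", {
  tms <- default_time_ms()
  set.seed(41)
  w <- triangle_waveform(tms) + stats::rnorm(length(tms), sd = 1)
  avg <- baseline_normalize(make_avg(w, tms))
  tr <- detect_transitions(avg)
  main <- tr[which.max(abs(tr$peak_value_uv)), ]
  expect_lt(abs(main$onset_ms - 5), 2)
})

test_that("first positive/negative peaks respect the amplitude and window rules", {
  tms <- default_time_ms()
  bump <- function(lat, amp, width) amp * exp(-(tms - lat)^2 / (2 * (width / 2.355)^2))
  w <- -15 * exp(-(tms - 8)^2 / (2 * (2.5 / 2.355)^2)) +
    -50 * exp(-(tms - 12)^2 / (2 * (4 / 2.355)^2)) +
    bump(25, 30, 6) + bump(60, 100, 8)
  avg <- baseline_normalize(make_avg(w, tms))
  pk <- detect_peaks(avg)
  expect_equal(pk$neg_latency_ms, 12, tolerance = 0.3)
  expect_equal(pk$neg_value_uv, -50, tolerance = 0.5)
  expect_equal(pk$pos_latency_ms, 25, tolerance = 0.3)
  expect_equal(pk$pos_value_uv, 30, tolerance = 0.5)

  only60 <- baseline_normalize(make_avg(bump(60, 100, 8), tms))
  p60 <- detect_peaks(only60)
  expect_true(is.na(p60$pos_latency_ms))             # outside 3-50 ms

  small <- baseline_normalize(make_avg(bump(20, 15, 6) - bump(35, 15, 6), tms))
  ps <- detect_peaks(small)
  expect_true(is.na(ps$pos_latency_ms) && is.na(ps$neg_latency_ms))
})

test_that("amplitude and AUC reproduce the triangle and rectangle closed forms", {
  tms <- default_time_ms()
  avg <- baseline_normalize(make_avg(triangle_waveform(tms), tms))
  m <- compute_amplitude_auc(avg, detect_peaks(avg))
  expect_equal(m$pos_amplitude_uv, 100, tolerance = 1e-6)
  expect_equal(m$pos_auc_uv_ms, 1000, tolerance = 0.005 * 1000)
  expect_equal(m$first_latency_ms, 15, tolerance = 0.2)

  rect <- numeric(length(tms)); rect[tms >= 10 & tms < 20] <- 50
  ar <- baseline_normalize(make_avg(rect, tms))
  tr <- detect_transitions(ar)
  auc_r <- trapz_err <- abs(pracma::trapz(
    tms[tms >= tr$onset_ms[1] & tms <= tr$offset_ms[1]],
    rect[tms >= tr$onset_ms[1] & tms <= tr$offset_ms[1]]))
  expect_lt(abs(auc_r - 500), 50 * 0.2 * 2 + 1e-9)   # one sample edge error
})

test_that("amplitude and AUC are homogeneous of degree 1; latency is not", {
  tms <- default_time_ms()
  base <- baseline_normalize(make_avg(triangle_waveform(tms), tms))
  m1 <- compute_amplitude_auc(base, detect_peaks(base))
  dbl <- baseline_normalize(make_avg(2 * triangle_waveform(tms), tms))
  m2 <- compute_amplitude_auc(dbl, detect_peaks(dbl))
  expect_equal(m2$pos_amplitude_uv, 2 * m1$pos_amplitude_uv)
  expect_equal(m2$pos_auc_uv_ms, 2 * m1$pos_auc_uv_ms)
  expect_equal(m2$pos_latency_ms, m1$pos_latency_ms)
})

test_that("shifting the template shifts all reported latencies equally", {
  tms <- default_time_ms()
  sh <- 7
  a1 <- baseline_normalize(make_avg(triangle_waveform(tms, t0 = 5), tms))
  a2 <- baseline_normalize(make_avg(triangle_waveform(tms, t0 = 5 + sh), tms))
  m1 <- compute_amplitude_auc(a1, detect_peaks(a1))
  m2 <- compute_amplitude_auc(a2, detect_peaks(a2))
  expect_equal(m2$pos_latency_ms - m1$pos_latency_ms, sh)
  expect_equal(m2$pos_onset_ms - m1$pos_onset_ms, sh)
})

test_that("planted peaks are recovered from noisy simulated trials", {
  comps <- data.frame(polarity = c(-1, 1), peak_latency_ms = c(12, 25),
                      peak_amplitude_uv = c(50, 30), width_ms = c(4, 6))
  sigma <- 5
  sh <- evoked_shape(components = comps, trial_noise_sd = sigma, seed = 17)
  tr <- simulate_evoked_trials(stim_protocol(intensities_ua = 80), sh)
  avg <- baseline_normalize(epoch_and_average(tr, 1))
  pk <- detect_peaks(avg)
  expect_lt(abs(pk$neg_latency_ms - 12), 2)
  expect_lt(abs(pk$pos_latency_ms - 25), 2)
  expect_lt(abs(pk$neg_value_uv - (-50)), 3 * sigma / sqrt(50))
})

test_that("long-lasting metrics: null, homogeneous, and decaying-array cases", {
  tms <- default_time_ms()
  nt <- length(tms)
  zero <- make_trials(list(array(0, dim = c(2, 3, nt))), tms, 80)
  llz <- long_lasting_metrics(zero)
  expect_equal(llz$auc_600, 0)
  expect_equal(llz$channel_spread, 0)
  expect_true(all(llz$qc_zero_baseline_sd))

  set.seed(50)
  w <- 30 * exp(-(tms - 100)^2 / (2 * 50^2))
  ep <- array(0, dim = c(5, 3, nt))
  noise <- stats::rnorm(nt, sd = 2)
  for (ch in 1:3) for (k in 1:5) ep[k, ch, ] <- w + noise   # identical channels
  ll <- long_lasting_metrics(make_trials(list(ep), tms, 80))
  expect_equal(ll$channel_spread, 0)
  expect_gt(ll$auc_600, 0)

  one_ch <- long_lasting_metrics(make_trials(list(ep[, 1, , drop = FALSE]),
                                             tms, 80))
  expect_true(is.na(one_ch$channel_spread))

  # baseline z-scoring cancels a pure gain, so the spatial decay shows up as
  # a falling signal-to-noise ratio: per-channel AUC tracks the decay gain
  geo <- array_geometry(n_channels = 8, pitch_um = 550)
  base <- simulate_evoked_trials(stim_protocol(n_pulses = 20,
                                               intensities_ua = 80),
                                 evoked_shape(trial_noise_sd = 5, seed = 5))
  arr <- simulate_array_recording(geo, 1, 600, base)
  lla <- long_lasting_metrics(arr)
  expect_gt(stats::cor(lla$per_channel_auc, arr$decay_gains,
                       method = "spearman"), 0.8)
  expect_equal(which.max(lla$per_channel_auc), 1L)   # source channel
})

test_that("intensity-response curves are tabulated per intensity", {
  intens <- seq(40, 240, by = 40)
  sh <- evoked_shape(trial_noise_sd = 0, seed = 9)
  tr <- simulate_evoked_trials(stim_protocol(n_pulses = 1,
                                             intensities_ua = intens), sh)
  metrics <- lapply(seq_along(intens), function(k) {
    avg <- baseline_normalize(epoch_and_average(tr, k))
    compute_amplitude_auc(avg, detect_peaks(avg))
  })
  curve <- intensity_response_curve(metrics, intens)
  expect_equal(nrow(curve$channel_max), 6L)
  amp <- curve$channel_max$max_amplitude_uv
  expect_true(all(diff(amp[!is.na(amp)]) >= 0))      # monotone gain, noiseless
  expect_equal(curve$channel_max$max_amplitude_uv,
               curve$per_channel$amplitude_uv)       # single channel identity
})
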