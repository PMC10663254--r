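# Synthetic LFP and evoked-trial generators with exported ground truth.
#
# The simulator emulates the statistical structure the detection pipeline
# assumes: alternating Up/Down epochs in which the 200-1500 Hz broadband
# ("MUA") amplitude and 30-100 Hz gamma content are elevated during Up
# states, riding on a 1/f background, plus stimulus-locked evoked waveforms
# with a saturating intensity-gain curve.

with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(expr)
}

#' Parameters of the slow-oscillation simulator
#'
#' State durations are drawn from a normal distribution truncated below at
#' `dur_floor`. During Up states the broadband 200-1500 Hz component has
#' `up_mua_gain` times the Down-state amplitude and a band-limited 30-100 Hz
#' gamma component of `up_gamma_amp` uV is added; a low-frequency deflection
#' of `lfp_up_offset` uV marks the Up state in the raw LFP. A state whose
#' duration mean and SD are both zero is absent from the simulation.
#'
#' @param sampling_rate Hz; must exceed twice the 1500 Hz band edge.
#' @param duration total record length, s.
#' @param up_dur_mean,up_dur_sd Up-state duration mean and SD, s.
#' @param down_dur_mean,down_dur_sd Down-state duration mean and SD, s.
#' @param dur_floor truncation floor for state durations, s.
#' @param up_mua_gain dimensionless multiplier (> 1 for a detectable record)
#'   on the broadband amplitude during Up states.
#' @param mua_base_amp Down-state broadband amplitude, uV (SD of the
#'   band-passed component).
#' @param up_gamma_amp amplitude (uV, SD) of gamma noise added during Up.
#' @param lfp_up_offset uV low-frequency LFP deflection during Up states.
#' @param background_1f_amp uV (SD) of the 1/f background.
#' @param noise_sd uV of white measurement noise.
#' @param seed integer RNG seed.
#' @return object of class `slow_osc_params`.
#' @export
slow_osc_params <- function(sampling_rate = 5000, duration = 60,
                            up_dur_mean = 0.5, up_dur_sd = 0.15,
                            down_dur_mean = 0.5, down_dur_sd = 0.15,
                            dur_floor = 0.1,
                            up_mua_gain = 4, mua_base_amp = 10,
                            up_gamma_amp = 15, lfp_up_offset = 80,
                            background_1f_amp = 30, noise_sd = 5,
                            seed = 1L) {
  check_scalar(sampling_rate, "sampling_rate", lower = 2 * 1500, strict_lower = TRUE)
  check_scalar(duration, "duration", lower = 0, strict_lower = TRUE)
  for (nm in c("up_dur_mean", "up_dur_sd", "down_dur_mean", "down_dur_sd",
               "dur_floor", "mua_base_amp", "up_gamma_amp", "lfp_up_offset",
               "background_1f_amp", "noise_sd"))
    check_scalar(get(nm), nm, lower = 0)
  check_scalar(up_mua_gain, "up_mua_gain", lower = 0, strict_lower = TRUE)
  structure(list(
    sampling_rate = sampling_rate, duration = duration,
    up_dur_mean = up_dur_mean, up_dur_sd = up_dur_sd,
    down_dur_mean = down_dur_mean, down_dur_sd = down_dur_sd,
    dur_floor = dur_floor, up_mua_gain = up_mua_gain,
    mua_base_amp = mua_base_amp, up_gamma_amp = up_gamma_amp,
    lfp_up_offset = lfp_up_offset, background_1f_amp = background_1f_amp,
    noise_sd = noise_sd, seed = as.integer(seed)), class = "slow_osc_params")
}

# One truncated-normal state duration; a state with mean == sd == 0 is absent.
rdur_trunc <- function(mean, sd, floor) {
  if (mean == 0 && sd == 0) return(0)
  if (sd == 0) return(max(mean, floor))
  repeat {
    d <- stats::rnorm(1, mean, sd)
    if (d >= floor) return(d)
  }
}

# 1/f-amplitude background noise via FFT shaping, unit SD.
one_over_f_noise <- function(n, fs, f_lo = 0.1) {
  x <- stats::rnorm(n)
  X <- stats::fft(x)
  f <- seq(0, fs, length.out = n + 1)[seq_len(n)]
  f <- pmin(f, fs - f)                      # two-sided frequency axis
  w <- 1 / sqrt(pmax(f, f_lo))              # power ~ 1/f above the corner
  w[1] <- 0                                 # remove DC
  y <- Re(stats::fft(X * w, inverse = TRUE)) / n
  y / stats::sd(y)
}

#' Simulate a slow-oscillation LFP recording with ground truth
#'
#' Draws alternating Up/Down intervals (truncated-normal durations, Down
#' first), then synthesizes the voltage trace as the sum of a 1/f background,
#' white noise, a 200-1500 Hz broadband component whose amplitude is
#' state-modulated, gamma noise during Up states, and a low-pass-smoothed Up
#' deflection. The same parameters and seed give bit-identical output.
#'
#' @param params a [slow_osc_params()] object.
#' @return list with `recording` (class `lfp_recording`: `samples`,
#'   `sampling_rate`, `highpass_corner`, `channel_ids`) and `truth` (class
#'   `ground_truth`: `state_labels`, `intervals`, `generator_params`,
#'   `warning_short_record`).
#' @export
simulate_slow_oscillation <- function(params) {
  stopifnot(inherits(params, "slow_osc_params"))
  p <- params
  fs <- p$sampling_rate
  n <- round(p$duration * fs)
  cycle <- p$up_dur_mean + p$down_dur_mean
  short_record <- cycle > 0 && p$duration < cycle

  with_seed(child_seed(p$seed, "slowosc"), {
    # Realize the alternating state sequence (Down first).
    states <- integer(0); durs <- numeric(0); tot <- 0; st <- 0L
    while (tot < p$duration) {
      d <- if (st == 1L) rdur_trunc(p$up_dur_mean, p$up_dur_sd, p$dur_floor)
           else          rdur_trunc(p$down_dur_mean, p$down_dur_sd, p$dur_floor)
      if (d > 0) { states <- c(states, st); durs <- c(durs, d); tot <- tot + d }
      st <- 1L - st
      if (d == 0 && ((st == 1L && p$up_dur_mean == 0 && p$up_dur_sd == 0) ||
                     (st == 0L && p$down_dur_mean == 0 && p$down_dur_sd == 0)))
        st <- 1L - st                       # both absent would loop forever
      if (length(states) == 0 && st == 0L && p$down_dur_mean == 0 &&
          p$down_dur_sd == 0 && p$up_dur_mean == 0 && p$up_dur_sd == 0)
        stop("both states have zero duration", call. = FALSE)
    }
    ends <- pmin(round(cumsum(durs) * fs), n)
    starts <- c(0L, ends[-length(ends)])
    keep <- ends > starts
    intervals <- data.frame(state = states[keep], start_s = starts[keep] / fs,
                            end_s = ends[keep] / fs)
    # Merge accidental same-state neighbours created by clipping at n.
    labels <- intervals_to_labels(intervals, fs, n)
    intervals <- labels_to_intervals(labels, fs)

    up <- as.numeric(labels)
    broadband <- bandpass_filtfilt(stats::rnorm(n), fs, 200, 1500)
    broadband <- broadband / stats::sd(broadband)
    amp <- p$mua_base_amp * (1 + (p$up_mua_gain - 1) * up)
    gamma <- bandpass_filtfilt(stats::rnorm(n), fs, 30, 100)
    gamma <- gamma / stats::sd(gamma)
    up_smooth <- lowpass_filtfilt(up, fs, 10)
    x <- p$background_1f_amp * one_over_f_noise(n, fs) +
      amp * broadband +
      p$up_gamma_amp * gamma * up +
      p$lfp_up_offset * up_smooth +
      p$noise_sd * stats::rnorm(n)

    rec <- structure(list(samples = x, sampling_rate = fs,
                          highpass_corner = 0.1, channel_ids = "ch1"),
                     class = "lfp_recording")
    truth <- structure(list(state_labels = labels, intervals = intervals,
                            generator_params = p,
                            warning_short_record = short_record),
                       class = "ground_truth")
    if (short_record)
      warning("record shorter than one mean Up+Down cycle", call. = FALSE)
    list(recording = rec, truth = truth)
  })
}

#' Stimulation protocol description
#'
#' Defaults follow the in vivo protocol: 50 single square pulses of 0.3 ms
#' delivered at 0.1 Hz, at intensities of 40-320 uA in 40 uA steps
#' (thalamo-striatal) or 20-160 uA in 20 uA steps (thalamo-cortical).
#'
#' @param n_pulses pulses per intensity.
#' @param pulse_width_ms pulse width, ms.
#' @param rate_hz stimulation rate, Hz.
#' @param intensities_ua strictly increasing intensities, uA.
#' @export
stim_protocol <- function(n_pulses = 50, pulse_width_ms = 0.3, rate_hz = 0.1,
                          intensities_ua = seq(40, 320, by = 40)) {
  check_scalar(n_pulses, "n_pulses", lower = 1)
  check_scalar(rate_hz, "rate_hz", lower = 0, strict_lower = TRUE)
  check_scalar(pulse_width_ms, "pulse_width_ms", lower = 0, strict_lower = TRUE)
  if (length(intensities_ua) < 1 || any(diff(intensities_ua) <= 0) ||
      any(!is.finite(intensities_ua)))
    stop("`intensities_ua` must be strictly increasing and finite", call. = FALSE)
  structure(list(n_pulses = as.integer(n_pulses),
                 pulse_width_ms = pulse_width_ms, rate_hz = rate_hz,
                 intensities_ua = intensities_ua), class = "stim_protocol")
}

#' Evoked-waveform template parameters
#'
#' Each component is a Gaussian-shaped deflection `polarity * amplitude *
#' exp(-(t - latency)^2 / (2 sigma^2))` with `sigma = width / 2.355` (width is
#' the full width at half maximum). Amplitudes are scaled across intensities
#' by a saturating logistic gain in log-intensity, anchored to 1 at
#' `ref_intensity_ua`.
#'
#' @param components data.frame with columns `polarity` (+1/-1),
#'   `peak_latency_ms`, `peak_amplitude_uv` (at the reference intensity),
#'   `width_ms`.
#' @param ref_intensity_ua intensity at which the gain is exactly 1.
#' @param gain_midpoint_ua,gain_slope logistic midpoint (uA) and slope (on
#'   log-intensity).
#' @param trial_noise_sd per-trial additive noise, uV.
#' @param seed integer RNG seed.
#' @export
evoked_shape <- function(components = data.frame(
                           polarity = c(-1, 1),
                           peak_latency_ms = c(12, 25),
                           peak_amplitude_uv = c(120, 60),
                           width_ms = c(8, 14)),
                         ref_intensity_ua = 80,
                         gain_midpoint_ua = 80, gain_slope = 0.6,
                         trial_noise_sd = 5, seed = 1L) {
  stopifnot(is.data.frame(components),
            all(c("polarity", "peak_latency_ms", "peak_amplitude_uv",
                  "width_ms") %in% names(components)))
  if (any(components$peak_latency_ms <= 0) || any(components$width_ms <= 0))
    stop("component latencies and widths must be positive", call. = FALSE)
  check_scalar(trial_noise_sd, "trial_noise_sd", lower = 0)
  check_scalar(gain_slope, "gain_slope", lower = 0, strict_lower = TRUE)
  structure(list(components = components, ref_intensity_ua = ref_intensity_ua,
                 gain_midpoint_ua = gain_midpoint_ua, gain_slope = gain_slope,
                 trial_noise_sd = trial_noise_sd, seed = as.integer(seed)),
            class = "evoked_shape")
}

#' Saturating intensity gain
#'
#' Logistic in log-intensity, anchored to 1 at the reference intensity;
#' monotone non-decreasing in intensity.
#'
#' @param intensity_ua stimulation intensity, uA.
#' @param shape an [evoked_shape()] object.
#' @export
intensity_gain <- function(intensity_ua, shape) {
  f <- function(i) stats::plogis((log(i) - log(shape$gain_midpoint_ua)) /
                                   shape$gain_slope)
  f(intensity_ua) / f(shape$ref_intensity_ua)
}

evoked_template <- function(time_ms, shape, intensity_ua) {
  g <- intensity_gain(intensity_ua, shape)
  w <- numeric(length(time_ms))
  for (i in seq_len(nrow(shape$components))) {
    cmp <- shape$components[i, ]
    sigma <- cmp$width_ms / 2.355
    w <- w + cmp$polarity * cmp$peak_amplitude_uv * g *
      exp(-(time_ms - cmp$peak_latency_ms)^2 / (2 * sigma^2))
  }
  w
}

#' Simulate stimulus-locked evoked trials
#'
#' For every pulse of every intensity, emits one epoch equal to the
#' deterministic intensity-scaled template plus i.i.d. Gaussian noise. Epoch
#' time is in ms relative to stimulus onset, half-open
#' `[-baseline_ms, post_ms)`.
#'
#' @param protocol a [stim_protocol()].
#' @param shape an [evoked_shape()].
#' @param sampling_rate Hz.
#' @param baseline_ms pre-stimulus span, ms.
#' @param post_ms post-stimulus span, ms (>= 600 for long-lasting metrics).
#' @return class `evoked_trial_set`: `epochs` (list over intensities of
#'   `trials x channels x time` arrays), `time_ms`, `intensities_ua`,
#'   `templates` (noiseless `intensity x time` matrix), `protocol`, `shape`,
#'   `sampling_rate`.
#' @export
simulate_evoked_trials <- function(protocol, shape, sampling_rate = 5000,
                                   baseline_ms = 200, post_ms = 700) {
  stopifnot(inherits(protocol, "stim_protocol"), inherits(shape, "evoked_shape"))
  check_scalar(baseline_ms, "baseline_ms", lower = 0, strict_lower = TRUE)
  check_scalar(post_ms, "post_ms", lower = 600)
  isi_ms <- 1000 / protocol$rate_hz
  if (baseline_ms + post_ms > isi_ms)
    stop("epoch window exceeds the inter-stimulus interval", call. = FALSE)
  dt <- 1000 / sampling_rate
  time_ms <- seq(-baseline_ms, post_ms - dt, by = dt)
  nt <- length(time_ms)
  templates <- t(vapply(protocol$intensities_ua,
                        function(i) evoked_template(time_ms, shape, i),
                        numeric(nt)))
  epochs <- with_seed(child_seed(shape$seed, "evoked"), {
    lapply(seq_along(protocol$intensities_ua), function(k) {
      a <- array(0, dim = c(protocol$n_pulses, 1L, nt))
      for (tr in seq_len(protocol$n_pulses))
        a[tr, 1L, ] <- templates[k, ] +
          stats::rnorm(nt, sd = shape$trial_noise_sd)
      a
    })
  })
  structure(list(epochs = epochs, time_ms = time_ms,
                 intensities_ua = protocol$intensities_ua,
                 templates = templates, protocol = protocol, shape = shape,
                 sampling_rate = sampling_rate),
            class = "evoked_trial_set")
}

#' Multielectrode array geometry
#'
#' Default: a 4 x 8 grid of 32 channels at 550 um pitch, matching a cortical
#' surface array.
#'
#' @param n_channels channel count.
#' @param pitch_um spacing between recording points, um.
#' @param layout optional `n_channels x 2` matrix of coordinates (um); if
#'   omitted, a near-square grid is generated.
#' @export
array_geometry <- function(n_channels = 32, pitch_um = 550, layout = NULL) {
  check_scalar(n_channels, "n_channels", lower = 1)
  check_scalar(pitch_um, "pitch_um", lower = 0, strict_lower = TRUE)
  if (is.null(layout)) {
    ncol_g <- ceiling(sqrt(n_channels / 2))
    nrow_g <- ceiling(n_channels / ncol_g)
    g <- expand.grid(col = seq_len(ncol_g), row = seq_len(nrow_g))[seq_len(n_channels), ]
    layout <- cbind(x_um = (g$col - 1) * pitch_um, y_um = (g$row - 1) * pitch_um)
  }
  layout <- as.matrix(layout)
  if (nrow(layout) != n_channels)
    stop("`layout` must have one row per channel", call. = FALSE)
  if (anyDuplicated(layout))
    stop("channel coordinates must be unique", call. = FALSE)
  structure(list(n_channels = as.integer(n_channels), pitch_um = pitch_um,
                 layout = layout), class = "array_geometry")
}

#' Spread a single-channel evoked set over a simulated array
#'
#' Channel `k` receives the base template attenuated by
#' `exp(-distance(k, source) / decay_length)`, with fresh independent noise
#' per channel and trial.
#'
#' @param geometry an [array_geometry()].
#' @param source_channel index of the source channel in the layout.
#' @param decay_length_um spatial decay constant, um (> 0).
#' @param base a single-channel `evoked_trial_set`.
#' @return multi-channel `evoked_trial_set` with `decay_gains` attached.
#' @export
simulate_array_recording <- function(geometry, source_channel, decay_length_um,
                                     base) {
  stopifnot(inherits(geometry, "array_geometry"),
            inherits(base, "evoked_trial_set"))
  check_scalar(decay_length_um, "decay_length_um", lower = 0, strict_lower = TRUE)
  if (source_channel < 1 || source_channel > geometry$n_channels)
    stop("`source_channel` not in the layout", call. = FALSE)
  d <- sqrt(rowSums((geometry$layout -
                       matrix(geometry$layout[source_channel, ],
                              geometry$n_channels, 2, byrow = TRUE))^2))
  gains <- exp(-d / decay_length_um)
  nt <- length(base$time_ms)
  epochs <- with_seed(child_seed(base$shape$seed, "array"), {
    lapply(seq_along(base$intensities_ua), function(k) {
      ntr <- dim(base$epochs[[k]])[1]
      a <- array(0, dim = c(ntr, geometry$n_channels, nt))
      for (tr in seq_len(ntr))
        for (ch in seq_len(geometry$n_channels))
          a[tr, ch, ] <- base$templates[k, ] * gains[ch] +
            stats::rnorm(nt, sd = base$shape$trial_noise_sd)
      a
    })
  })
  out <- base
  out$epochs <- epochs
  out$geometry <- geometry
  out$decay_gains <- gains
  out$source_channel <- as.integer(source_channel)
  out
}
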