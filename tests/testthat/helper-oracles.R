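# Independent oracles and small fixture builders shared across tests.

# Brute-force minimum-duration filter: works directly on the label vector,
# re-scanning runs from scratch each iteration and flipping the samples of
# the shortest sub-minimum interior interval to the surrounding state.
brute_force_duration_filter <- function(labels, fs, min_duration) {
  labels <- as.integer(labels)
  min_len <- round(min_duration * fs)
  repeat {
    r <- rle(labels)
    k <- length(r$lengths)
    if (k <= 2) break
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    interior <- 2:(k - 1)
    short <- interior[r$lengths[interior] < min_len]
    if (length(short) == 0) break
    i <- short[which.min(r$lengths[short])]
    labels[starts[i]:ends[i]] <- r$values[i - 1]   # neighbours share a state
  }
  labels
}

# Exhaustive BH step-up oracle: tries every cutoff rank directly.
brute_force_bh <- function(p, q) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  best <- 0L
  for (i in seq_len(m)) if (ps[i] <= i * q / m) best <- i
  rej <- logical(m)
  if (best > 0) rej[o[seq_len(best)]] <- TRUE
  rej
}

# Power-iteration oracle for the leading eigenvector of a covariance matrix.
power_iteration <- function(S, iters = 500) {
  v <- rep(1, ncol(S)) / sqrt(ncol(S))
  for (i in seq_len(iters)) { v <- S %*% v; v <- v / sqrt(sum(v^2)) }
  as.numeric(v)
}

# Build an `evoked_average` directly from a channels x time waveform matrix.
make_avg <- function(waveform, time_ms, fs = 5000, normalized = FALSE) {
  w <- if (is.matrix(waveform)) waveform else matrix(waveform, nrow = 1)
  structure(list(waveform = w, sd = w * 0, median = w,
                 n_trials = 1L, time_ms = time_ms, intensity_ua = 80,
                 sampling_rate = fs, baseline_normalized = normalized),
            class = "evoked_average")
}

# Triangular deflection: 0 at t0, peak `amp` at t0 + rise, back to 0 at
# t0 + rise + fall (uV), on a standard epoch time axis.
triangle_waveform <- function(time_ms, t0 = 5, rise = 10, fall = 10,
                              amp = 100) {
  w <- numeric(length(time_ms))
  up <- time_ms >= t0 & time_ms <= t0 + rise
  w[up] <- amp * (time_ms[up] - t0) / rise
  dn <- time_ms > t0 + rise & time_ms <= t0 + rise + fall
  w[dn] <- amp * (t0 + rise + fall - time_ms[dn]) / fall
  w
}

# Random piecewise-constant binary label vector with bounded interval count.
random_label_sequence <- function(max_intervals = 200, max_run = 40) {
  k <- sample(2:max_intervals, 1)
  lens <- sample(1:max_run, k, replace = TRUE)
  start <- sample(0:1, 1)
  as.integer(rep(rep(c(start, 1L - start), length.out = k), times = lens))
}

default_time_ms <- function(fs = 5000, baseline = 100, post = 700) {
  seq(-baseline, post - 1000 / fs, by = 1000 / fs)
}
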