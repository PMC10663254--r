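#' @keywords internal
#' @importFrom mclust Mclust mclustBIC
"_PACKAGE"

# Internal validation helper: stop with a consistent message on bad scalars.
check_scalar <- function(x, name, lower = -Inf, upper = Inf,
                         strict_lower = FALSE, allow_na = FALSE) {
  if (length(x) != 1L || (!allow_na && (is.na(x) || !is.finite(x))))
    stop(sprintf("`%s` must be a single finite number", name), call. = FALSE)
  if (strict_lower) {
    if (x <= lower) stop(sprintf("`%s` must be > %g", name, lower), call. = FALSE)
  } else if (x < lower) {
    stop(sprintf("`%s` must be >= %g", name, lower), call. = FALSE)
  }
  if (x > upper) stop(sprintf("`%s` must be <= %g", name, upper), call. = FALSE)
  invisible(x)
}

#' Convert a per-sample binary label vector to an interval table
#'
#' Run-length encodes `labels` into alternating state intervals. Intervals are
#' half-open `[start_s, end_s)` in seconds from the start of the record.
#'
#' @param labels integer/logical vector of per-sample states (1 = Up, 0 = Down).
#' @param fs sampling rate of `labels` in Hz.
#' @return data.frame with columns `state`, `start_s`, `end_s`.
#' @export
labels_to_intervals <- function(labels, fs) {
  check_scalar(fs, "fs", lower = 0, strict_lower = TRUE)
  labels <- as.integer(labels)
  if (length(labels) == 0L)
    return(data.frame(state = integer(0), start_s = numeric(0), end_s = numeric(0)))
  r <- rle(labels)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths
  data.frame(state = r$values, start_s = starts / fs, end_s = ends / fs)
}

#' Convert an interval table back to a per-sample label vector
#'
#' Inverse of [labels_to_intervals()]. The intervals must tile `[0, n/fs)`
#' without gaps or overlap.
#'
#' @param intervals data.frame with `state`, `start_s`, `end_s`.
#' @param fs sampling rate in Hz.
#' @param n number of samples to emit.
#' @return integer vector of length `n`.
#' @export
intervals_to_labels <- function(intervals, fs, n) {
  labels <- integer(n)
  for (i in seq_len(nrow(intervals))) {
    a <- round(intervals$start_s[i] * fs) + 1L
    b <- round(intervals$end_s[i] * fs)
    if (a <= b) labels[a:min(b, n)] <- intervals$state[i]
  }
  labels
}

# Centered moving average with edge shrinkage (window in samples).
moving_average <- function(x, w) {
  w <- max(1L, as.integer(w))
  if (w == 1L) return(x)
  cs <- cumsum(c(0, x))
  n <- length(x)
  half <- w %/% 2L
  lo <- pmax(seq_len(n) - half, 1L)
  hi <- pmin(seq_len(n) + (w - half - 1L), n)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

# Zero-phase Butterworth band-pass (order refers to the underlying filter;
# filtfilt doubles the effective order).
bandpass_filtfilt <- function(x, fs, lo, hi, order = 4L) {
  nyq <- fs / 2
  if (hi >= nyq) stop("band upper edge must be below the Nyquist frequency", call. = FALSE)
  bf <- signal::butter(order, c(lo, hi) / nyq, type = "pass")
  as.numeric(signal::filtfilt(bf, x))
}

lowpass_filtfilt <- function(x, fs, corner, order = 2L) {
  bf <- signal::butter(order, corner / (fs / 2), type = "low")
  as.numeric(signal::filtfilt(bf, x))
}

# Trapezoidal integral wrapper (x in ms, y in signal units).
trapz_abs <- function(x, y) abs(pracma::trapz(x, y))

# Derive a child RNG seed deterministically from a parent seed and a stream
# tag (double arithmetic: exact below 2^53, reduced into 32-bit range).
child_seed <- function(seed, tag) {
  h <- sum(utf8ToInt(tag) * seq_along(utf8ToInt(tag)))
  as.integer((as.numeric(seed) * 1103 + h * 31) %% 2147483647)
}
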