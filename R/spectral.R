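# Welch power spectral density and band-power aggregation.

#' Welch power spectral density of the (z-scored) LFP
#'
#' Averaged-periodogram estimate: the signal is split into `window_s`-long
#' Hann-tapered segments with 50% overlap, each segment is zero-padded so the
#' frequency grid has `bin_hz` spacing, and the one-sided periodograms are
#' averaged. By default the input is z-scored first (centered; scaled only if
#' its SD is positive), so power is in z-units^2/Hz.
#'
#' @param x an `lfp_recording` or numeric vector.
#' @param window_s segment length, s (default 2).
#' @param bin_hz frequency bin size, Hz (default 0.1).
#' @param zscore z-score the signal before estimation (default TRUE).
#' @param fs sampling rate, required for a bare numeric vector.
#' @return class `psd_estimate`: `frequencies` (Hz), `power`, `window_s`,
#'   `bin_hz`, `n_segments`.
#' @export
welch_psd <- function(x, window_s = 2, bin_hz = 0.1, zscore = TRUE, fs = NULL) {
  v <- if (inherits(x, "lfp_recording")) x$samples else as.numeric(x)
  if (inherits(x, "lfp_recording")) fs <- x$sampling_rate
  if (is.null(fs)) stop("`fs` required for a bare numeric input", call. = FALSE)
  check_scalar(window_s, "window_s", lower = 0, strict_lower = TRUE)
  check_scalar(bin_hz, "bin_hz", lower = 0, strict_lower = TRUE)
  L <- round(window_s * fs)
  if (L > length(v))
    stop("`window_s` exceeds the record length", call. = FALSE)
  if (zscore) {
    v <- v - mean(v)
    s <- stats::sd(v)
    if (is.finite(s) && s > 0) v <- v / s
  }
  nfft <- max(L, round(fs / bin_hz))
  w <- 0.5 * (1 - cos(2 * pi * seq(0, L - 1) / (L - 1)))   # Hann taper
  step <- max(1L, L %/% 2L)
  starts <- seq(1L, length(v) - L + 1L, by = step)
  nfreq <- nfft %/% 2L + 1L
  acc <- numeric(nfreq)
  for (s0 in starts) {
    seg <- v[s0:(s0 + L - 1L)] * w
    X <- stats::fft(c(seg, numeric(nfft - L)))
    acc <- acc + Mod(X[seq_len(nfreq)])^2
  }
  pxx <- acc / (length(starts) * fs * sum(w^2))
  pxx[2:(nfreq - 1L)] <- 2 * pxx[2:(nfreq - 1L)]           # one-sided
  structure(list(frequencies = (seq_len(nfreq) - 1L) * fs / nfft,
                 power = pxx, window_s = window_s,
                 bin_hz = fs / nfft, n_segments = length(starts)),
            class = "psd_estimate")
}

#' Named frequency bands
#'
#' Default bands: alpha 8-12 Hz, beta 12-30 Hz, low-gamma 30-60 Hz,
#' high-gamma 60-100 Hz. Bands are half-open `[lo, hi)` and may share edges
#' but must not overlap.
#'
#' @param bands named list of two-element Hz ranges.
#' @export
band_power_spec <- function(bands = list(alpha = c(8, 12), beta = c(12, 30),
                                         low_gamma = c(30, 60),
                                         high_gamma = c(60, 100))) {
  stopifnot(is.list(bands), length(names(bands)) == length(bands))
  for (nm in names(bands))
    if (length(bands[[nm]]) != 2 || bands[[nm]][1] >= bands[[nm]][2])
      stop(sprintf("band `%s` must be (lower, upper) with lower < upper", nm),
           call. = FALSE)
  b <- bands[order(vapply(bands, `[`, numeric(1), 1))]
  los <- vapply(b, `[`, numeric(1), 1); his <- vapply(b, `[`, numeric(1), 2)
  if (any(los[-1] < his[-length(his)]))
    stop("bands overlap beyond shared edges", call. = FALSE)
  structure(bands, class = "band_power_spec")
}

#' Band power from a PSD estimate
#'
#' Mean PSD over each half-open band `[lo, hi)`.
#'
#' @param psd a `psd_estimate`.
#' @param spec a [band_power_spec()].
#' @return data.frame with `band`, `lo_hz`, `hi_hz`, `power`.
#' @export
band_power <- function(psd, spec = band_power_spec()) {
  stopifnot(inherits(psd, "psd_estimate"), inherits(spec, "band_power_spec"))
  fmax <- max(psd$frequencies)
  out <- lapply(names(spec), function(nm) {
    lo <- spec[[nm]][1]; hi <- spec[[nm]][2]
    if (hi > fmax + psd$bin_hz / 2)
      stop(sprintf("band `%s` exceeds the PSD frequency range", nm),
           call. = FALSE)
    sel <- psd$frequencies >= lo & psd$frequencies < hi
    data.frame(band = nm, lo_hz = lo, hi_hz = hi,
               power = mean(psd$power[sel]))
  })
  do.call(rbind, out)
}
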