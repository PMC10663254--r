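# Feature construction for Up/Down state detection: the detector combines
# three time-aligned series — the raw LFP, a log-scaled estimate of
# 200-1500 Hz power (logMUA, a proxy for population firing), and the
# envelope of the variance of the gamma-filtered LFP — z-scores each, and
# projects onto the first principal component.

feature_grid <- function(n, fs, feature_step_s) {
  dec <- max(1L, round(feature_step_s * fs))
  idx <- seq.int(from = ceiling(dec / 2), to = n, by = dec)
  list(idx = idx, dec = dec, fs = fs / dec, time_s = (idx - 1) / fs)
}

new_feature_series <- function(values, grid) {
  structure(list(values = values, fs = grid$fs, time_s = grid$time_s),
            class = "feature_series")
}

#' Log-scaled moving band power (logMUA)
#'
#' Band-passes the LFP (zero-phase Butterworth, order 4), squares it,
#' averages over a moving window, floors at `eps` and takes the natural log;
#' the result is decimated onto a regular feature grid aligned to the input
#' timeline. With the default 200-1500 Hz band this is the logMUA estimate
#' used as the firing-rate proxy.
#'
#' @param lfp an `lfp_recording` (or numeric vector with `fs` given).
#' @param band two-element Hz range; upper edge must be below Nyquist.
#' @param power_window_s moving-average window for the power estimate, s.
#' @param feature_step_s output sample step, s.
#' @param eps power floor applied before the log, uV^2.
#' @param fs sampling rate, required when `lfp` is a bare numeric vector.
#' @return a `feature_series` (fields `values`, `fs`, `time_s`).
#' @export
compute_log_mua <- function(lfp, band = c(200, 1500), power_window_s = 0.05,
                            feature_step_s = 0.005, eps = 1e-12, fs = NULL) {
  x <- if (inherits(lfp, "lfp_recording")) lfp$samples else as.numeric(lfp)
  if (inherits(lfp, "lfp_recording")) fs <- lfp$sampling_rate
  if (is.null(fs)) stop("`fs` required for a bare numeric input", call. = FALSE)
  if (band[2] >= fs / 2)
    stop("band upper edge must be below the Nyquist frequency", call. = FALSE)
  bp <- bandpass_filtfilt(x, fs, band[1], band[2])
  pow <- moving_average(bp^2, round(power_window_s * fs))
  g <- feature_grid(length(x), fs, feature_step_s)
  new_feature_series(log(pmax(pow[g$idx], eps)), g)
}

#' Envelope of the variance of the gamma-filtered LFP
#'
#' Band-passes the LFP into the gamma band, computes a moving variance, and
#' low-pass smooths the result into an envelope (clipped at zero), decimated
#' onto the feature grid.
#'
#' @param lfp an `lfp_recording` or numeric vector.
#' @param gamma_band Hz range; default 30-100 Hz spans low and high gamma.
#' @param var_window_s moving-variance window, s; must cover at least three
#'   cycles of the band's lower edge.
#' @param smooth_corner_hz low-pass corner for envelope smoothing, Hz.
#' @inheritParams compute_log_mua
#' @return a `feature_series`.
#' @export
compute_gamma_variance_envelope <- function(lfp, gamma_band = c(30, 100),
                                            var_window_s = 0.1,
                                            smooth_corner_hz = 20,
                                            feature_step_s = 0.005, fs = NULL) {
  x <- if (inherits(lfp, "lfp_recording")) lfp$samples else as.numeric(lfp)
  if (inherits(lfp, "lfp_recording")) fs <- lfp$sampling_rate
  if (is.null(fs)) stop("`fs` required for a bare numeric input", call. = FALSE)
  if (gamma_band[2] >= fs / 2)
    stop("gamma band must lie below the Nyquist frequency", call. = FALSE)
  if (var_window_s < 3 / gamma_band[1])
    stop("`var_window_s` must span at least 3 cycles of the gamma band",
         call. = FALSE)
  bp <- bandpass_filtfilt(x, fs, gamma_band[1], gamma_band[2])
  w <- round(var_window_s * fs)
  v <- pmax(moving_average(bp^2, w) - moving_average(bp, w)^2, 0)
  env <- pmax(lowpass_filtfilt(v, fs, smooth_corner_hz), 0)
  g <- feature_grid(length(x), fs, feature_step_s)
  new_feature_series(env[g$idx], g)
}

#' Assemble the z-scored multivariate feature matrix
#'
#' Decimates the raw LFP onto the same feature grid as the two derived
#' features (moving-average anti-aliasing over one feature step) and z-scores
#' each of the three columns independently over the full analyzed span.
#'
#' @param lfp the `lfp_recording` the features were derived from.
#' @param logmua,gammavar `feature_series` from [compute_log_mua()] and
#'   [compute_gamma_variance_envelope()], on identical grids.
#' @param feature_step_s feature grid step, s (must match the inputs).
#' @param fs sampling rate, required when `lfp` is a bare numeric vector.
#' @return class `feature_matrix`: `z` (columns `z_lfp`, `z_logmua`,
#'   `z_gammavar`), `fs`, `time_s`.
#' @export
build_feature_matrix <- function(lfp, logmua, gammavar,
                                 feature_step_s = 0.005, fs = NULL) {
  stopifnot(inherits(logmua, "feature_series"),
            inherits(gammavar, "feature_series"))
  x <- if (inherits(lfp, "lfp_recording")) lfp$samples else as.numeric(lfp)
  if (inherits(lfp, "lfp_recording")) fs <- lfp$sampling_rate
  if (is.null(fs)) stop("`fs` required for a bare numeric input", call. = FALSE)
  g <- feature_grid(length(x), fs, feature_step_s)
  if (length(g$idx) != length(logmua$values) ||
      length(g$idx) != length(gammavar$values))
    stop("feature series are not on a common grid", call. = FALSE)
  lfp_dec <- moving_average(x, g$dec)[g$idx]
  cols <- list(z_lfp = lfp_dec, z_logmua = logmua$values,
               z_gammavar = gammavar$values)
  z <- vapply(names(cols), function(nm) {
    v <- cols[[nm]]
    s <- stats::sd(v)
    if (!is.finite(s) || s == 0)
      stop(sprintf("feature column `%s` has zero variance", nm), call. = FALSE)
    (v - mean(v)) / s
  }, numeric(length(g$idx)))
  structure(list(z = z, fs = g$fs, time_s = g$time_s), class = "feature_matrix")
}

#' Project the feature matrix onto its first principal component
#'
#' Eigendecomposes the 3 x 3 covariance of the z-scored features and projects
#' each time sample onto the leading eigenvector. The projection is
#' standardized to unit variance and its sign is fixed so that it correlates
#' positively with the logMUA column (Up states high). If the covariance is
#' rank deficient the dominant surviving direction is used and a warning flag
#' is set.
#'
#' @param fm a `feature_matrix`.
#' @return class `projection_series`: `pc1`, `loadings` (unit norm),
#'   `explained_variance_fraction`, `fs`, `time_s`, `rank_deficient`.
#' @export
project_first_pc <- function(fm) {
  stopifnot(inherits(fm, "feature_matrix"))
  cv <- stats::cov(fm$z)
  eg <- eigen(cv, symmetric = TRUE)
  rank_def <- eg$values[length(eg$values)] < 1e-10 * eg$values[1]
  if (rank_def) warning("feature covariance is rank deficient", call. = FALSE)
  v <- eg$vectors[, 1]
  pc1 <- as.numeric(fm$z %*% v)
  if (stats::cor(pc1, fm$z[, "z_logmua"]) < 0) { v <- -v; pc1 <- -pc1 }
  s <- stats::sd(pc1)
  if (s > 0) pc1 <- pc1 / s
  structure(list(pc1 = pc1, loadings = v,
                 explained_variance_fraction = eg$values[1] / sum(eg$values),
                 fs = fm$fs, time_s = fm$time_s, rank_deficient = rank_def),
            class = "projection_series")
}
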