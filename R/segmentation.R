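# Up/Down state segmentation: bimodal Gaussian-mixture thresholding of the
# detection series, binarization, and an iterative minimum-duration filter.

#' Select a threshold from the bimodal distribution of a detection series
#'
#' Fits a two-component one-dimensional Gaussian mixture to the values
#' (unequal variances) and places the threshold at the mixture-density
#' crossing between the two component means; if no crossing lies between
#' them, the midpoint of the means is used. A bimodality diagnostic is
#' returned: Ashman's D, `|m1 - m2| / sqrt(2 (s1^2 + s2^2))`, together with a
#' valley ratio (mixture density at the threshold relative to the lower of
#' the densities at the two means). Recordings whose mixture is not clearly
#' bimodal (D below `min_separation`, or no density valley) are rejected as
#' not bistable.
#'
#' @param pc1 a `projection_series` or numeric vector of detection values.
#' @param min_separation floor on Ashman's D below which the fit is declared
#'   degenerate (2 is the conventional bimodality cutoff).
#' @param max_fit_points the mixture is fitted on at most this many points
#'   (deterministic thinning) to bound runtime.
#' @return class `bimodal_threshold`: `threshold`, `separation_index`,
#'   `valley_ratio`, `means`, `sds`, `proportions`.
#' @export
select_bimodal_threshold <- function(pc1, min_separation = 2,
                                     max_fit_points = 50000) {
  x <- if (inherits(pc1, "projection_series")) pc1$pc1 else as.numeric(pc1)
  n_min <- if (inherits(pc1, "projection_series")) ceiling(2 * pc1$fs) else 400L
  if (length(x) < n_min)
    stop("need at least 2 s of detection samples", call. = FALSE)
  if (length(x) > max_fit_points)
    x <- x[seq(1L, length(x), length.out = max_fit_points)]
  fit <- mclust::Mclust(x, G = 2, modelNames = "V", verbose = FALSE)
  if (is.null(fit))
    stop("mixture fit failed; recording does not appear bistable", call. = FALSE)
  m <- fit$parameters$mean
  s <- sqrt(fit$parameters$variance$sigmasq)
  if (length(s) == 1) s <- rep(s, 2)
  pro <- fit$parameters$pro
  o <- order(m); m <- m[o]; s <- s[o]; pro <- pro[o]
  D <- abs(diff(m)) / sqrt(2 * sum(s^2))
  dens <- function(t) pro[1] * stats::dnorm(t, m[1], s[1]) +
    pro[2] * stats::dnorm(t, m[2], s[2])
  f <- function(t) pro[1] * stats::dnorm(t, m[1], s[1]) -
    pro[2] * stats::dnorm(t, m[2], s[2])
  thr <- if (f(m[1]) * f(m[2]) < 0)
    stats::uniroot(f, lower = m[1], upper = m[2])$root else mean(m)
  valley <- dens(thr) / min(dens(m[1]), dens(m[2]))
  if (D < min_separation || valley >= 0.9)
    stop(sprintf(paste("detection values are not clearly bimodal (separation",
                       "index %.2f, valley ratio %.2f); the recording does",
                       "not appear bistable"), D, valley), call. = FALSE)
  structure(list(threshold = thr, separation_index = D, valley_ratio = valley,
                 means = m, sds = s, proportions = pro),
            class = "bimodal_threshold")
}

# Iterative shortest-first merge of sub-minimum runs, on a run-length
# encoding. Interior runs shorter than min_len are absorbed into their
# (equal-state) neighbours, shortest first, earliest on ties; runs touching
# the record edges are exempt.
merge_short_runs <- function(values, lengths, min_len) {
  repeat {
    k <- length(lengths)
    if (k <= 2L) break
    interior <- 2:(k - 1L)
    short <- interior[lengths[interior] < min_len]
    if (length(short) == 0L) break
    i <- short[which.min(lengths[short])]
    lengths[i - 1L] <- lengths[i - 1L] + lengths[i] + lengths[i + 1L]
    values <- values[-c(i, i + 1L)]
    lengths <- lengths[-c(i, i + 1L)]
  }
  list(values = values, lengths = lengths)
}

#' Binarize a detection series and enforce a minimum state duration
#'
#' Samples above the threshold are labeled Up (1), the rest Down (0). Any
#' interior interval shorter than `min_duration` is then merged into its
#' surrounding state, shortest interval first (earliest on ties), repeating
#' until none remain; intervals truncated at the record edges are exempt.
#' The default minimum of 80 ms suppresses random signal fluctuations.
#'
#' @param series a `projection_series` or numeric detection series.
#' @param threshold scalar threshold or a `bimodal_threshold`.
#' @param min_duration minimum state duration, s (default 0.080).
#' @param fs sampling rate of `series`, required for a bare numeric vector.
#' @return class `state_segmentation`: `labels`, `intervals` (`state`,
#'   `start_s`, `end_s`, half-open), `threshold_used`, `min_duration`, `fs`.
#' @export
binarize_and_filter <- function(series, threshold, min_duration = 0.080,
                                fs = NULL) {
  x <- if (inherits(series, "projection_series")) series$pc1 else
    as.numeric(series)
  if (inherits(series, "projection_series")) fs <- series$fs
  if (is.null(fs)) stop("`fs` required for a bare numeric input", call. = FALSE)
  if (inherits(threshold, "bimodal_threshold")) threshold <- threshold$threshold
  check_scalar(min_duration, "min_duration", lower = 0, strict_lower = TRUE)
  raw <- as.integer(x > threshold)
  r <- rle(raw)
  m <- merge_short_runs(r$values, r$lengths, round(min_duration * fs))
  labels <- inverse.rle(structure(list(lengths = m$lengths, values = m$values),
                                  class = "rle"))
  seg <- structure(list(labels = labels,
                        intervals = labels_to_intervals(labels, fs),
                        threshold_used = threshold,
                        min_duration = min_duration, fs = fs),
                   class = "state_segmentation")
  stopifnot(all(diff(seg$intervals$state) != 0))
  iv <- seg$intervals
  if (nrow(iv) > 2) {
    dur <- (iv$end_s - iv$start_s)[2:(nrow(iv) - 1)]
    stopifnot(all(dur >= min_duration - 0.5 / fs))
  }
  seg
}

#' Up/Down state statistics
#'
#' Mean state durations are computed over interior intervals (intervals
#' truncated at the record edges are excluded); state "firing rates" are the
#' mean logMUA over all samples labeled Up and Down respectively (arbitrary
#' log-power units).
#'
#' @param seg a `state_segmentation`.
#' @param logmua a `feature_series` aligned with `seg` (same grid).
#' @return class `state_stats`: `mean_up_duration`, `mean_down_duration`
#'   (`NA` if a state was never detected), `firing_rate_up`,
#'   `firing_rate_down`, `n_up`, `n_down`.
#' @export
state_statistics <- function(seg, logmua) {
  stopifnot(inherits(seg, "state_segmentation"))
  mu <- if (inherits(logmua, "feature_series")) logmua$values else
    as.numeric(logmua)
  if (length(mu) != length(seg$labels))
    stop("`logmua` is not aligned with the segmentation", call. = FALSE)
  iv <- seg$intervals
  interior <- if (nrow(iv) > 2) iv[2:(nrow(iv) - 1), ] else iv[0, ]
  dur <- interior$end_s - interior$start_s
  mean_dur <- function(st) {
    d <- dur[interior$state == st]
    if (length(d) == 0) NA_real_ else mean(d)
  }
  structure(list(
    mean_up_duration = mean_dur(1L), mean_down_duration = mean_dur(0L),
    firing_rate_up = if (any(seg$labels == 1L)) mean(mu[seg$labels == 1L]) else NA_real_,
    firing_rate_down = if (any(seg$labels == 0L)) mean(mu[seg$labels == 0L]) else NA_real_,
    n_up = sum(iv$state == 1L), n_down = sum(iv$state == 0L)),
    class = "state_stats")
}

#' Detect Up/Down states from a raw LFP recording
#'
#' Convenience wrapper running the full detection chain: logMUA and
#' gamma-variance features, z-scored feature matrix, first-principal-
#' component projection, bimodal threshold, binarization and duration
#' filtering. The detection series is the PC1 projection by default; set
#' `detection_signal = "logmua"` to threshold the z-scored logMUA directly.
#'
#' @param lfp an `lfp_recording`.
#' @param min_duration minimum state duration, s.
#' @param detection_signal `"pc1"` or `"logmua"`.
#' @param feature_step_s feature grid step, s.
#' @return list with `segmentation`, `stats`, `projection`, `threshold`,
#'   `features`, `logmua`.
#' @export
detect_states <- function(lfp, min_duration = 0.080,
                          detection_signal = c("pc1", "logmua"),
                          feature_step_s = 0.005) {
  detection_signal <- match.arg(detection_signal)
  logmua <- compute_log_mua(lfp, feature_step_s = feature_step_s)
  gv <- compute_gamma_variance_envelope(lfp, feature_step_s = feature_step_s)
  fm <- build_feature_matrix(lfp, logmua, gv, feature_step_s = feature_step_s)
  pr <- project_first_pc(fm)
  series <- if (detection_signal == "pc1") pr else {
    structure(list(pc1 = fm$z[, "z_logmua"], loadings = c(0, 1, 0),
                   explained_variance_fraction = NA_real_, fs = fm$fs,
                   time_s = fm$time_s, rank_deficient = FALSE),
              class = "projection_series")
  }
  thr <- select_bimodal_threshold(series)
  seg <- binarize_and_filter(series, thr, min_duration = min_duration)
  list(segmentation = seg, stats = state_statistics(seg, logmua),
       projection = pr, threshold = thr, features = fm, logmua = logmua)
}
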