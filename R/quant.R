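# Scalar quantifications (tracing normalization, spine density, Cavalieri
# volume, microdialysis percent-of-baseline) and the Benjamini-Hochberg FDR
# step-up procedure.

#' Normalize traced presynaptic input counts per starter neuron
#'
#' Monosynaptic retrograde tracing counts are made comparable across animals
#' by dividing each region's traced-neuron count by the number of striatal
#' starter neurons.
#'
#' @param counts data.frame with columns `region`, `traced_count`.
#' @param starter_count number of starter neurons (> 0).
#' @return input data.frame with an added `normalized` column.
#' @export
normalize_traced_inputs <- function(counts, starter_count) {
  stopifnot(is.data.frame(counts),
            all(c("region", "traced_count") %in% names(counts)))
  if (any(counts$traced_count < 0) ||
      any(counts$traced_count != round(counts$traced_count)))
    stop("traced counts must be non-negative integers", call. = FALSE)
  check_scalar(starter_count, "starter_count", lower = 0, strict_lower = TRUE)
  counts$normalized <- counts$traced_count / starter_count
  counts
}

#' Dendritic spine density
#'
#' Density = number of spines / segment length (spines/um). Segments not
#' longer than `min_length_um` (inclusion rule: secondary segments > 20 um)
#' are flagged `excluded` with `NA` density rather than raising an error.
#'
#' @param measures data.frame with columns `n_spines`, `segment_length_um`.
#' @param min_length_um inclusion threshold, um (default 20).
#' @return input data.frame with `density_per_um` and `excluded` columns.
#' @export
spine_density <- function(measures, min_length_um = 20) {
  stopifnot(is.data.frame(measures),
            all(c("n_spines", "segment_length_um") %in% names(measures)))
  if (any(measures$segment_length_um <= 0))
    stop("segment lengths must be positive", call. = FALSE)
  if (any(measures$n_spines < 0))
    stop("spine counts must be non-negative", call. = FALSE)
  excl <- measures$segment_length_um <= min_length_um
  measures$density_per_um <-
    ifelse(excl, NA_real_, measures$n_spines / measures$segment_length_um)
  measures$excluded <- excl
  measures
}

#' Cavalieri volume estimate from serial section areas
#'
#' Volume = section spacing x sum of section areas.
#'
#' @param areas_um2 section areas, um^2 (>= 1 section, all >= 0).
#' @param spacing_um distance between sections, um (> 0).
#' @return volume in um^3.
#' @export
cavalieri_volume <- function(areas_um2, spacing_um) {
  if (length(areas_um2) < 1 || any(!is.finite(areas_um2)) || any(areas_um2 < 0))
    stop("`areas_um2` must be >= 1 non-negative finite values", call. = FALSE)
  check_scalar(spacing_um, "spacing_um", lower = 0, strict_lower = TRUE)
  spacing_um * sum(areas_um2)
}

#' Microdialysis percent-of-baseline normalization
#'
#' Expresses each dialysate fraction as a percentage of the mean of the
#' first `n_baseline` (pre-drug) fractions.
#'
#' @param fractions fmol per fraction (>= `n_baseline` values).
#' @param n_baseline number of leading baseline fractions (default 5).
#' @return numeric vector of percentages.
#' @export
percent_of_baseline <- function(fractions, n_baseline = 5) {
  if (length(fractions) < n_baseline)
    stop(sprintf("need at least %d fractions", n_baseline), call. = FALSE)
  base <- mean(fractions[seq_len(n_baseline)])
  if (!is.finite(base) || base <= 0)
    stop("baseline mean must be positive", call. = FALSE)
  100 * fractions / base
}

#' Benjamini-Hochberg step-up false discovery rate procedure
#'
#' Sorts the m p-values ascending, finds the largest rank i with
#' `p_(i) <= i q / m`, and rejects all hypotheses of rank <= i. Adjusted
#' values are `min over j >= i of m p_(j) / j`, capped at 1; ties keep the
#' stable order of the original indices.
#'
#' @param pvalues p-values in (0, 1]; exact zeros are rejected as invalid.
#' @param q target FDR level in (0, 1).
#' @return class `pvalue_set`: `pvalues`, `q`, `rejections` (logical, in
#'   input order), `adjusted`, `n_rejected`.
#' @export
benjamini_hochberg <- function(pvalues, q = 0.05) {
  p <- as.numeric(pvalues)
  if (length(p) == 0 || any(!is.finite(p)) || any(p <= 0) || any(p > 1))
    stop("p-values must lie in (0, 1]", call. = FALSE)
  check_scalar(q, "q", lower = 0, upper = 1, strict_lower = TRUE)
  if (q >= 1) stop("`q` must be < 1", call. = FALSE)
  m <- length(p)
  o <- order(p)                         # stable in base R
  ps <- p[o]
  crit <- seq_len(m) * q / m
  k <- which(ps <= crit)
  imax <- if (length(k)) max(k) else 0L
  rej_sorted <- seq_len(m) <= imax
  adj_sorted <- rev(cummin(rev(m * ps / seq_len(m))))
  adj_sorted <- pmin(adj_sorted, 1)
  rejections <- logical(m); rejections[o] <- rej_sorted
  adjusted <- numeric(m); adjusted[o] <- adj_sorted
  structure(list(pvalues = p, q = q, rejections = rejections,
                 adjusted = adjusted, n_rejected = imax),
            class = "pvalue_set")
}
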