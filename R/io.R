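# Plain-text signal containers: CSV (one column per channel) plus a JSON
# sidecar carrying sampling metadata.

write_json_file <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Write an LFP recording to CSV with a JSON sidecar
#'
#' The CSV holds one column per channel (uV); `<path>.json` records the
#' sampling rate, units, high-pass corner and channel ids.
#'
#' @param rec an `lfp_recording`.
#' @param path output CSV path.
#' @export
write_recording_csv <- function(rec, path) {
  stopifnot(inherits(rec, "lfp_recording"))
  m <- as.data.frame(as.matrix(rec$samples))
  names(m) <- rec$channel_ids
  utils::write.csv(m, path, row.names = FALSE)
  write_json_file(list(sampling_rate = rec$sampling_rate, units = "uV",
                       highpass_corner = rec$highpass_corner,
                       channel_ids = rec$channel_ids),
                  paste0(path, ".json"))
  invisible(path)
}

#' Read an LFP recording written by [write_recording_csv()]
#'
#' @param path CSV path (its `.json` sidecar must sit beside it).
#' @return an `lfp_recording`.
#' @export
read_recording_csv <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  m <- utils::read.csv(path)
  samples <- if (ncol(m) == 1) m[[1]] else as.matrix(m)
  structure(list(samples = samples, sampling_rate = meta$sampling_rate,
                 highpass_corner = meta$highpass_corner,
                 channel_ids = meta$channel_ids), class = "lfp_recording")
}

#' Write a state segmentation interval table to CSV
#'
#' @param seg a `state_segmentation` (or a `ground_truth`).
#' @param path output CSV path; columns `state,start_s,end_s`.
#' @export
write_intervals_csv <- function(seg, path) {
  iv <- if (inherits(seg, c("state_segmentation", "ground_truth")))
    seg$intervals else seg
  utils::write.csv(iv, path, row.names = FALSE)
  invisible(path)
}
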