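#' Labelled multichannel recording
#'
#' Container for a continuous multichannel time series: a samples-by-channels
#' numeric matrix with a sampling rate and channel labels. Used for sensor
#' arrays together with an intracranial reference (LFP) channel.
#'
#' @param data Numeric matrix, samples in rows, channels in columns.
#' @param fs Sampling rate in Hz.
#' @param labels Character vector of channel labels; defaults to the column
#'   names of `data`, or `ch1, ch2, ...` when absent.
#' @return An object of class `ts_recording`.
#' @export
recording <- function(data, fs, labels = colnames(data)) {
  data <- as.matrix(data)
  if (!is.numeric(data)) stop("recording data must be numeric")
  if (!is.numeric(fs) || length(fs) != 1L || fs <= 0)
    stop("fs must be a single positive number")
  if (is.null(labels)) labels <- paste0("ch", seq_len(ncol(data)))
  if (length(labels) != ncol(data))
    stop("labels length (", length(labels), ") != number of channels (",
         ncol(data), ")")
  if (anyDuplicated(labels)) stop("channel labels must be unique")
  dimnames(data) <- list(NULL, labels)
  structure(list(data = data, fs = fs, labels = labels),
            class = "ts_recording")
}

#' @export
print.ts_recording <- function(x, ...) {
  cat(sprintf("<ts_recording> %d channels x %d samples @ %g Hz (%.1f s)\n",
              ncol(x$data), nrow(x$data), x$fs, nrow(x$data) / x$fs))
  cat("  channels:", paste(utils::head(x$labels, 8), collapse = ", "),
      if (length(x$labels) > 8) "..." else "", "\n")
  invisible(x)
}

#' Number of samples / duration of a recording
#' @param rec A `ts_recording`.
#' @return Integer sample count or duration in seconds.
#' @export
n_samples <- function(rec) nrow(rec$data)

#' @rdname n_samples
#' @export
duration <- function(rec) nrow(rec$data) / rec$fs

#' Select channels by label
#' @param rec A `ts_recording`.
#' @param labels Channel labels to keep, in the requested order.
#' @return A `ts_recording` with the selected channels.
#' @export
select_channels <- function(rec, labels) {
  miss <- setdiff(labels, rec$labels)
  if (length(miss)) stop("unknown channel(s): ", paste(miss, collapse = ", "))
  recording(rec$data[, labels, drop = FALSE], rec$fs, labels)
}

#' Reverse the sample order of a recording
#'
#' Time reversal used to construct surrogate data for the directionality
#' test: a genuine time-lagged influence flips direction under reversal,
#' while lag-free confounds do not.
#'
#' @param rec A `ts_recording`.
#' @return The recording with sample order reversed in every channel.
#' @export
reverse_time <- function(rec) {
  recording(rec$data[rev(seq_len(nrow(rec$data))), , drop = FALSE],
            rec$fs, rec$labels)
}
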