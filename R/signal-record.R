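#' Multichannel signal records
#'
#' A `signal_record` is a tibble with one numeric column per sensor channel,
#' carrying the sampling rate (Hz) and an optional class label as attributes.
#' Rows are uniformly sampled in time, in acquisition order. All posturekit
#' signal operations take and return this type, so calls chain with the pipe.
#'
#' @param samples A numeric matrix or data frame, `n_samples x n_channels`.
#' @param fs Sampling rate in Hz (positive scalar).
#' @param channel_names Optional character vector of unique channel names;
#'   defaults to the column names of `samples`, or `ch1, ch2, ...`.
#' @param label Optional class-label string attached to the whole record.
#'
#' @return A `signal_record`: a tibble of class
#'   `c("signal_record", "tbl_df", "tbl", "data.frame")` with attributes
#'   `fs` and `label`.
#' @examples
#' rec <- signal_record(cbind(sin(1:100), cos(1:100)), fs = 100,
#'                      channel_names = c("x", "y"))
#' sig_fs(rec)
#' @export
signal_record <- function(samples, fs, channel_names = NULL, label = NULL) {
  if (is.data.frame(samples)) samples <- as.matrix(samples)
  if (!is.matrix(samples)) samples <- matrix(samples, ncol = 1L)
  storage.mode(samples) <- "double"
  if (nrow(samples) < 1L || ncol(samples) < 1L) {
    stop("`samples` must have at least one row and one channel", call. = FALSE)
  }
  if (!is.numeric(fs) || length(fs) != 1L || !is.finite(fs) || fs <= 0) {
    stop("`fs` must be a single positive number (Hz)", call. = FALSE)
  }
  if (is.null(channel_names)) {
    channel_names <- colnames(samples)
    if (is.null(channel_names)) channel_names <- paste0("ch", seq_len(ncol(samples)))
  }
  channel_names <- as.character(channel_names)
  if (length(channel_names) != ncol(samples)) {
    stop("`channel_names` length must equal the number of channels", call. = FALSE)
  }
  if (anyDuplicated(channel_names)) {
    stop("channel names must be unique", call. = FALSE)
  }
  colnames(samples) <- channel_names
  out <- tibble::as_tibble(samples)
  attr(out, "fs") <- as.numeric(fs)
  attr(out, "label") <- if (is.null(label)) NULL else as.character(label)
  class(out) <- c("signal_record", class(tibble::tibble()))
  out
}

#' @rdname signal_record
#' @param x A `signal_record`.
#' @export
sig_fs <- function(x) attr(x, "fs")

#' @rdname signal_record
#' @export
sig_label <- function(x) attr(x, "label")

#' @rdname signal_record
#' @export
sig_channels <- function(x) names(x)

#' @rdname signal_record
#' @export
sig_matrix <- function(x) {
  m <- as.matrix(as.data.frame(x))
  storage.mode(m) <- "double"
  m
}

#' @export
print.signal_record <- function(x, ...) {
  lab <- sig_label(x)
  cat(sprintf(
    "<signal_record> %d samples x %d channels @ %g Hz%s\n",
    nrow(x), ncol(x), sig_fs(x),
    if (is.null(lab)) "" else paste0("  label: ", lab)
  ))
  NextMethod()
}

assert_signal_record <- function(x, arg = "record") {
  if (!inherits(x, "signal_record")) {
    stop(sprintf("`%s` must be a signal_record (see ?signal_record)", arg),
         call. = FALSE)
  }
  if (is.null(sig_fs(x)) || sig_fs(x) <= 0) {
    stop(sprintf("`%s` has no valid sampling rate", arg), call. = FALSE)
  }
  invisible(x)
}

# rebuild a record from a transformed sample matrix, keeping metadata
rewrap_record <- function(template, samples) {
  signal_record(samples, fs = sig_fs(template),
                channel_names = sig_channels(template),
                label = sig_label(template))
}
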