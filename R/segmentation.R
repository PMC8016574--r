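#' Active-segment detection by moving-average energy thresholding
#'
#' The detector squares a single sEMG channel to get its instantaneous
#' energy, smooths it with a fixed-length forward moving window, and marks a
#' motion onset at the first index where the averaged energy rises to, and
#' stays at or above, a threshold for a full window; offsets are declared
#' symmetrically when the energy stays below the threshold for a full
#' window. The threshold is a fixed fraction (default 2%) of the maximum of
#' the averaged-energy sequence, so detection is invariant to overall
#' amplitude scaling.
#'
#' @name segmentation
NULL

#' Segmenter configuration
#'
#' @param window_len Moving-average window length N in samples (default 128).
#'   The same N is used as the sustain length for onset/offset declaration.
#' @param threshold_fraction Threshold as a proportion of the maximum
#'   averaged energy (default 0.02, i.e. 2%).
#' @param min_segment_len Minimum retained segment length in samples
#'   (default `window_len`); shorter detections are discarded.
#' @param merge_gap Segments separated by fewer than this many samples are
#'   merged (default `window_len / 2`).
#' @return A `segmenter_config` list.
#' @export
segmenter_config <- function(window_len = 128L, threshold_fraction = 0.02,
                             min_segment_len = window_len,
                             merge_gap = window_len %/% 2L) {
  window_len <- as.integer(window_len)
  if (window_len < 1L) stop("`window_len` must be >= 1", call. = FALSE)
  if (!is.numeric(threshold_fraction) || threshold_fraction <= 0 ||
      threshold_fraction >= 1) {
    stop("`threshold_fraction` must lie in (0, 1)", call. = FALSE)
  }
  if (min_segment_len < 1L) stop("`min_segment_len` must be >= 1", call. = FALSE)
  structure(
    list(window_len = window_len,
         threshold_fraction = as.numeric(threshold_fraction),
         min_segment_len = as.integer(min_segment_len),
         merge_gap = as.integer(merge_gap)),
    class = "segmenter_config"
  )
}

#' Instantaneous energy of a single channel
#'
#' Squares the signal sample-wise: `E[i] = x[i]^2`.
#'
#' @param x Numeric vector, one channel.
#' @return Numeric vector of the same length, all values >= 0.
#' @export
instantaneous_energy <- function(x) {
  if (length(x) < 1L) stop("`x` must be non-empty", call. = FALSE)
  as.numeric(x)^2
}

#' Forward moving-average of an energy sequence
#'
#' `out[i] = mean(E[i..i+N-1])` (1-based), a causal-forward window; the
#' output has `length(E) - N + 1` values and carries `window_len = N` as an
#' attribute.
#'
#' @param energy Nonnegative numeric vector (instantaneous energy).
#' @param window_len Window length N in samples, `1 <= N <= length(energy)`.
#' @return Numeric vector of windowed means with attribute `window_len`.
#' @export
moving_average_energy <- function(energy, window_len) {
  window_len <- as.integer(window_len)
  if (window_len < 1L) stop("`window_len` must be >= 1", call. = FALSE)
  if (window_len > length(energy)) {
    stop(sprintf("`window_len` (%d) exceeds the sequence length (%d)",
                 window_len, length(energy)), call. = FALSE)
  }
  cs <- cumsum(c(0, as.numeric(energy)))
  n <- length(energy)
  out <- (cs[(window_len + 1L):(n + 1L)] - cs[1L:(n - window_len + 1L)]) /
    window_len
  attr(out, "window_len") <- window_len
  out
}

#' Detection threshold from the averaged-energy maximum
#'
#' Returns `fraction * max(ema)`. If the sequence is identically zero the
#' threshold is 0 and a warning is emitted, since no burst can then be
#' detected.
#'
#' @param ema Averaged-energy sequence (from [moving_average_energy()]).
#' @param fraction Proportion of the maximum (default 0.02).
#' @return A single nonnegative energy value.
#' @export
compute_threshold <- function(ema, fraction = 0.02) {
  if (length(ema) < 1L) stop("`ema` must be non-empty", call. = FALSE)
  if (fraction <= 0 || fraction >= 1) {
    stop("`fraction` must lie in (0, 1)", call. = FALSE)
  }
  mx <- max(ema)
  if (mx == 0) {
    warning("averaged energy is identically zero; threshold is 0 and no burst can be detected")
    return(0)
  }
  fraction * mx
}

#' Detect active segments in an averaged-energy sequence
#'
#' An onset is declared at index `t` where the averaged energy is at or
#' above the threshold and remains so for `window_len` consecutive samples;
#' an offset is declared where it stays below the threshold for
#' `window_len` consecutive samples (or at the record end, with a warning,
#' for a burst still active there). Detections shorter than
#' `min_segment_len` are discarded, then detections separated by fewer than
#' `merge_gap` samples are merged. Indices are 0-based raw-signal
#' coordinates with the moving window anchored at its left edge, and
#' intervals are half-open `[start, end)`.
#'
#' @param ema Averaged-energy sequence produced with `cfg$window_len`.
#' @param threshold Nonnegative energy threshold.
#' @param cfg A [segmenter_config()].
#' @param channel Channel name recorded in the output (default `"all"`).
#' @return A tibble with integer columns `start`, `end` and character
#'   column `channel`; rows sorted and non-overlapping.
#' @export
detect_active_segments <- function(ema, threshold, cfg = segmenter_config(),
                                   channel = "all") {
  if (threshold < 0) stop("`threshold` must be >= 0", call. = FALSE)
  n <- length(ema)
  N <- cfg$window_len
  if (threshold == 0) {
    # energy is nonnegative, so no upward crossing from < 0 can exist;
    # a zero threshold (all-quiet record) detects nothing
    return(tibble::tibble(start = integer(0), end = integer(0),
                          channel = character(0)))
  }
  supra <- as.numeric(ema) >= threshold
  r <- rle(supra)
  run_start <- cumsum(c(1L, r$lengths))[seq_along(r$lengths)]

  starts <- integer(0)
  ends <- integer(0)
  open <- NA_integer_
  for (k in seq_along(r$lengths)) {
    if (r$values[k] && is.na(open) && r$lengths[k] >= N) {
      open <- run_start[k]
    } else if (!r$values[k] && !is.na(open) && r$lengths[k] >= N) {
      starts <- c(starts, open)
      ends <- c(ends, run_start[k])
      open <- NA_integer_
    }
  }
  if (!is.na(open)) {
    warning(warningCondition(
      "burst still active at record end; segment closed at the final sample",
      class = "posturekit_open_burst"
    ))
    starts <- c(starts, open)
    ends <- c(ends, n + 1L)
  }

  # to 0-based raw coordinates (left-anchored forward window: ema i <-> raw i)
  seg <- tibble::tibble(start = starts - 1L, end = ends - 1L)
  seg <- seg[seg$end - seg$start >= cfg$min_segment_len, , drop = FALSE]
  seg <- merge_close_segments(seg, cfg$merge_gap)
  seg$channel <- rep(channel, nrow(seg))
  seg
}

merge_close_segments <- function(seg, gap) {
  if (nrow(seg) <= 1L) return(seg)
  seg <- seg[order(seg$start), , drop = FALSE]
  out_start <- seg$start[1L]
  out_end <- seg$end[1L]
  starts <- integer(0); ends <- integer(0)
  for (i in seq_len(nrow(seg))[-1L]) {
    if (seg$start[i] - out_end < gap) {
      out_end <- max(out_end, seg$end[i])
    } else {
      starts <- c(starts, out_start); ends <- c(ends, out_end)
      out_start <- seg$start[i]; out_end <- seg$end[i]
    }
  }
  tibble::tibble(start = c(starts, out_start), end = c(ends, out_end))
}

#' Segment one channel of a signal record
#'
#' Composes [instantaneous_energy()], [moving_average_energy()],
#' [compute_threshold()] and [detect_active_segments()] on the named
#' channel.
#'
#' @param record A [signal_record].
#' @param cfg A [segmenter_config()].
#' @param channel Channel name to segment (default: first channel).
#' @return A tibble of segments (`start`, `end`, `channel`), 0-based
#'   half-open raw-signal indices.
#' @examples
#' x <- c(rnorm(500, sd = 0.01), rnorm(400, sd = 1), rnorm(500, sd = 0.01))
#' rec <- signal_record(matrix(x), fs = 1000, channel_names = "emg")
#' segment_record(rec, channel = "emg")
#' @export
segment_record <- function(record, cfg = segmenter_config(),
                           channel = sig_channels(record)[1L]) {
  assert_signal_record(record)
  if (!channel %in% sig_channels(record)) {
    stop("unknown channel: ", channel, call. = FALSE)
  }
  x <- sig_matrix(record)[, channel]
  ema <- moving_average_energy(instantaneous_energy(x), cfg$window_len)
  thr <- compute_threshold(ema, cfg$threshold_fraction)
  detect_active_segments(ema, thr, cfg, channel = channel)
}
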