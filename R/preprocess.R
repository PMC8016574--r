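#' Zero-phase Butterworth filtering of signal records
#'
#' Both filters design a Butterworth prototype and apply it forward and
#' backward (so the effective magnitude response is squared and the phase
#' response is zero, leaving burst onsets unshifted). Edge transients are
#' suppressed by odd-reflection padding before filtering, as is conventional
#' for zero-phase offline filtering.
#'
#' Defaults follow common wearable-sensor practice: sEMG is band-passed
#' 20-450 Hz (motion artifact below, negligible sEMG power above);
#' acceleration and plantar pressure are low-passed at 20 Hz, above the
#' frequency content of voluntary gait.
#'
#' @param record A [signal_record].
#' @param low_hz,high_hz Band edges in Hz, `0 < low_hz < high_hz < fs/2`.
#' @param cutoff_hz Low-pass cutoff in Hz, `0 < cutoff_hz < fs/2`.
#' @param order Butterworth prototype order (>= 1); the forward-backward
#'   pass doubles the effective order.
#' @return A [signal_record] of the same shape, sampling rate, channel
#'   names and label, containing the filtered samples.
#' @examples
#' rec <- signal_record(matrix(rnorm(2000), ncol = 2), fs = 1000)
#' filtered <- bandpass_filter(rec, 20, 450)
#' @export
bandpass_filter <- function(record, low_hz = 20, high_hz = 450, order = 4) {
  assert_signal_record(record)
  fs <- sig_fs(record)
  check_filter_band(low_hz, high_hz, fs, order)
  bf <- signal::butter(order, c(low_hz, high_hz) / (fs / 2), type = "pass")
  apply_filtfilt(record, bf, order, f_corner = low_hz)
}

#' @rdname bandpass_filter
#' @export
lowpass_filter <- function(record, cutoff_hz = 20, order = 4) {
  assert_signal_record(record)
  fs <- sig_fs(record)
  if (!is.numeric(cutoff_hz) || cutoff_hz <= 0 || cutoff_hz >= fs / 2) {
    stop(sprintf("`cutoff_hz` must lie in (0, Nyquist = %g Hz)", fs / 2),
         call. = FALSE)
  }
  if (order < 1) stop("`order` must be >= 1", call. = FALSE)
  bf <- signal::butter(order, cutoff_hz / (fs / 2), type = "low")
  apply_filtfilt(record, bf, order, f_corner = cutoff_hz)
}

check_filter_band <- function(low_hz, high_hz, fs, order) {
  if (!is.numeric(low_hz) || !is.numeric(high_hz) || low_hz <= 0 ||
      low_hz >= high_hz) {
    stop("need 0 < low_hz < high_hz", call. = FALSE)
  }
  if (high_hz >= fs / 2) {
    stop(sprintf("`high_hz` (%g) must be below the Nyquist frequency %g Hz",
                 high_hz, fs / 2), call. = FALSE)
  }
  if (order < 1) stop("`order` must be >= 1", call. = FALSE)
  invisible(TRUE)
}

# forward-backward filtering with odd-reflection padding on each channel
apply_filtfilt <- function(record, bf, order, f_corner) {
  m <- sig_matrix(record)
  n <- nrow(m)
  # band-pass doubles the state dimension, hence 2*order taps per direction
  warmup <- 3L * (2L * order + 1L)
  if (n <= warmup) {
    stop(sprintf(
      "record too short for the filter warm-up: %d samples <= %d required",
      n, warmup
    ), call. = FALSE)
  }
  # pad long enough for the slowest pole (near the lowest corner) to settle
  pad <- min(n - 1L, max(warmup, ceiling(12 * sig_fs(record) / f_corner)))
  out <- apply(m, 2L, function(x) filtfilt_padded(bf, x, pad))
  rewrap_record(record, out)
}

filtfilt_padded <- function(bf, x, pad) {
  n <- length(x)
  left <- 2 * x[1L] - x[seq(pad + 1L, 2L, by = -1L)]
  right <- 2 * x[n] - x[seq(n - 1L, n - pad, by = -1L)]
  ext <- c(left, x, right)
  y <- as.numeric(signal::filter(bf, ext))
  y <- rev(as.numeric(signal::filter(bf, rev(y))))
  y[seq(pad + 1L, pad + n)]
}
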