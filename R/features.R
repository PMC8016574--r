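#' Wavelet / feature-extraction configuration
#'
#' @param basis_emg Wavelet basis for the sEMG discrete wavelet transform
#'   (default `"db4"`).
#' @param level_emg sEMG decomposition depth, 3 to 5 (default 3, giving the
#'   `a3, d3, d2, d1` subbands).
#' @param basis_gait Wavelet basis for the gait wavelet-packet transform
#'   (default `"db1"`).
#' @param level_gait Gait packet depth (default 3, giving 8 terminal
#'   subspaces per axis).
#' @param svd_embed_rows Number of rows of the Hankel trajectory matrix
#'   built from each subband before taking its largest singular value
#'   (default 10).
#' @return A `wavelet_config` list.
#' @export
wavelet_config <- function(basis_emg = "db4", level_emg = 3L,
                           basis_gait = "db1", level_gait = 3L,
                           svd_embed_rows = 10L) {
  level_emg <- as.integer(level_emg)
  if (level_emg < 3L || level_emg > 5L) {
    stop("`level_emg` must be 3, 4 or 5", call. = FALSE)
  }
  if (svd_embed_rows < 1L) stop("`svd_embed_rows` must be >= 1", call. = FALSE)
  structure(
    list(basis_emg = basis_emg, level_emg = level_emg,
         basis_gait = basis_gait, level_gait = as.integer(level_gait),
         svd_embed_rows = as.integer(svd_embed_rows)),
    class = "wavelet_config"
  )
}

#' Population standard deviation of a signal segment
#'
#' `sqrt(mean((x - mean(x))^2))` — the population form with divisor N, the
#' amplitude-dispersion feature used for sEMG segments.
#'
#' @param x Numeric vector with at least 2 samples.
#' @return A nonnegative scalar.
#' @export
standard_deviation <- function(x) {
  if (length(x) < 2L) stop("need at least 2 samples", call. = FALSE)
  x <- as.numeric(x)
  sqrt(mean((x - mean(x))^2))
}

#' Largest singular value of each subband's trajectory matrix
#'
#' Each 1-D coefficient vector is embedded as a Hankel trajectory matrix
#' `A` with `embed_rows` rows (row i holds the subband delayed by i - 1
#' samples); the feature is the largest singular value of `A`, i.e. the
#' positive square root of the largest eigenvalue of `A A^T`.
#'
#' @param subbands List of numeric coefficient vectors (e.g. from
#'   [dwt_subbands()]).
#' @param embed_rows Trajectory-matrix height (default 10); each subband
#'   must be at least this long.
#' @return Named numeric vector, one nonnegative value per subband.
#' @export
subband_singular_values <- function(subbands, embed_rows = 10L) {
  embed_rows <- as.integer(embed_rows)
  if (embed_rows < 1L) stop("`embed_rows` must be >= 1", call. = FALSE)
  out <- vapply(subbands, function(v) {
    if (length(v) < embed_rows) {
      stop(sprintf("subband length %d is shorter than embed_rows = %d",
                   length(v), embed_rows), call. = FALSE)
    }
    A <- trajectory_matrix(v, embed_rows)
    svd(A, nu = 0L, nv = 0L)$d[1L]
  }, numeric(1))
  names(out) <- names(subbands)
  out
}

trajectory_matrix <- function(v, m) {
  n <- length(v)
  k <- n - m + 1L
  idx <- outer(seq_len(m), seq_len(k) - 1L, `+`)
  matrix(v[idx], nrow = m)
}

#' sEMG feature vector for one active segment
#'
#' For every channel of the record, restricted to the segment: the
#' population standard deviation followed by the largest singular value of
#' each wavelet subband (`level + 1` values). Channels are concatenated in
#' channel order with names like `biceps.sd`, `biceps.svd.a3`, ...
#'
#' @param record A [signal_record].
#' @param segment One segment: a list/one-row data frame with 0-based
#'   half-open `start`/`end` sample indices.
#' @param cfg A [wavelet_config()].
#' @return A named numeric vector of `n_channels * (level_emg + 2)`
#'   features.
#' @export
emg_feature_vector <- function(record, segment, cfg = wavelet_config()) {
  assert_signal_record(record)
  start <- as.integer(segment$start[[1L]])
  end <- as.integer(segment$end[[1L]])
  if (start < 0L || end <= start || end > nrow(record)) {
    stop("segment out of record bounds", call. = FALSE)
  }
  m <- sig_matrix(record)[(start + 1L):end, , drop = FALSE]
  feats <- lapply(sig_channels(record), function(ch) {
    x <- m[, ch]
    sb <- dwt_subbands(x, cfg$basis_emg, cfg$level_emg)
    sv <- subband_singular_values(sb, cfg$svd_embed_rows)
    v <- c(standard_deviation(x), sv)
    names(v) <- paste0(ch, ".", c("sd", paste0("svd.", names(sb))))
    v
  })
  unlist(feats)
}

#' Time-domain acceleration features
#'
#' Per axis: mean, population standard deviation and population variance
#' (9 values for a triaxial window), named `<axis>.mean`, `<axis>.sd`,
#' `<axis>.var`.
#'
#' @param acc_window Numeric matrix, `n x 3` (columns = axes), n >= 2.
#' @return Named numeric vector of 9 features.
#' @export
acc_time_features <- function(acc_window) {
  acc_window <- as.matrix(acc_window)
  if (ncol(acc_window) != 3L) {
    stop("`acc_window` must have exactly 3 axis columns", call. = FALSE)
  }
  if (nrow(acc_window) < 2L) stop("window too short", call. = FALSE)
  axes <- colnames(acc_window)
  if (is.null(axes)) axes <- c("ax", "ay", "az")
  out <- lapply(seq_len(3L), function(j) {
    x <- acc_window[, j]
    s <- standard_deviation(x)
    v <- c(mean(x), s, s^2)
    names(v) <- paste0(axes[j], c(".mean", ".sd", ".var"))
    v
  })
  unlist(out)
}

#' Mean forefoot-heel pressure difference
#'
#' `mean(forefoot - heel)`; positive when forefoot loading dominates the
#' window (toe-strike patterns such as stair ascent), negative when heel
#' loading dominates (stair descent).
#'
#' @param forefoot,heel Equal-length numeric pressure vectors.
#' @return A scalar.
#' @export
pressure_diff_mean <- function(forefoot, heel) {
  if (length(forefoot) != length(heel) || length(forefoot) < 1L) {
    stop("`forefoot` and `heel` must be non-empty and equal length",
         call. = FALSE)
  }
  mean(as.numeric(forefoot) - as.numeric(heel))
}

#' Gait feature vector for one time-aligned window
#'
#' Fusion features are the 9 time-domain acceleration statistics, the
#' `3 x 2^level` wavelet-packet energies (one spectrum per axis), and the
#' mean forefoot-heel pressure difference — 34 features at the default
#' level 3. `"acc_only"` drops the pressure feature (33), and
#' `"pressure_only"` keeps only it (1); the fusion vector is exactly the
#' concatenation of the two.
#'
#' @param acc_window `n x 3` acceleration matrix.
#' @param pressure_window `n x 2` matrix, columns forefoot then heel.
#' @param cfg A [wavelet_config()].
#' @param mode `"fusion"` (default), `"acc_only"` or `"pressure_only"`.
#' @return A named numeric vector.
#' @export
gait_feature_vector <- function(acc_window, pressure_window,
                                cfg = wavelet_config(),
                                mode = c("fusion", "acc_only", "pressure_only")) {
  mode <- match.arg(mode)
  acc_window <- as.matrix(acc_window)
  axes <- colnames(acc_window)
  if (is.null(axes)) axes <- c("ax", "ay", "az")
  acc_part <- function() {
    wpe <- lapply(seq_len(3L), function(j) {
      e <- wavelet_packet_energy(acc_window[, j], cfg$basis_gait, cfg$level_gait)
      names(e) <- paste0(axes[j], ".", names(e))
      e
    })
    c(acc_time_features(acc_window), unlist(wpe))
  }
  press_part <- function() {
    pressure_window <- as.matrix(pressure_window)
    if (ncol(pressure_window) != 2L) {
      stop("`pressure_window` must have 2 columns (forefoot, heel)",
           call. = FALSE)
    }
    c(pressure.diff.mean = pressure_diff_mean(pressure_window[, 1L],
                                              pressure_window[, 2L]))
  }
  switch(mode,
         fusion = c(acc_part(), press_part()),
         acc_only = acc_part(),
         pressure_only = press_part())
}

#' Fixed-length sliding windows over a record
#'
#' @param record A [signal_record].
#' @param window_s Window duration in seconds (default 2).
#' @param overlap Fractional overlap between consecutive windows in
#'   `[0, 1)` (default 0.5).
#' @return A tibble with 0-based half-open `start`/`end` columns.
#' @export
sliding_windows <- function(record, window_s = 2, overlap = 0.5) {
  assert_signal_record(record)
  len <- as.integer(round(window_s * sig_fs(record)))
  if (len < 2L) stop("window too short", call. = FALSE)
  if (overlap < 0 || overlap >= 1) stop("`overlap` must lie in [0, 1)", call. = FALSE)
  step <- max(1L, as.integer(round(len * (1 - overlap))))
  n <- nrow(record)
  if (n < len) return(tibble::tibble(start = integer(0), end = integer(0)))
  starts <- seq.int(0L, n - len, by = step)
  tibble::tibble(start = starts, end = starts + len)
}
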