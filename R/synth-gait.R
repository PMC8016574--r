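#' Synthetic gait trials (triaxial acceleration + plantar pressure)
#'
#' Generates five-mode gait trials: an ankle-worn triaxial accelerometer
#' (channels `ax`, `ay`, `az`, units of g, gravity included) and two
#' membrane pressure sensors (`forefoot`, `heel`, arbitrary load units).
#' Locomotion modes are sinusoid-plus-harmonic oscillations at a
#' mode-specific step frequency with anti-phase forefoot/heel loading;
#' stair ascent shifts loading forefoot-ward and descent heel-ward (this
#' is what gives the pressure-difference feature its discriminative
#' power). Waiting is a static stance: gravity, sensor noise, constant
#' mid-foot load. Falling is a single high-amplitude transient at a random
#' time, after which the gravity vector rotates from the vertical to the
#' anteroposterior axis (body horizontal) and plantar load drops to zero.
#'
#' Stair ascent and descent share a step frequency and acceleration
#' amplitudes by construction, so they are separable only through the
#' pressure channels — acceleration-only classification is expected to
#' confuse them while sensor fusion resolves them.
#'
#' @param fs Sampling rate in Hz (default 100).
#' @param modes Gait-mode labels.
#' @param trial_duration Trial length in seconds (default 10).
#' @param acc_noise_sd Accelerometer noise SD in g (default 0.02, typical
#'   of a resting MEMS accelerometer; static modes are then orders of
#'   magnitude quieter than locomotion).
#' @param pressure_noise_sd Pressure sensor noise SD (default 0.03).
#' @param pressure_amp Full-load pressure amplitude (default 1).
#' @param n_trials_per_mode Trials per mode (default 12).
#' @param seed Integer master seed.
#' @return A `gait_synth_config` list.
#' @export
gait_synth_config <- function(fs = 100,
                              modes = c("walking", "waiting", "upstairs",
                                        "downstairs", "falling"),
                              trial_duration = 10,
                              acc_noise_sd = 0.02,
                              pressure_noise_sd = 0.03,
                              pressure_amp = 1,
                              n_trials_per_mode = 12L,
                              seed = 1L) {
  structure(
    list(fs = fs, modes = modes, trial_duration = trial_duration,
         acc_noise_sd = acc_noise_sd, pressure_noise_sd = pressure_noise_sd,
         pressure_amp = pressure_amp,
         n_trials_per_mode = as.integer(n_trials_per_mode),
         seed = as.integer(seed)),
    class = "gait_synth_config"
  )
}

# per-mode dynamics: step frequency (Hz), per-axis oscillation amplitude
# (g), and forefoot/heel loading scales
gait_mode_params <- function(mode) {
  switch(
    mode,
    walking = list(step_freq = 1.9, amp = c(ax = 0.35, ay = 0.25, az = 0.80),
                   ff = 1.0, heel = 1.0),
    upstairs = list(step_freq = 1.4, amp = c(ax = 0.50, ay = 0.35, az = 0.90),
                    ff = 1.3, heel = 0.5),
    downstairs = list(step_freq = 1.4, amp = c(ax = 0.50, ay = 0.35, az = 0.90),
                      ff = 0.5, heel = 1.3),
    waiting = list(step_freq = 0, amp = c(ax = 0, ay = 0, az = 0),
                   ff = 0.5, heel = 0.5),
    falling = list(step_freq = 0, amp = c(ax = 0, ay = 0, az = 0),
                   ff = 0.5, heel = 0.5),
    stop("unknown gait mode: ", mode, call. = FALSE)
  )
}

#' Generate one synthetic gait trial
#'
#' @param mode One of `cfg$modes`.
#' @param cfg A [gait_synth_config()].
#' @param trial_seed Integer seed; output is deterministic given
#'   `(mode, cfg, trial_seed)`.
#' @return A labelled [signal_record] with channels
#'   `ax, ay, az, forefoot, heel`. For falling trials the attribute
#'   `event_sample` holds the 0-based sample index of the impact onset.
#' @export
gen_gait_trial <- function(mode, cfg = gait_synth_config(), trial_seed = 1L) {
  if (!mode %in% cfg$modes) stop("unknown gait mode: ", mode, call. = FALSE)
  p <- gait_mode_params(mode)
  n <- as.integer(round(cfg$trial_duration * cfg$fs))
  t <- (seq_len(n) - 1L) / cfg$fs
  event_sample <- NULL

  withr::with_seed(as.integer(trial_seed), {
    f <- p$step_freq * stats::runif(1, 0.95, 1.05)
    amp <- p$amp * stats::runif(3, 0.9, 1.1)
    phase <- stats::runif(3, 0, 2 * pi)
    gait_phase <- stats::runif(1, 0, 2 * pi)

    grav_z <- rep(1, n)
    grav_x <- rep(0, n)
    osc <- sapply(seq_len(3L), function(j) {
      if (f <= 0) return(numeric(n))
      amp[j] * (sin(2 * pi * f * t + phase[j]) +
                  0.3 * sin(4 * pi * f * t + 2 * phase[j]))
    })
    transient <- matrix(0, n, 3L)
    load_gate <- rep(1, n)

    if (mode == "falling") {
      t0 <- stats::runif(1, 0.3 * cfg$trial_duration, 0.7 * cfg$trial_duration)
      event_sample <- as.integer(floor(t0 * cfg$fs))
      # body rotates to horizontal over ~0.5 s around the impact
      rot <- stats::plogis((t - t0) / 0.08)
      grav_z <- 1 - rot
      grav_x <- rot
      bump <- exp(-((t - t0) / 0.12)^2)
      transient[, 1L] <- 1.5 * bump
      transient[, 3L] <- -2.5 * bump
      load_gate <- exp(-pmax(t - t0, 0) / 0.25)
      load_gate[t < t0] <- 1
    }

    acc <- osc + transient +
      cbind(grav_x, 0, grav_z) +
      matrix(stats::rnorm(3L * n, sd = cfg$acc_noise_sd), n, 3L)

    if (f > 0) {
      s <- 0.5 * (1 + tanh(4 * sin(2 * pi * f * t + gait_phase)))
      forefoot <- cfg$pressure_amp * p$ff * s
      heel <- cfg$pressure_amp * p$heel * (1 - s)
    } else {
      forefoot <- rep(cfg$pressure_amp * p$ff, n)
      heel <- rep(cfg$pressure_amp * p$heel, n)
    }
    # slow load-redistribution drift (postural sway / weight shifting),
    # independent per sensor, present whenever the foot is loaded
    drift_f <- stats::runif(2, 0.05, 0.25)
    drift_p <- stats::runif(2, 0, 2 * pi)
    forefoot <- forefoot + 0.08 * cfg$pressure_amp *
      sin(2 * pi * drift_f[1L] * t + drift_p[1L])
    heel <- heel + 0.08 * cfg$pressure_amp *
      sin(2 * pi * drift_f[2L] * t + drift_p[2L])
    # after a fall the shoe keeps a small random residual contact load
    resid <- stats::runif(2, 0, 0.15) * cfg$pressure_amp
    forefoot <- forefoot * load_gate + resid[1L] * (1 - load_gate) +
      stats::rnorm(n, sd = cfg$pressure_noise_sd)
    heel <- heel * load_gate + resid[2L] * (1 - load_gate) +
      stats::rnorm(n, sd = cfg$pressure_noise_sd)
  })

  rec <- signal_record(cbind(acc, forefoot, heel), fs = cfg$fs,
                       channel_names = c("ax", "ay", "az", "forefoot", "heel"),
                       label = mode)
  attr(rec, "event_sample") <- event_sample
  rec
}

#' Generate a labelled gait feature dataset
#'
#' Low-pass filters each synthetic trial, slides fixed-length windows over
#' it, and extracts one gait feature vector per window. For falling trials
#' the pre-impact windows (entirely before the transient) are dropped, so
#' only windows that actually contain or follow the fall carry the
#' `falling` label.
#'
#' @param cfg A [gait_synth_config()].
#' @param wav_cfg A [wavelet_config()].
#' @param mode Feature set: `"fusion"` (34 features), `"acc_only"` (33)
#'   or `"pressure_only"` (1).
#' @param window_s,overlap Sliding-window duration (s) and fractional
#'   overlap; defaults 2 s and 0.5.
#' @param lowpass_hz Pre-filter cutoff in Hz (default 20).
#' @return A tibble with columns `label`, `trial` (identifier) and the
#'   gait features.
#' @export
gen_gait_dataset <- function(cfg = gait_synth_config(),
                             wav_cfg = wavelet_config(),
                             mode = c("fusion", "acc_only", "pressure_only"),
                             window_s = 2, overlap = 0.5, lowpass_hz = 20) {
  mode <- match.arg(mode)
  n_total <- length(cfg$modes) * cfg$n_trials_per_mode
  seeds <- derive_seeds(cfg$seed, n_total)
  rows <- list()
  idx <- 0L
  for (gm in cfg$modes) {
    for (tr in seq_len(cfg$n_trials_per_mode)) {
      idx <- idx + 1L
      rec <- gen_gait_trial(gm, cfg, seeds[idx])
      event <- attr(rec, "event_sample")
      filtered <- lowpass_filter(rec, lowpass_hz)
      wins <- sliding_windows(filtered, window_s, overlap)
      if (!is.null(event)) {
        # keep only windows that contain a meaningful part of the fall:
        # pre-impact stance windows would carry a misleading label
        keep <- wins$end > event + as.integer(round(0.25 * cfg$fs))
        wins <- wins[keep, , drop = FALSE]
      }
      m <- sig_matrix(filtered)
      for (w in seq_len(nrow(wins))) {
        sl <- seq.int(wins$start[w] + 1L, wins$end[w])
        fv <- gait_feature_vector(m[sl, c("ax", "ay", "az"), drop = FALSE],
                                  m[sl, c("forefoot", "heel"), drop = FALSE],
                                  wav_cfg, mode)
        rows[[length(rows) + 1L]] <-
          tibble::as_tibble(c(list(label = gm, trial = idx), as.list(fv)))
      }
    }
  }
  dplyr::bind_rows(rows)
}
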