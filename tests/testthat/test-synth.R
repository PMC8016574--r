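test_that("sEMG trials are deterministic and carry valid ground truth", {
  cfg <- emg_synth_config()
  t1 <- gen_emg_trial("left_turn", cfg, trial_seed = 5L)
  t2 <- gen_emg_trial("left_turn", cfg, trial_seed = 5L)
  expect_identical(sig_matrix(t1$record), sig_matrix(t2$record))
  expect_identical(t1$truth, t2$truth)
  n <- nrow(t1$record)
  expect_gte(t1$truth$start, 0L)
  expect_lte(t1$truth$end, n)
  expect_equal(sig_label(t1$record), "left_turn")
  expect_equal(sig_channels(t1$record), c("biceps", "extensor"))
  expect_error(gen_emg_trial("wave", cfg), "unknown gesture")
  expect_error(emg_synth_config(burst_duration = 5, trial_duration = 3),
               "shorter")
})

test_that("stop bursts are far weaker than left-turn bursts on the biceps channel", {
  cfg <- emg_synth_config()
  seg_sd <- function(gesture, seed) {
    tr <- gen_emg_trial(gesture, cfg, seed)
    idx <- (tr$truth$start + 1L):tr$truth$end
    standard_deviation(sig_matrix(tr$record)[idx, "biceps"])
  }
  sds_stop <- vapply(1:50, function(s) seg_sd("stop", s), numeric(1))
  sds_left <- vapply(51:100, function(s) seg_sd("left_turn", s), numeric(1))
  expect_lt(mean(sds_stop), 0.3 * mean(sds_left))
  # ordering of the three gestures' biceps amplitude: left > right > stop
  sds_right <- vapply(101:130, function(s) seg_sd("right_turn", s), numeric(1))
  expect_gt(mean(sds_left), mean(sds_right))
  expect_gt(mean(sds_right), mean(sds_stop))
})

test_that("gait trials are deterministic with mode-dependent dynamics", {
  cfg <- gait_synth_config()
  r1 <- gen_gait_trial("walking", cfg, 3L)
  r2 <- gen_gait_trial("walking", cfg, 3L)
  expect_identical(sig_matrix(r1), sig_matrix(r2))
  expect_equal(sig_channels(r1), c("ax", "ay", "az", "forefoot", "heel"))

  # waiting is essentially static relative to walking
  wait_var <- sapply(1:20, function(s) {
    m <- sig_matrix(gen_gait_trial("waiting", cfg, s))
    mean(apply(m[, 1:3], 2, var))
  })
  walk_var <- sapply(21:40, function(s) {
    m <- sig_matrix(gen_gait_trial("walking", cfg, s))
    mean(apply(m[, 1:3], 2, var))
  })
  expect_lt(mean(wait_var), 0.01 * mean(walk_var))
  expect_error(gen_gait_trial("sprinting", cfg), "unknown gait mode")
})

test_that("stair direction sets the sign of the forefoot-heel difference", {
  cfg <- gait_synth_config()
  diff_mean <- function(mode, s) {
    m <- sig_matrix(gen_gait_trial(mode, cfg, s))
    pressure_diff_mean(m[, "forefoot"], m[, "heel"])
  }
  up <- vapply(1:20, function(s) diff_mean("upstairs", s), numeric(1))
  down <- vapply(21:40, function(s) diff_mean("downstairs", s), numeric(1))
  expect_true(all(up > 0))
  expect_true(all(down < 0))
})

test_that("falling trials rotate gravity and unload the foot after the impact", {
  cfg <- gait_synth_config()
  rec <- gen_gait_trial("falling", cfg, 9L)
  ev <- attr(rec, "event_sample")
  expect_true(!is.null(ev) && ev > 0)
  m <- sig_matrix(rec)
  n <- nrow(m)
  post <- seq.int(min(n, ev + 200L), n)
  pre <- seq_len(max(1L, ev - 100L))
  expect_gt(mean(m[post, "ax"]), 0.8)     # horizontal after the fall
  expect_lt(mean(m[post, "az"]), 0.2)
  expect_gt(mean(m[pre, "az"]), 0.8)      # upright before
  expect_lt(mean(m[post, "forefoot"] + m[post, "heel"]),
            0.5 * mean(m[pre, "forefoot"] + m[pre, "heel"]))
})

test_that("the sEMG feature dataset is class-balanced with stable shape", {
  cfg <- emg_synth_config(n_trials_per_gesture = 8L, seed = 2L)
  ds <- gen_emg_dataset(cfg)
  counts <- table(ds$label)
  expect_equal(sort(names(counts)), sort(cfg$gestures))
  # balance within 5% of the nominal per-class trial count
  expect_true(all(abs(counts - 8) <= ceiling(0.05 * 8) + 1))
  expect_equal(setdiff(names(ds), c("label", "trial")),
               names(emg_feature_vector(gen_emg_trial("stop", cfg, 1L)$record,
                                        tibble::tibble(start = 0L, end = 512L))))
  expect_identical(ds, gen_emg_dataset(cfg))
})

test_that("the gait feature dataset has the documented widths per setting", {
  cfg <- gait_synth_config(n_trials_per_mode = 2L, trial_duration = 6, seed = 3L)
  fus <- gen_gait_dataset(cfg, mode = "fusion")
  expect_equal(ncol(fus) - 2L, 34L)
  acc <- gen_gait_dataset(cfg, mode = "acc_only")
  expect_equal(ncol(acc) - 2L, 33L)
  prs <- gen_gait_dataset(cfg, mode = "pressure_only")
  expect_equal(ncol(prs) - 2L, 1L)
  expect_setequal(unique(fus$label), cfg$modes)
  expect_identical(fus, gen_gait_dataset(cfg, mode = "fusion"))
})

test_that("collapsing the amplitude contrast degrades class separability", {
  accs <- vapply(c(1, 0.04, 0), function(contrast) {
    cfg <- emg_synth_config(amplitude_contrast = contrast,
                            n_trials_per_gesture = 10L, seed = 6L)
    ds <- gen_emg_dataset(cfg)
    ds <- ds[, setdiff(names(ds), "trial")]
    cv_fitness(ds, svm_params(10, 0.1), folds = 5, seed = 8)
  }, numeric(1))
  expect_true(accs[1] > accs[2] & accs[2] > accs[3])
  expect_gt(accs[1], 0.9)
  expect_lt(accs[3], 0.6)
})
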