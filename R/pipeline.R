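#' End-to-end gesture-recognition experiment
#'
#' Runs the full sEMG pipeline on synthetic data: generate gesture trials,
#' band-pass filter, detect active segments by moving-average energy
#' thresholding, extract the standard-deviation + wavelet-subband
#' singular-value features, tune `(C, gamma)` with the genetic algorithm
#' on the training trials, and evaluate the tuned SVM on held-out trials.
#' The train/test split is stratified at the trial level, so every segment
#' of a trial stays on one side — no window-level leakage.
#'
#' @param emg_cfg An [emg_synth_config()].
#' @param seg_cfg A [segmenter_config()].
#' @param wav_cfg A [wavelet_config()].
#' @param ga_cfg A [ga_config()].
#' @param train_fraction Fraction of trials per class used for training
#'   (default 0.7).
#' @return A `posture_eval` report; element `ga` holds the
#'   [glance()][generics::glance] row of the GA run and `best_params` the
#'   tuned [svm_params()].
#' @export
run_emg_experiment <- function(emg_cfg = emg_synth_config(),
                               seg_cfg = segmenter_config(),
                               wav_cfg = wavelet_config(),
                               ga_cfg = ga_config(),
                               train_fraction = 0.7) {
  ds <- gen_emg_dataset(emg_cfg, seg_cfg, wav_cfg)
  missing_cls <- setdiff(emg_cfg$gestures, unique(ds$label))
  if (length(missing_cls)) {
    stop("no active segments detected for class: ",
         paste(missing_cls, collapse = ", "), call. = FALSE)
  }
  run_classification(ds, ga_cfg, train_fraction,
                     config = list(synth = unclass(emg_cfg),
                                   seg = unclass(seg_cfg),
                                   wavelet = unclass(wav_cfg),
                                   ga = unclass(ga_cfg),
                                   train_fraction = train_fraction),
                     seed = emg_cfg$seed)
}

#' End-to-end gait-recognition experiment with sensor-fusion comparison
#'
#' Generates one set of synthetic five-mode gait trials and classifies it
#' under each requested feature setting — `fusion` (acceleration +
#' pressure), `acc_only`, `pressure_only` — with an independently tuned
#' GA-SVM per setting. All settings see identical generated data and an
#' identical trial-level train/test split, so accuracy differences
#' reflect the feature sets alone.
#'
#' @param gait_cfg A [gait_synth_config()].
#' @param wav_cfg A [wavelet_config()].
#' @param ga_cfg A [ga_config()].
#' @param settings Character vector of feature settings to compare.
#' @param train_fraction Fraction of trials per class used for training.
#' @return A named list of `posture_eval` reports, one per setting.
#' @export
run_gait_experiment <- function(gait_cfg = gait_synth_config(),
                                wav_cfg = wavelet_config(),
                                ga_cfg = ga_config(),
                                settings = c("fusion", "acc_only",
                                             "pressure_only"),
                                train_fraction = 0.7) {
  settings <- match.arg(settings, several.ok = TRUE)
  fusion <- gen_gait_dataset(gait_cfg, wav_cfg, mode = "fusion")
  feat_names <- setdiff(names(fusion), c("label", "trial"))
  acc_names <- setdiff(feat_names, "pressure.diff.mean")

  out <- lapply(settings, function(s) {
    ds <- switch(s,
                 fusion = fusion,
                 acc_only = fusion[, c("label", "trial", acc_names)],
                 pressure_only = fusion[, c("label", "trial",
                                            "pressure.diff.mean")])
    run_classification(ds, ga_cfg, train_fraction,
                       config = list(synth = unclass(gait_cfg),
                                     wavelet = unclass(wav_cfg),
                                     ga = unclass(ga_cfg),
                                     setting = s,
                                     train_fraction = train_fraction),
                       seed = gait_cfg$seed)
  })
  names(out) <- settings
  out
}

# shared back end: trial-level stratified split -> GA tune -> final fit ->
# held-out evaluation
run_classification <- function(ds, ga_cfg, train_fraction, config, seed) {
  split <- split_trials(ds, train_fraction, seed)
  train <- ds[ds$trial %in% split$train, , drop = FALSE]
  test <- ds[ds$trial %in% split$test, , drop = FALSE]
  train_ds <- train[, setdiff(names(train), "trial"), drop = FALSE]
  test_ds <- test[, setdiff(names(test), "trial"), drop = FALSE]

  ga <- ga_optimize(train_ds, ga_cfg)
  model <- train_svm(train_ds, ga$best_params)
  pred <- predict(model, test_ds)

  report <- evaluation_report(test_ds$label, pred, config = config, seed = seed)
  report$ga <- glance(ga)
  report$best_params <- ga$best_params
  report
}

# stratified trial-level split: every trial id goes wholly to one side
split_trials <- function(ds, train_fraction, seed) {
  if (!"trial" %in% names(ds)) stop("dataset has no `trial` column", call. = FALSE)
  trial_label <- dplyr::distinct(ds[, c("trial", "label")])
  train_ids <- integer(0)
  withr::with_seed(as.integer(seed) + 20011L, {
    for (cl in sort(unique(trial_label$label))) {
      ids <- trial_label$trial[trial_label$label == cl]
      ids <- ids[sample.int(length(ids))]
      n_train <- max(1L, min(length(ids) - 1L,
                             as.integer(round(train_fraction * length(ids)))))
      train_ids <- c(train_ids, ids[seq_len(n_train)])
    }
  })
  list(train = train_ids, test = setdiff(trial_label$trial, train_ids))
}
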