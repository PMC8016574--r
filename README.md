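# posturekit

Wearable-sensor posture and gait recognition in R.

posturekit is for researchers and engineers building human-activity
recognition from body-worn sensors: it recognises **steering gestures**
(left turn, stop, right turn) from two-channel upper-limb surface EMG
(sEMG), and **gait modes** (walking, waiting, going upstairs, going
downstairs, falling) from an ankle accelerometer fused with forefoot and
heel plantar-pressure sensors. Because no public recordings accompany
this problem, the package ships first-class synthetic generators with
known ground truth, so every stage is testable end to end.

The pipeline has three stages:

1. **Active-segment detection.** The band-passed sEMG is squared to its
   instantaneous energy E(i) = x(i)², smoothed with a forward moving
   window of N samples, E_MA(i) = (1/N) Σ_{j=i..i+N−1} E(j), and compared
   with a threshold T = 2% of max E_MA. A motion onset is declared where
   E_MA stays ≥ T for a full window, an offset where it stays < T —
   amplitude-scale-invariant burst detection.
2. **Feature extraction.** sEMG segments: per-channel population standard
   deviation plus the largest singular value of the Hankel trajectory
   matrix of each DWT subband (a3, d3, d2, d1 at level 3). Gait windows:
   per-axis mean/SD/variance, the 8-band db1 wavelet-packet energy
   spectrum per axis, and the mean forefoot−heel pressure difference
   F̄ = (1/N) Σ (F_i − f_i) — 34 features fused.
3. **GA-optimized RBF-SVM.** A one-vs-one soft-margin SVM with kernel
   K(x_i, x) = exp(−γ‖x_i − x‖²), with (C, γ) tuned by a real-coded
   genetic algorithm (population 50, 50 generations, crossover 0.8,
   mutation 0.1, generation gap 0.95 with 5% elitism) scored by
   stratified 5-fold cross-validated accuracy.

## Worked example

```r
library(posturekit)

# one synthetic left-turn trial: burst-modulated band-limited noise
trial <- gen_emg_trial("left_turn", emg_synth_config(), trial_seed = 42)
filtered <- bandpass_filter(trial$record, 20, 450)
segment_record(filtered, channel = "biceps")
#> # A tibble: 1 × 3
#>   start   end channel
#>   <int> <int> <chr>
#> 1   586  1609 biceps
trial$truth[, 1:2]
#> # A tibble: 1 × 2
#>   start   end
#>   <int> <int>
#> 1   661  1661
```

The detected burst brackets the true one to within a moving-average
window (128 samples). The full gesture experiment — generate, segment,
extract features, tune (C, γ) with the GA on 70% of trials, evaluate on
the held-out 30% — is one call:

```r
report <- run_emg_experiment(emg_synth_config(seed = 7),
                             ga_cfg = ga_config(pop_size = 20, max_gen = 15,
                                                seed = 7))
report
#> <posture_eval> overall accuracy 1.0000 on 27 observations
#>  left_turn right_turn       stop
#>          1          1          1
```

At the default synthetic class contrast the three gestures are fully
separated on held-out trials (the regime of interest is ≥ 90%). The gait
experiment compares sensor settings on identical data and splits:

```r
reports <- run_gait_experiment(gait_synth_config(seed = 7),
                               ga_cfg = ga_config(pop_size = 20, max_gen = 15,
                                                  seed = 7))
sapply(reports, function(r) r$overall)
#>        fusion      acc_only pressure_only
#>     1.0000000     0.7976190     0.6428571
```

Fusing acceleration with plantar pressure beats either signal alone:
the two stair modes share acceleration dynamics and are resolved only by
the sign of the forefoot−heel difference, while the single pressure
feature cannot distinguish the level-ground modes. `tidy()`, `glance()`
and `autoplot()` methods give per-class tables, one-row summaries and
confusion-matrix / GA-convergence / signal plots.

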