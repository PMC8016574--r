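---
title: "Methods: wearable posture and gait recognition in posturekit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: wearable posture and gait recognition in posturekit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(posturekit)
```

posturekit implements a complete wearable posture-detection workflow for
two sensing problems: recognising steering gestures (left turn, stop,
right turn) from two-channel upper-limb surface EMG, and recognising five
gait modes (walking, waiting, going upstairs, going downstairs, falling)
from an ankle accelerometer fused with two plantar pressure sensors. This
vignette describes the models, the tunable parameters, the synthetic data
the package tests itself on, and the numerical choices behind the
implementation.

## Active-segment detection for sEMG

A gesture appears in surface EMG as a burst of broadband activity over a
quiet baseline. The detector works on the band-passed signal $x(i)$:

1. **Instantaneous energy** $E(i) = x(i)^2$.
2. **Moving average** over a forward window of $N$ samples:
   $E_{MA}(i) = \frac{1}{N}\sum_{j=i}^{i+N-1} E(j)$.
3. **Threshold comparison**: the threshold $T$ is 2% of
   $\max_i E_{MA}(i)$. An onset is declared at the first index where
   $E_{MA} \ge T$ holds for $N$ consecutive samples; an offset where
   $E_{MA} < T$ holds for $N$ consecutive samples.

Because $T$ is relative to the per-record maximum, detection is invariant
to amplitude scaling (electrode gain, skin impedance). The window length
defaults to $N = 128$ samples (128 ms at 1 kHz); the sustain condition
uses the same $N$, which suppresses isolated threshold crossings. Two
post-rules handle noisy boundaries: detections shorter than
`min_segment_len` (default $N$) are discarded, and detections separated
by less than `merge_gap` (default $N/2$) are merged. A burst still active
at the record end is closed at the final sample and flagged with a
classed warning. All indices are 0-based, half-open, in raw-signal
coordinates with the forward window anchored at its left edge.

The value taken as the sequence maximum is computed per record; nothing
in the method requires cross-trial state.

## Feature extraction

**sEMG branch.** Per channel of a detected segment: the population
standard deviation (divisor $N$, not $N-1$ — the estimator is used as a
signal-power descriptor, not an unbiased variance estimate), plus one
singular value per subband of a discrete wavelet transform. The DWT
decomposes the segment into `level + 1` subbands (default level 3:
$a_3, d_3, d_2, d_1$). Each 1-D subband is embedded as a Hankel
trajectory matrix $A$ with `svd_embed_rows` rows (default 10; row $i$ is
the subband delayed by $i-1$ samples) and the feature is its largest
singular value $\sigma_1(A) = \sqrt{\lambda_{\max}(AA^T)}$. The
trajectory embedding is the standard way to attach an SVD to a 1-D
sequence; keeping only the dominant singular value gives exactly one
feature per subband, is stable under noise, and scales linearly with
burst amplitude, which is the physically discriminative quantity here.
The sEMG wavelet basis defaults to `db4`, a common sEMG choice; the
transform is periodized and orthonormal, so Parseval holds exactly.

**Gait branch.** Fixed-length sliding windows (default 2 s with 50%
overlap) over the low-pass-filtered trial. Per window: per-axis mean,
population SD and variance of the three acceleration channels (9
features); the wavelet-packet energy spectrum of each axis — a full
packet decomposition with basis `db1` to level 3, yielding the energies
of all $2^3 = 8$ terminal subspaces in natural tree order (24 features);
and the mean forefoot–heel pressure difference
$\bar F = \frac{1}{N}\sum_i (F_i - f_i)$ (1 feature), positive when
forefoot loading dominates. The fusion vector is the concatenation
(34 features); the acceleration-only and pressure-only settings drop or
keep the pressure feature respectively.

**Scaling.** Features are z-score standardized before the SVM, with the
scaler fitted on training data only (refitted inside every
cross-validation fold) and stored in the model. RBF kernels are not
scale-invariant, so this is required for heterogeneous feature banks.

## Filtering

Butterworth filters applied forward–backward (zero phase, so detected
boundaries are not shifted; the magnitude response is squared). Defaults:
sEMG band-pass 20–450 Hz, order 4; acceleration and pressure low-pass
20 Hz, order 4. The pass bands are the conventional wearable-sensor
choices and are exposed as arguments. Edge transients are suppressed by
odd-reflection padding sized to let the slowest pole (near the lowest
corner frequency) settle; records shorter than the filter warm-up are
rejected. No notch filter is applied by default: the synthetic data
carry no power-line interference.

## GA-optimized RBF-SVM

Classification uses a soft-margin SVM with RBF kernel
$K(x_i, x) = \exp(-\gamma\|x_i - x\|^2)$, one-vs-one for more than two
classes with majority voting (ties broken by the largest aggregate
decision margin, then lexicographic label order). The inner quadratic
program is solved by libsvm via e1071; the package stores the support
vectors, signed dual coefficients and biases, evaluates the decision
function $f(x) = \mathrm{sgn}\left(\sum_i \hat\alpha_i y_i K(x_i, x) +
\hat b\right)$ itself from those quantities, and verifies the dual box
($0 \le \alpha_i \le C$) and equality ($\sum_i \alpha_i y_i = 0$)
constraints on every fit. The test suite additionally checks the
decision function against an independently solved dual (interior-point
QP) on small instances, so the inner solver is replaceable.

The penalty factor $C$ and kernel width $\gamma$ are tuned by a
real-coded genetic algorithm over $(\log_2 C, \log_2\gamma)$ with search
ranges $\log_2 C \in [-5, 15]$, $\log_2\gamma \in [-15, 3]$ (the
community-standard grid bounds). Defaults: population 50, 50 generations,
crossover probability 0.8, per-gene Gaussian mutation probability 0.1,
generation gap 0.95 — interpreted as 95% of the population replaced each
generation, with the complementary top 5% carried over unchanged
(elitism), which makes the best-fitness history non-decreasing by
construction. Selection is by tournament of 3; crossover is blend (BLX-α
with α = 0.5, clipped to the range); mutation adds Gaussian noise with SD
equal to 10% of the range width. Fitness is stratified 5-fold
cross-validated accuracy; the fold assignment is drawn once per run from
the GA seed, so each chromosome is scored on identical folds and the run
is bit-reproducible from its configuration. Generations are counted
after initialization; "50 generations" means 50 breeding cycles beyond
the initial population.

## Synthetic data: what it emulates and what it does not

No public recordings accompany this problem, so the package generates
its own study conditions with known ground truth.

**sEMG gestures.** Each trial (3 s at 1 kHz, two channels named `biceps`
and `extensor`) is baseline Gaussian sensor noise (SD 0.005) plus one
1-s burst: 20–450 Hz filtered Gaussian noise under a raised-cosine
envelope at a uniformly random onset, scaled by a per-gesture,
per-channel amplitude. The default amplitude matrix — left turn
(1.00, 0.85), stop (0.05, 0.05), right turn (0.28, 0.42) — preserves the
qualitative ordering seen in steering-gesture EMG on this montage (the
biceps separates left turn ≫ right turn ≫ stop) without targeting any
subject-specific values; the stop burst still carries 100× the baseline
energy, so segmentation works on every class. Amplitude-modulated
filtered noise is the standard interference-pattern surrogate for sEMG;
it reproduces the energy and variance structure the pipeline consumes
but not motor-unit firing statistics, signal nonstationarity within a
contraction, electrode artifacts, or inter-subject variability — so
passing tests demonstrate the pipeline's correctness and its behaviour
under the modelled class structure, not performance on real recordings.

An `amplitude_contrast` dial in $[0, 1]$ geometrically interpolates the
per-gesture amplitudes toward their per-channel geometric mean: at 0 the
classes are identically distributed and downstream accuracy must fall to
chance, which the tests use as a negative control.

**Gait modes.** Trials are 10 s at 100 Hz with channels
`ax, ay, az, forefoot, heel`. Locomotion modes are
sinusoid-plus-harmonic accelerations at a mode-specific step frequency
(walking 1.9 Hz; both stair modes 1.4 Hz) with ±5% frequency and ±10%
amplitude jitter per trial, gravity on the vertical axis, and anti-phase
forefoot/heel loading at the step frequency. Stair ascent shifts load
forefoot-ward (mean difference ≈ +0.4) and descent heel-ward (≈ −0.4);
the two stair modes share acceleration dynamics *by construction*, so
they are separable only through pressure — this is what makes fusion
strictly better than acceleration alone. Waiting is static stance
(gravity, sensor noise, constant mid-foot load). Falling is a single
impact transient at a random time, after which the gravity vector
rotates to the anteroposterior axis and plantar load decays to a small
random residual contact load. All loaded phases carry a slow
load-redistribution drift (postural sway), which keeps the pressure
distributions of walking, waiting and post-fall lying overlapping — the
single pressure feature then resolves the stair modes but not the rest,
reproducing the expected fusion > acceleration-only > pressure-only
ordering. The generator is not a biomechanical gait model: no
double-support timing, no stride-length variability, no terrain effects.

Falling trials are labelled at the trial level; sliding windows that end
before (or barely overlap) the impact are dropped, since they show
quiet stance and would carry a misleading label.

## Experiment pipelines

`run_emg_experiment()` and `run_gait_experiment()` chain generation,
filtering, segmentation/windowing, feature extraction, GA tuning on the
training portion, a final fit at the tuned $(C, \gamma)$, and held-out
evaluation. Splits are stratified at the **trial** level (default 70/30),
so all windows or segments of a trial stay on one side; window-level
splitting would leak within-trial correlation and inflate accuracy. The
gait experiment evaluates all three sensor settings on identical
generated data and an identical split, so accuracy differences reflect
the feature sets alone. Reports carry the confusion matrix, per-class
and overall accuracy, the configuration snapshot and the seed, and are
bit-reproducible from configuration + seed.

Problem sizes used in the shipped tests and the acceptance script: 30
trials per gesture and 12 trials per gait mode, with the GA at
population 20 for 15 generations — enough for the accuracy regimes to be
stable across seeds while keeping a full end-to-end run in the
low minutes on a single core. The GA defaults (50/50) remain the
recommended setting for real analyses.

## Numerical choices and degenerate inputs

- Periodized orthonormal DWT/packet transforms with zero-padding to a
  multiple of $2^{level}$; energy is conserved exactly, so Parseval
  holds to floating-point precision on any length.
- Threshold ties count as supra-threshold ($\ge T$), which makes the
  all-zero record deterministic: threshold 0, warning, no segments.
- An identically-zero averaged-energy sequence yields threshold 0 with a
  warning rather than an error.
- Constant features get unit scale in the standardizer (instead of a
  0/0), leaving them inert in the kernel.
- GA chromosomes are clipped to the search box after crossover and
  mutation; fitness ties resolve to the earlier index (stable order).
- All randomness flows from explicit integer seeds through one
  generator; sub-seeds are drawn once per run, and repeated runs are
  bitwise identical.

## Known limitations

- The synthetic generators define the difficulty of the task; accuracy
  numbers quoted by the package are statements about those conditions,
  not about human recordings.
- Only Daubechies bases db1/db2/db4 are built in.
- The per-subband SVD keeps a single singular value; richer spectra
  (several leading values) may help on real data but would change the
  feature count downstream.
- The one-feature pressure-only setting is intentionally weak; it exists
  for the fusion comparison, not as a usable classifier.
- No real-time/streaming mode: the segmenter is single-pass-capable but
  the package evaluates offline.
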