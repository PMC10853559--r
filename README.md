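# fingertap

Quantification and ordinal severity scoring of the MDS-UPDRS finger-tapping
task from 21-landmark hand-keypoint video time series.

Clinicians grade bradykinesia — the cardinal Parkinson's sign — by watching
a patient tap index finger on thumb and assigning an ordinal item score
(0 normal ... 3+ severe), judging speed, amplitude, hesitations and
decrement. Hand-pose extractors turn a consumer video of that task into a
per-frame stream of 21 three-dimensional hand landmarks. `fingertap` is the
analysis layer on top of that stream, for movement-disorder researchers and
engineers building video-based motor assessment:

* **Quality control** — error-frame ratio `EFR = n_error / n_frames`,
  confidence tiers (high < 0.16 <= moderate < 0.5 <= low), dataset
  filtering at a cutoff TEFR, and repair of missing frames by tracking back
  to the nearest valid frame.
* **Hand parameters** — all geometry in units of the subject's thumb
  length. The thumb–index distance signal d(t) (5-frame moving average)
  yields: tap **peaks** (topographic prominence >= 0.1 thumb-lengths),
  **frequency** f and **intensity** I per step from a short-time Fourier
  transform (2 s Hann window, 0.1 s hop, 0.5–8 Hz band), the **FI value**
  f·I (A.U./s) and the absolute frequency difference |Δf| as a
  hesitation cue.
* **Augmentation** — 3D keypoint rotation (an exact isometry of the
  landmark set) and Gaussian-centered random cropping, applicable at the
  training / model-picking / inference stages.
* **Ordinal scorer** — binary decomposition: three dilated temporal CNNs
  answer "score >= 1 / >= 2 / >= 3+?", trained with SGD (momentum 0.9,
  cross-entropy) under subject-stratified cross-validation with MCC model
  selection; the item score is the count of positive boundary decisions.
  The networks (forward and backprop) are implemented in base R on BLAS.
* **Agreement metrics** — accuracy, sensitivity, specificity, precision,
  F1, MCC; number of significant errors (|y − ŷ| >= 2), acceptable
  accuracy AAC = P(|y − ŷ| <= 1) and Cohen's kappa over {0, 1, 2, 3+}.
* **Synthetic tapping generator** — severity-graded cohorts with
  d(t) = A(t)(1 − cos φ(t)), clinical effect signatures (hesitation,
  decrement, slowing, freezing), camera pose, jitter and frame dropout;
  the test bed standing in for non-public clinical video.
* **Reports** — per-clip JSON/CSV reports, left/right radar comparison on
  an 80–20 scale anchored at cohort reference medians, longitudinal
  tracking, base-graphics plots, and a thin CLI (`inst/cli/fingertap`).

## Worked example

```r
library(fingertap)

# a moderate-severity synthetic recording: 10 s at 60 fps, 2.2 Hz taps,
# amplitude 0.22 thumb-lengths, mild decrement, occasional hesitations
cfg <- tap_sim_config(base_frequency = 2.2, base_amplitude = 0.22,
                      decrement_rate = 0.04, missing_rate = 0.1,
                      hesitation = list(rate = 0.4, depth = 0.5, duration_s = 0.4),
                      seed = 7)
sim <- simulate_clip(cfg)
report <- analyze_clip(sim$clip)
report
#> <clip_report> right hand
#>   quality: EFR 0.100 -> confidence high
#>   medians: frequency 2.00 Hz, intensity 0.138 A.U., FI 0.276 A.U./s, peak 0.329
#>   max |frequency difference|: 0.50 Hz
```

Reading: 10% of frames were dropped, still high confidence (EFR < 0.16).
The recovered median frequency (2.0 Hz, within one 0.5 Hz STFT bin of the
programmed 2.2 Hz) and median peak (0.329 thumb-lengths — the programmed
2A = 0.44 eroded by the decrement and hesitation effects) land in the
score-2 neighbourhood of the bundled cohort reference medians; the nonzero
frequency-difference maximum reflects the injected hesitations.

Training and scoring end to end on a synthetic cohort:

```r
cohort <- simulate_cohort(severity_presets("left"), n_per_class = 50, seed = 1)
sp     <- split_by_subject(cohort, ratio = 0.85, seed = 1)
pol    <- augment_policy(c("training", "inference"), seed = 1, n_rotations = 4)
scorer <- tap_scorer(sp$non_testing,
                     tcfg = train_config(epochs = 40, seed = 1, augment = pol))
ev <- evaluate_scorer(scorer, sp$testing)
ev$report$aac
#> [1] 1
ev$report$kappa
#> [1] 0.6417910
```

Every held-out clip is scored within one grade of its label (AAC 1.0) and
chance-corrected exact agreement is substantial (kappa 0.64).

(Training the three boundary classifiers takes a few minutes on one core.)

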