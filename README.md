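# footstrike

Automated foot-strike detection for lower-limb amputee gait from a single
smartphone IMU worn at the posterior pelvis.

## The problem

A foot strike (FS) — the instant a foot touches the ground — delimits the
gait cycle. Step time, stride time, cadence and every per-stride clinical
measure derived from a six-minute walk test (6MWT) depend on locating each
FS. With only a pelvis-mounted smartphone (accelerometer, gyroscope,
orientation at a nominal 50 Hz) this is hard for lower-limb amputees, whose
gait is asymmetric and variable and whose walking aids distort the
acceleration traces. Manual labelling works but is impractical in clinic.

`footstrike` implements an automated pipeline:

1. **Preprocessing** — resample variably-sampled channels to a uniform
   50 Hz grid; 4th-order zero-lag Butterworth low-pass at 4 Hz (forward–
   backward pass: phase cancels, so peak timing is preserved).
2. **Labelling** — per-frame binary labels (1 = FS); an automatic peak-pair
   rule (AP acceleration peak immediately followed by a vertical peak)
   stands in for manual annotation on synthetic data.
3. **Detection** — a per-frame decision tree on the 12 signal channels, and
   an LSTM on 31-frame windows (LSTM → dropout → dense ReLU → sigmoid,
   class-weighted binary cross-entropy; implemented natively in R with
   batched BLAS operations and exactly reproducible under a seed).
4. **Correction** — collapse "banded" runs of consecutive positive
   predictions onto the AP peak; insert missed steps into intervals longer
   than 1.5× their predecessor, guarded by a per-trial locking period
   derived from zero crossings of early vertical acceleration.
5. **Evaluation** — one-to-one event matching within ±2 frames (±0.04 s);
   sensitivity/specificity/accuracy/precision; stride parameters compared
   against minimal detectable change (MDC); grouped 5-fold
   cross-validation pooled at the cohort level.

Because no public amputee 6MWT smartphone dataset exists, the package
includes a synthetic gait simulator (`generate_trial()`) producing
12-channel recordings with known FS events, amputee-like asymmetry and
variability, gait-aid double peaks, weak peaks, and steps the sensor barely
registers. All tests and the shipped experiment run against it.

## Worked example

```r
library(footstrike)

# one synthetic participant: 30 s of asymmetric gait at 50 Hz
trial <- generate_trial(gait_sim_config(duration = 30, seed = 7))
prep  <- prepare_trial(trial)        # resample + filter + labels

# rule-based detection (no training needed)
events <- auto_label_peak_rule(ap_channel(prep$recording),
                               vertical_channel(prep$recording))
cm <- match_events(events, prep$truth, length(prep$labels), tolerance = 2)
compute_metrics(cm)
#> sensitivity  98.3%
#> specificity  99.9%
#> accuracy     99.9%
#> precision    98.3%

# stride parameters vs ground truth, flagged against MDC
compare_to_mdc(stride_parameters(events), stride_parameters(prep$truth))
#>     parameter    difference   mdc within_mdc
#> 1   step_time  1.110223e-16 0.042       TRUE
#> 2 stride_time -3.571429e-04 0.772       TRUE
#> 3     cadence  2.249586e-01 8.440       TRUE
```

Sensitivity 98.3% means the peak-pair rule found 57 of the 58 true foot
strikes within ±2 frames (the miss is a simulated "dropped" step that
leaves no pelvis signal, so no rule can see it); precision 98.3% means 1 of
its 58 detections matched no true strike. The stride-parameter differences
are all inside the MDC, i.e. clinically equivalent to ground truth.

The full learned pipeline — simulate a 20-participant cohort, 5-fold
grouped cross-validation of the LSTM, correction, pooled evaluation:

```r
report <- run_pipeline(default_run_config(seed = 1), verbose = TRUE)
print(report)
#> <fs_report> lstm model on 20 trials (seed 1)
#> after correction:
#> sensitivity  94.9%
#> specificity  99.6%
#> accuracy     99.4%
#> precision    90.7%
#> before correction:
#> sensitivity  94.1%
#> specificity  98.5%
#> accuracy     98.4%
#> precision    72.2%
```

This takes a few minutes on one CPU (the LSTM trains natively in R).

The correction stage's precision gain (band collapse removes the duplicate
predictions flanking each true strike; gap insertion recovers missed steps)
is the expected signature of the method.

A thin command-line wrapper lives at `inst/cli/footstrike.R`
(`simulate`, `label`, `correct`, `evaluate`, `run-all` subcommands).

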