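---
title: "Detecting foot strikes from a pelvis-worn smartphone IMU"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting foot strikes from a pelvis-worn smartphone IMU}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

A foot strike (FS) — the instant a foot contacts the ground — delimits the
gait cycle; locating every FS in a walking trial is the prerequisite for step
time, stride time, cadence, and any downstream per-stride analysis such as
fall-risk scoring. In clinic-friendly setups the only sensor is a smartphone
strapped to the posterior pelvis during a six-minute walk test (6MWT),
sampling accelerometer, gyroscope and orientation channels at a nominal
50 Hz. For lower-limb amputees the problem is harder than for able-bodied
walkers: gait is asymmetric and variable, walking aids inject double peaks
into the acceleration traces, and some steps barely register at the pelvis.

`footstrike` implements the full detection pipeline: preprocessing,
rule-based labelling, per-frame decision-tree and windowed LSTM classifiers,
two post-processing corrections, tolerance-matched evaluation, and stride
parameters compared against minimal detectable change (MDC). Because no
suitable public dataset of amputee 6MWT smartphone recordings exists, the
package ships a synthetic gait simulator that reproduces the signal
phenomenology the pipeline keys on; every stage is trainable and testable
against simulated ground truth.

## The signal model behind the simulator

At the pelvis, a typical gait cycle shows an anterior–posterior (AP)
acceleration peak at the foot strike, followed shortly by a vertical
acceleration peak. The simulator (`generate_trial()`) builds each trial from
that signature:

* **Events.** Left and right step times alternate with ratio
  `asymmetry_ratio` (default 1.1) around `mean_step_time` (default 0.5 s,
  within the 0.4–0.6 s band of normal walking), each multiplied by a
  unit-mean lognormal factor with coefficient of variation `step_time_cv`
  (default 0.08). The first FS follows a 1-s standing lead-in.
* **Channels.** Each non-dropped step adds a Gaussian AP bump (sd
  `peak_width` = 0.05 s) at the event and a vertical bump `ap_vertical_lag`
  = 0.08 s later, superposed on step-frequency sinusoids; medio-lateral
  acceleration oscillates at stride frequency (sign alternates per step);
  angular velocities oscillate at step frequency; orientation drifts slowly
  (the pipeline treats orientation as a nuisance channel). Raw acceleration
  is linear acceleration plus gravity. White noise (`noise_sd` = 0.15 m/s²)
  is added to all acceleration channels, and timestamps are jittered
  (sd 2 ms) to emulate the variable smartphone sampling rate.
* **Artifacts.** With small per-step probabilities a step's AP peak is split
  in two (`p_double_peak` = 0.05, the walking-aid signature, second sub-peak
  slightly higher), scaled by 0.3 (`p_weak_peak` = 0.05), or omitted
  entirely while the event *stays in the ground truth*
  (`p_dropped_step` = 0.03). Dropped steps create honest false negatives
  for the missed-step corrector to repair.

These defaults are the package's standing study conditions; they were chosen
to represent mildly impaired, aided gait and are not tuned per experiment.

What the simulator does **not** emulate: musculoskeletal dynamics, ground
reaction forces, sensor-frame rotation, magnetometer drift, rests mid-trial,
or turning at hallway ends. Passing tests on synthetic data therefore show
that the pipeline's logic is correct under the stated signal model, not that
the reported clinical accuracy transfers to any particular patient cohort.

## Preprocessing

Smartphone streams are variably sampled, so every channel is linearly
interpolated onto a uniform 50 Hz grid (`resample_to_uniform()`; linear is
the simplest monotone interpolant and the grid spacing is far below the 4 Hz
signal band). All 12 channels are then low-pass filtered with a 4th-order
zero-lag Butterworth at 4 Hz (`zero_lag_lowpass()`). "Zero-lag" means the
filter runs forward then backward: phase cancels, so peak *timing* — the
quantity every downstream stage depends on — is preserved, at the price of
squaring the magnitude response (a 20 Hz tone passes with amplitude
$1/(1+5^8) \approx 2.6\times10^{-6}$ of its input). Each pass starts from
steady-state initial conditions on a signal extended by odd reflection
(3 × order samples), confining startup transients to the padding and making
the DC gain exactly 1. Whether orientation and gyroscope channels need
filtering at all is debatable; the package filters all 12 uniformly for
simplicity.

## Labelling

Ground truth is carried as per-frame binary labels (1 = FS at this frame),
interconvertible with event lists (`events_to_labels()` /
`labels_to_events()`). For synthetic or benchmark data the manual labelling
procedure — find AP peaks immediately followed by a vertical peak — is
operationalised by `auto_label_peak_rule()`: AP local maxima with prominence
at least half the AP median absolute deviation and separation at least
0.3 s (just below the shortest plausible step) are kept iff a vertical local
maximum follows within 0.25 s. When a gait-aid double peak puts two
candidates inside the separation window the higher peak wins. These three
constants are configurable; they are this package's operationalisation of a
visual procedure, and the prominence default is deliberately conservative.

## Classifiers

Both models classify *frames*. The decision tree consumes single 12-feature
frames; the LSTM consumes 31-frame windows (0.3 s context each side of the
anchor frame; the first/last 15 frames use the 30 frames after/before the
anchor so every window is complete). The asymmetry is deliberate: the tree
is the fast, interpretable baseline, the LSTM the sequence model.

* **Tree** (`train_decision_tree()`): CART via `rpart`, grown with `cp = 0`,
  `minsplit = 2`, `minbucket = 1` so that `max_depth` is the binding
  capacity control (complexity pruning would otherwise dominate and make the
  depth grid meaningless at 3 % positive prevalence). Class weighting
  multiplies positive-example weights. Best known configuration: depth 10,
  weighting 1:20.
* **LSTM** (`train_lstm()`): one LSTM layer, dropout, one dense ReLU layer,
  one sigmoid unit; class-weighted binary cross-entropy; Adam with
  minibatch shuffling. The ReLU sits on the hidden dense layer (the
  architecture description leaves its placement ambiguous; a ReLU directly
  on the LSTM input would discard negative acceleration half-waves). The
  engine is implemented natively in R with batched BLAS matrix operations —
  forward pass, backpropagation through time, Adam — and is exactly
  reproducible given `hp$seed` (initialisation, shuffling and dropout all
  derive from it). Best known configuration: batch 64, 100 LSTM nodes, 50
  dense nodes, dropout 0.4, weighting 1:2. Optimiser settings are
  implementation choices: learning rate 1e-3, up to 30 epochs with early
  stopping (patience 5) on a 10 % window hold-out by default.

Prediction thresholds the class-1 probability at 0.5 (configurable).
`grid_search()` evaluates hyperparameter grids with the *corrected* pipeline
metrics, since corrected performance is what the method ultimately reports;
ranking is by pooled accuracy, ties broken by sensitivity then precision.

## Post-processing corrections

Per-frame classifiers fire on several consecutive frames around one true
strike ("banding"). `collapse_bands()` replaces every run of ≥ 2 consecutive
positive labels with a single label at the frame of maximum AP acceleration
within the run (ties to the earlier frame — closer to initial contact). The
operation is idempotent, never increases label count, and preserves isolated
predictions exactly.

Missed steps are repaired by `insert_missed_steps()` using a per-trial
*locking period* derived from the first 5 s of filtered vertical
acceleration (`compute_locking_period()`): with `M` the maximum and `m` the
mean interval between upward zero crossings of the mean-centred sample, the
period is `M/2`, or `m/2` if `M > 0.6` s, or `2M` if `M < 0.3` s (boundary
values use the default rule; fewer than 3 crossings disables the correction
with a warning). The 5-s sample is mean-centred before crossing detection —
filtered linear vertical acceleration oscillates around 0 anyway, and
centring makes the sign convention well defined.

An interval between consecutive predicted events is a *gap* when it exceeds
1.5× the previous interval (scanning starts at the second interval, which is
the first to have a predecessor). The gap is shrunk by half the locking
period at each end and an event is inserted at the AP maximum inside the
shrunken window; a degenerate window (start ≥ end) suppresses insertion.
One design point deserves emphasis: gaps are identified from the *original*
event sequence, and after an insertion only the sub-intervals of that gap
are re-scanned, still against the pre-gap reference interval. The naive
alternative — re-scanning globally with inserted events as references —
cascades: one spurious short interval makes every following normal step look
like a gap (0.5 s > 1.5 × 0.25 s) and the corrector walks down the trial
inserting events everywhere. Within-gap re-scanning still fills multi-step
gaps (each insertion splits the remaining gap) and a hard cap of 3× the
initial event count guarantees termination. Events are never removed.

`correct_predictions()` composes the two: band collapse first, then
insertion. Band correction needs the whole trial, so the pipeline is a
post-processing design, not a streaming detector.

## Evaluation

`match_events()` matches predicted to truth events one-to-one within ±2
frames (±0.04 s), greedily by increasing offset, ties to the earlier truth
event; unmatched predictions/truths are false positives/negatives and all
remaining frames true negatives, so counts tile the trial exactly and
tolerance 0 degenerates to frame-wise confusion. Metrics with a zero
denominator are reported as undefined (`NA`), never as 0.

Stride parameters (`stride_parameters()`): step time = consecutive FS
interval, stride time = alternate FS interval, cadence = mean of per-step
instantaneous cadence `60/step_time`. The instantaneous definition is
deliberately sensitive to spurious or missed events — a single halved
interval raises it — which is what makes cadence a useful error probe;
`cadence_method = "global"` gives the robust total-steps definition.
Differences (predicted − truth) are flagged against MDC for healthy older
adults (step 0.042 s, stride 0.772 s, cadence 8.44 steps/min); amputee MDC
values are not established.

`cross_validate()` folds by *trial* (participant), never by frame — windows
from one trial never appear on both sides of a split, preventing temporal
leakage. Confusion counts are pooled across folds before computing metrics
(micro-averaging, matching cohort-level reporting), and corrected and
uncorrected results are both returned.

## The default experiment, and numerical choices

`default_run_config()` defines the desk-scale study: 20 simulated
participants × 30 s at 50 Hz, 5-fold grouped CV, the best LSTM
configuration at a reduced budget (3 epochs, Adam learning rate 2.5e-3, no
validation hold-out — about 1,100 weight updates per fold, which is ample
for this signal model), band + gap correction, ±2-frame matching. These
sizes are the package's choice of a problem large enough to exercise every
stage while a full run stays in the minutes range on a single CPU;
full-length 6-min trials and the full epoch budget are YAML overrides.

Other numerical choices: interpolation is linear (cubic would change values
by far less than the noise floor); filter padding is 3× order; AP-peak ties
break to the earlier frame; per-fold LSTM seeds derive from the run seed
plus the fold index; all RNG flows from one run-level seed recorded in every
report.

## Known limitations

* The synthetic cohort is far cleaner than amputee clinic data; absolute
  metric values on it exceed what real recordings would give and should be
  read as pipeline health checks, not clinical claims.
* The LSTM engine is CPU-only and minutes-scale; it is meant for
  reproducible desk experiments, not large-scale training.
* The peak-pair auto-labeller replaces a human consensus procedure; on
  irregular gait its prominence/lag defaults may need tuning.
* Orientation channels are simulated as drift and carry no gait
  information, so models trained on synthetic data learn to ignore them —
  real orientation signals may carry more.
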