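# grfsync

Event-based temporal synchronization of markerless motion-capture heel
kinematics with force-platform vertical ground reaction force (vGRF)
recordings.

## The problem

Smartphone-based markerless motion capture (60 Hz video) and laboratory
force platforms (1000 Hz) record the same functional movement — squats,
lunges, step tasks — on independent clocks. Without a hardware trigger
the two streams start at an arbitrary relative time, so kinetic and
kinematic data cannot be combined until the clock offset is found and
removed. `grfsync` is for movement scientists, clinicians and
biomechanists who need that alignment without extra hardware.

## The algorithm

Both modalities see the same physical event — the heel striking the
ground — so the offset between its two detections is the clock error:

* the **heel contact** is detected on the min–max normalized, median
  despiked, zero-phase Butterworth filtered (2 × 4th order, 3 Hz)
  vertical heel coordinate, as the first ascending sample after a local
  minimum that crosses the adaptive threshold
  `thr = (max_post_stab − min) · c + min`, with `c = 0.2` (bilateral
  tasks) or `0.6` (single-leg tasks);
* the **loading onset** is detected on the 30 Hz zero-phase filtered
  vGRF as the first post-baseline sample above
  `thr = baseline + 0.1 · SD(signal)`, with the baseline the mean of
  the first 10 resting samples;
* the signed offset `Δt = t_onset − t_contact` (negative ⇔ the force
  clock runs ahead) re-times the force stream onto the kinematic clock
  as a pure clock correction — samples are never rolled or resampled;
* all channels are then expressed on a 0–100% movement-cycle axis
  (101 points), and curve agreement is quantified with Pearson r, RMSE
  and MAE on amplitude-normalized (0–1) curves.

Trials whose events cannot be detected (flat channels, no threshold
crossing) are reported as counted failures with reasons, and a QC check
flags trials containing a preliminary-step force transient — a known
failure mode in which the onset detector fires on the wrong contact.

A deterministic synthetic-trial generator (`synthetic_trial_spec()`,
`generate_trial()`, `generate_bank()`) produces trials with exact
ground-truth offsets, so the whole pipeline is testable with no
recordings.

## Worked example

```r
library(grfsync)

spec <- synthetic_trial_spec(true_offset_s = -1.38, seed = 7)
g <- generate_trial(spec)
res <- synchronize_trial(g$trial)
print(res)
#> <sync_result> task=squat: offset -1.3727 s (heel left @ 3.0167 s, force @ 1.6440 s)
```

The injected −1.38 s clock offset is recovered as −1.3727 s — within
one kinematic sample (1/60 s ≈ 16.7 ms) of the truth. The heel contact
was detected at 3.0167 s on the camera clock, the loading onset at
1.6440 s on the platform clock; the negative offset means the platform
clock runs ahead, and `res$shifted_vgrf` carries the force signal on
the corrected clock.

Comparing the aligned, normalized vGRF cycle of this trial with that of
an independently simulated and synchronized repetition of the same
movement:

```r
spec2 <- synthetic_trial_spec(true_offset_s = 0.52, seed = 8)
res2 <- synchronize_trial(generate_trial(spec2)$trial)
compare_curves(amplitude_normalize(res$cycle_curves$vgrf),
               amplitude_normalize(res2$cycle_curves$vgrf))
#> <agreement_metrics> r = 0.8452, RMSE = 0.1014, MAE = 0.0808 (n = 101)
```

High correlation with small dimensionless errors: the two repetitions,
recorded with different clock offsets and noise, land on the same cycle
once synchronized.

Batch processing mirrors how a recording session is analysed:

```r
bank <- generate_bank(20, extra_step_fraction = 0.1, seed = 99)
batch_synchronize(lapply(bank, `[[`, "trial"))
#> <sync_batch> 20/20 trials synchronized (100.0%)
#> Per-task offsets (s):
#>   task  n mean_offset_s sd_offset_s
#>  squat 20    -0.2243667    1.031486
```

## Command line

A thin wrapper script is installed at
`system.file("cli", "grfsync", package = "grfsync")`:

```sh
grfsync simulate --out trials/ --n 20 --seed 7
grfsync batch --manifest trials/manifest.csv --out reports/
grfsync run --trc trial.trc --force forces.csv --force-rate 1000 --out report.json
grfsync validate --ref ref_curves.csv --test test_curves.csv --out table.csv
```

Inputs are TRC marker files and delimited force exports (comma,
semicolon or tab; header names mapped in the YAML config); outputs are
JSON reports (0-based indices, seconds, full provenance including every
threshold and filter setting), CSV metric tables, and optional OpenSim
MOT exports of the shifted force channel.

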