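# texchange

Oscillatory EEG correlates of texture change during active touch: a
tested, end-to-end R implementation of the full analysis chain, from
printing-ready stimulus synthesis to electrode-wise permutation
statistics, with a synthetic-session generator that makes every stage
verifiable against known ground truth.

## The problem

When a fingertip slides across a boundary between a smooth and a rough
surface, does ongoing cortical oscillatory activity register the change?
The experimental design this package implements: participants sweep a
finger back and forth across a 100 × 50 mm tile (40 mm smooth, 40 mm
rough, 10 mm blended transition in the centre) at a cued 2.5 cm/s — one
sweep per 4 s trial, 120 trials, 60 per direction — while a six-axis
force/torque sensor under the tile tracks the fingertip and 129-channel
EEG is recorded. Band-limited power (θ 4–7, α 8–12, β 16–24 Hz) around
the moment the finger crosses the texture boundary is compared against an
*active* pre-transition baseline, electrode by electrode.

The package is for researchers who want to run, audit, or extend this
kind of naturalistic tactile-change analysis: every stage is an exported,
documented, unit-tested function.

## What it implements

* **Stimulus synthesis** — isotropic rough surfaces with the piecewise
  height PSD
  φ(q) = C on [q₀, q_r], C·(q/q_r)^(−2(1+H)) on (q_r, q₁], 0 otherwise
  (defaults q₀ = 1200, q_r = 2400, q₁ = 3600 rad/m; wavelengths
  2.62–5.24 mm), spectrally synthesized, calibrated to 0.15 mm RMS
  height, and blended into the smooth/transition/rough tile. Export as
  delimited text, 16-bit TIFF heightmap, or STL mesh.
* **Touch-sensor fusion** — block averaging 1,000 → 100 Hz,
  centre-of-pressure inversion x = −T_y/F_z, y = T_x/F_z, detection of
  complete ±5 mm transition-band traversals, 4 s trial epoching with the
  25% missing-sample rejection rule, and window loads in gram-force.
* **Time–frequency analysis** — zero-phase Butterworth preprocessing
  (0.5–100 Hz, 48–52 Hz notch, 256 Hz, common average), −2..2 s
  transition-locked epochs, a 400-point sliding Welch spectrogram (1 s
  Hanning windows every 0.01 s, 1–80 Hz at 1 Hz), robust
  z = (P − median)/MAD normalisation, and θ/α/β × window averages with a
  5-MAD trial outlier rule.
* **Statistics** — electrode-wise paired sign-flip permutation tests
  (5,000 resamples, add-one p), spatial clustering of significant
  electrodes on the sensor adjacency graph, follow-up paired t-tests with
  Bonferroni correction, and the paired load comparison.
* **Synthetic sessions** — kinematics, wrench streams and 129-channel
  EEG (1/f background + sensorimotor α/β rhythms) with event-related
  desynchronisation of exactly known magnitude injectable at chosen
  electrodes, written to disk as CSV + EDF + JSON ground truth.

See `vignettes/texture-change-eeg.Rmd` for the methods and the design
decisions behind each stage.

## Worked example

The numbered scripts under `analysis/` run the whole workflow on a
simulated session; each prints what it found and writes tables under
`results/`. Condensed from an actual run:

```sh
$ Rscript analysis/01_synthesize_texture.R
PSD: C = 3.645e-14 m^4, plateau 1200-2400 rad/m, roll-off to 3600
calibrated RMS 0.1500 mm; tile RMS 0.1041 mm
strip RMS: 0.0000 mm at x = -30 (smooth), 0.0654 at x = 0, 0.1752 at x = +30
empirical plateau / C = 0.974 (1 = perfect)

$ Rscript analysis/02_simulate_session.R   # injects −40% α power at 6 electrodes
$ Rscript analysis/03_contact_events.R
20/20 trials accepted (0% mean dropout)
transition timing vs ground truth: max |error| 9.5 ms
window loads: pre 44.0 g, transition 44.3 g

$ Rscript analysis/04_time_frequency.R
alpha z at injected electrodes: pre +0.79 -> transition +0.28
alpha z elsewhere:              pre +0.61 -> transition +0.60
```

The texture numbers say the surface is calibrated exactly (0.15 mm RMS;
the composed tile is lower because half of it is smooth) and its
empirical spectrum sits on the prescribed plateau within estimation
noise. The sensor stage recovers every simulated transition within one
100 Hz sample. The TF stage shows the injected effect exactly where it
was placed: at the six target electrodes the mean alpha z drops by ~0.5
from the pre-transition window to the transition window, while the other
122 electrodes stay flat (the common +0.6 offset is the skewness of
single-trial power under MAD scaling; it cancels in every contrast).

`analysis/05_group_stats.R` repeats this for a 10-participant group and
runs the statistics; the run that produced the outputs above flagged
5/6 injected electrodes, grouped four of them into one cluster with
follow-up t(9) = 8.04, p = 2.1e−05 (Bonferroni-corrected 1.7e−04), and
found no load difference between windows (p = 0.39) — the simulated
loads do not differ by construction.

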