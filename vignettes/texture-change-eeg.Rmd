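---
title: "Methods: oscillatory EEG correlates of texture change during active touch"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: oscillatory EEG correlates of texture change during active touch}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The experiment this package models

A participant sweeps their right index finger back and forth across a
100 x 50 mm resin tile whose left half is smooth and whose right half is
rough, with a 10 mm central region where the two surfaces merge. A visual
cue paces the sweeps at 2.5 cm/s, so one traversal of the tile takes 4 s;
trials run back to back in blocks of 30, four blocks per session,
counterbalanced by starting texture (120 trials, 60 per transition
direction). The tile sits on a six-axis force/torque sensor sampled at
1,000 Hz, and EEG is recorded from a 129-channel geodesic net at 1,000 Hz.
The scientific question is whether band-limited oscillatory power
(theta 4-7 Hz, alpha 8-12 Hz, beta 16-24 Hz) changes when the fingertip
crosses the texture boundary, relative to an *active* baseline of ongoing
texture processing just before the crossing.

The package implements every computational stage of that analysis —
stimulus synthesis, contact tracking, transition detection,
time-frequency transformation, robust normalisation, and electrode-wise
permutation statistics — plus a synthetic-session generator with known
ground truth, so the whole chain can be validated without human
recordings.

# Stimulus surface model

Rough surfaces are synthesized from an isotropic height power spectral
density with three regimes in wavenumber magnitude $q$ (rad/m):

$$
\phi(q) =
\begin{cases}
C, & q_0 \le q \le q_r,\\
C\,(q/q_r)^{-2(1+H)}, & q_r < q \le q_1,\\
0, & \text{otherwise,}
\end{cases}
$$

with defaults $q_0 = 1200$, $q_r = 2400$, $q_1 = 3600$ rad/m — texture
wavelengths 2.62-5.24 mm in the plateau band — and Hurst exponent $H$
controlling the roll-off. Realisations use spectral synthesis: a white
Gaussian field is Fourier transformed, scaled by $\sqrt{\phi(q)}$ on the
discrete wavenumber grid, and inverse transformed; because the white
field is real the result is exactly real and exactly zero-mean
($\phi(0)=0$). The amplitude constant is then calibrated so the RMS
height is 0.15 mm. The tile is composed by multiplying the rough field by
a weight $w(x)$ that rises linearly 0 to 1 across the 10 mm transition,
so there is no step edge anywhere.

Open choices and how they were fixed:

* **$H$ default 0.8.** The roll-off exponent of the printed stimulus is
  not independently documented; 0.8 is typical for real-world rough
  surfaces and is configurable (`spectral_params(H = ...)`).
* **Tile partition.** The stated segments (40 smooth + 10 transition +
  40 rough mm) sum to 90 mm of a 100 mm tile; `tile_spec()` assigns the
  remaining 10 mm as a 5 mm margin per end continuing the adjacent
  texture.
* **Blend function.** A linear cross-fade is the simplest monotone merge;
  the strip-RMS profile of a composed tile rises monotonically 0 to
  0.15 mm across the transition (tested).
* **Grid pitch 0.1 mm**, i.e. >= 17 samples per shortest retained
  wavelength ($2\pi/q_1 \approx 1.75$ mm); synthesis refuses pitches
  coarser than 4 samples per wavelength.

# Contact tracking and transition events

The tile surface defines $z = 0$; for a fingertip pressing at
$r = (x, y, 0)$ with force $F$ the sensor reads torque $T = r \times F$,
so with the dominant normal force $F_z$ (compression negative):
$x = -T_y/F_z$, $y = T_x/F_z$ — the standard centre-of-pressure
inversion, which no tangential (friction) force can bias because the
contact sits in the torque reference plane. Wrench streams are block
averaged 1,000 to 100 Hz (missing samples excluded; an all-missing block
is itself missing), and samples with load below 5 g are flagged invalid
rather than divided through — comfortably below the tens-of-grams contact
loads, so only true lift-offs are lost. Loads are reported in gram-force
($|F_z| \cdot 1000/9.81$).

A transition event is one complete monotone traversal of the +-5 mm band
about the tile centre. The reported instant is configurable because the
source description is ambiguous about which moment within the band was
used: `far-edge-exit` (default; the finger has fully left the transition
region — for a nominal sweep this is 2.2 s after sweep onset),
`band-entry`, or `centre-crossing`. Edge samples count as reaching an
edge (weak inequalities), and a traversal must happen under continuous
contact: a gap longer than 0.5 s in valid samples resets tracking, which
keeps stage reorientations between blocks from fabricating crossings.
Trials are rejected when 25% or more of their samples are missing or when
the window does not contain exactly one transition.

# Time-frequency analysis

Accepted transitions are epoched -2..2 s from EEG preprocessed with
zero-phase 4th-order Butterworth filters (0.5-100 Hz band-pass, 48-52 Hz
stop), resampled to 256 Hz, and common-average re-referenced. The
zero-phase (forward-backward) filtering is applied as the squared
magnitude response in the frequency domain in one pass over channels; the
sessions' resting lead-in/lead-out absorbs the circular edge effects, and
zero phase matters here because any group delay would shift the 0 ms
transition alignment.

Power is computed per trial and channel on a grid of 400 time bins: the
half-open interval $[-2, 2)$ s at 0.01 s pitch. Each bin's estimate is
the one-sided Hanning-tapered periodogram of the 1 s window centred on
the bin, at 1-80 Hz in 1 Hz steps (a 1 s window at 256 Hz gives exactly
1 Hz resolution, so the default uses a single full-length segment;
classic sub-segment averaging is available via `n_segments` but trades
away that resolution). Two numerical choices matter:

* **Centred windows, truncated at the edges.** A naive trailing window
  would only fit 301 windows into a 4 s epoch; centring on the half-open
  bin grid reproduces the 400-point series. Near the epoch edges the
  window is truncated and the periodogram is normalised by the truncated
  taper's energy $\sum w^2$, which keeps the estimate unbiased in
  expected power right up to the edge (tested against interior windows on
  white noise).
* **Implementation.** Interior and edge windows are checked to 1e-9
  relative error against a literal DFT-summation oracle; for small
  frequency sets the transform is evaluated as two real matrix products
  instead of FFTs, with identical results to machine precision.

## Robust normalisation

Power is converted to $z = (P - \mathrm{median})/\mathrm{MAD}$ per
participant, channel and frequency, with the *unscaled* MAD (no 1.4826
normal-consistency factor: the downstream 5-MAD outlier rule then reads
in raw MAD units, and any constant would cancel from the paired contrasts
anyway). Trials are pooled across both conditions. The open design
question is what else the reference distribution pools over, and the two
options behave very differently:

* `pool = "epoch"` (default): median and MAD are taken over trials *and*
  epoch time bins, per channel x frequency. The z at each time bin then
  measures deviation from trial-typical power, and an event-locked change
  common to all trials — the quantity under study — survives.
* `pool = "per_bin"`: median and MAD across trials separately at each
  time bin. This enforces median 0 / MAD 1 at every bin, but by the same
  token removes any component shared by all trials at a bin: a perfectly
  time-locked desynchronisation is regressed out, and only its
  trial-to-trial variability remains. A pipeline normalised this way
  cannot in principle recover a homogeneous injected effect (the package
  tests demonstrate exactly that contrast between the two modes).

The default is therefore the epoch-pooled form, which is the only
reading under which transition-locked power changes are measurable at
all. Either way, mean z retains the skew offset
$(\text{mean}-\text{median})/\text{MAD}$ of the power distribution
(about +0.6 for near-exponential power), which is why all analyses are
*contrasts* — pre vs transition, or direction vs direction — in which the
offset cancels. Bins with MAD = 0 are flagged `NA` and excluded.

Band x window values average z over the band's inclusive 1 Hz bins
(theta 4, alpha 5, beta 9 bins) and the window's half-open time bins
(pre -650..-200 ms and transition 0..450 ms: 45 bins each; the
alternative -600 ms pre-window start is configurable). Trial-level values
with $|z| > 5$ are excluded before averaging ("exceeds" is strict: 5.0
is retained).

# Statistics

For each band and contrast, a participant x electrode matrix of paired
values (128 scalp electrodes; the vertex reference is excluded) is tested
electrode-wise with a sign-flip permutation test: the observed statistic
is the paired t of the within-participant differences, the null flips
each participant's difference sign, 5,000 resamples shared across
electrodes, and the two-sided p uses the add-one estimator
$(b+1)/(n_{perm}+1)$, which cannot be exactly zero. Against exhaustive
enumeration at n = 5 the Monte-Carlo p agrees within binomial error, and
under a global null the electrode-wise rejection rate is 5% within
Monte-Carlo tolerance (both tested).

Electrodes with $p < 0.05$ are grouped into clusters as connected
components of a spatial adjacency graph; singletons are legitimate
clusters. The neighbourhood criterion is not documented for the original
montage, so adjacency is angular distance below a threshold derived from
the layout itself (median distance to the 6th-nearest neighbour, giving a
median degree near 6, typical of dense geodesic nets). Follow-up paired t
tests on cluster-mean values establish the direction of each effect, with
Bonferroni correction over the clusters tested within a contrast (the
exploratory electrode-wise stage is deliberately left uncorrected, and
bands are treated as separate families). Contact load is compared between
the two windows with a paired t test per participant means.

# The synthetic-session generator

The generator is the package's test bed: it emulates the study conditions
and nothing more.

* **Kinematics.** Back-to-back 4 s sweeps alternating direction, blocks
  counterbalanced by starting texture, smooth +-10% speed jitter with
  endpoints pinned (every sweep spans the tile in exactly one trial
  duration), small lateral wander. Between blocks the finger lifts off
  while the stage is reoriented.
* **Wrench.** Per-trial loads drawn from N(40, 10) g — the tens-of-grams
  range of real unilateral exploration — varying slowly within trials,
  driven through the forward contact model plus white sensor noise
  (5 mN force, 0.05 mN·m torque) and independent sample dropouts.
* **EEG.** Per channel: $1/f^\gamma$ background ($\gamma = 1$), plus
  narrowband 10 Hz and 20 Hz rhythms with Gaussian spatial weights
  centred on the left/right sensorimotor sites (alpha) and the central
  midline (beta), plus white measurement noise; default amplitudes
  10 / 5 / 3 / 2 uV. A PSD-slope check on a rhythm-free channel recovers
  gamma within +-0.2.
* **Injected effects.** An `erd_spec` scales a band's amplitude by
  $\sqrt{1 + \Delta}$ at named electrodes inside a window around each
  matching trial's true transition time, with 50 ms raised-cosine ramps
  (rectangular gating would splatter spectrally). Amplitude scaling makes
  the injected *power* change exactly $\Delta$, so ground truth is exact
  in the acceptance metric. Per-participant log-normal scalings of rhythm
  amplitude (sigma 0.2) and effect size (sigma 0.15) keep the group test
  nondegenerate.

What the generator does *not* emulate: volume-conducted source mixing,
ocular/cardiac artifacts (the pipeline's amplitude-threshold rejection
stands in for the original component-based cleaning), electrode drift, or
any texture-to-vibration transduction into the EEG. Passing recovery
tests therefore show the *pipeline* is correct and calibrated, not that
real scalp data behave this simply.

# Problem sizes and runtime

The recovery experiment shipped with the package simulates 30
participants at 12 trials each (2 blocks x 6 sweeps; the criterion this
feeds allows reduced trial counts) on the full 129-channel montage with
5,000 permutations — about 6-8 minutes on one core, dominated by the
400-window spectrogram. The demonstration scripts under `analysis/` use
10 participants and 2,000 permutations. Seeds flow from a single master
seed to every stage (sub-seeds are small fixed offsets), and identical
configurations reproduce identical tables bit for bit; this is asserted
by the test suite.

# Known limitations

* The contact model assumes a planar tile at the sensor reference height;
  a real fingertip applies force slightly above it, biasing the
  centre-of-pressure by the friction force times that height. The +-5 mm
  band makes transition timing insensitive to biases well below a
  millimetre.
* The per-bin robust-z variant is provided for completeness but is not a
  usable normalisation for time-locked effects (see above).
* The EDF writer/reader covers plain continuous EDF only (one rate, no
  annotations), which is all the pipeline exchanges.
* Linear-interpolation resampling attenuates power by <0.1% below 25 Hz
  and ~2% at 80 Hz; contrasts are unaffected because both windows share
  the attenuation.
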