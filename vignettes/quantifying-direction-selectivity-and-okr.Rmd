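---
title: "Methods: quantifying direction selectivity and the optokinetic reflex"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantifying direction selectivity and the optokinetic reflex}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dsokr)
```

This vignette is the package's own account of its methods: the models and
procedures implemented, the parameters that matter and their defaults, what
the synthetic-data generators do and do not emulate, the numerical choices,
and the design decisions taken where the methodology was genuinely open.

## The scientific problem

Direction-selective ganglion cells (DSGCs) fire preferentially for one
direction of visual motion. Their selectivity is classically attributed to
asymmetric GABAergic inhibition from starburst amacrine cells (SACs):
inhibition is strongest for motion in the null direction (ND), and the
preferred direction (PD) lies 180° opposite. Downstream, horizontal-coding
DSGCs drive the optokinetic reflex (OKR) — slow-pursuit eye movements that
track global motion, reset by saccades — so cellular tuning and behavioural
gain can be measured in the same animal. `dsokr` implements the
quantification chain for both levels.

## Trace preprocessing

Sweeps arrive as direction × trial matrices with a sampling-rate sidecar
(default protocol: 8 directions at 45° spacing, 3 trials, 10 kHz, 4.5 s
sweeps). The pipeline:

* averages trials pointwise per direction (`average_trials`);
* subtracts the mean of the first 500 ms (`baseline_subtract`); the window
  is configurable for recordings whose onset is contaminated;
* extracts peaks within two disjoint 1.5 s response windows, ON and OFF,
  analysed independently throughout because the two pathways are driven by
  different presynaptic circuits. IPSCs are window maxima, EPSCs window
  minima; ties go to the earliest sample. Window onsets default to 0.75 s
  and 2.75 s and should be set from the stimulus geometry (bar entry time =
  field offset / speed) when that metadata is available;
* detects spikes in cell-attached sweeps on a zero-phase 0.08–2 kHz
  Butterworth band-pass (`detect_spikes`). The classical workflow sets the
  threshold by eye; the automated default is 5 × MAD of the filtered trace
  (half the maximum on noiseless data, where the MAD degenerates to zero),
  with polarity and an explicit threshold exposed. One event per 1 ms
  refractory window, timed at the filtered local extremum;
* converts spikes to a maximum firing rate with a sliding window (100 ms by
  default, every sample offset) inside each response window
  (`max_firing_rate`);
* for current clamp, removes spikes by zero-phase low-pass filtering
  (50 Hz default) before taking the peak subthreshold depolarization
  (`remove_spikes_and_peak_vm`).

All filters are forward–backward (zero-phase) so that peak times are not
shifted; the alternative single-pass filter would bias peak latencies by
the group delay.

## Directional statistics

`vector_sum` sums response-weighted unit vectors and normalizes the length
by the peak response r_max, exactly as the field reports it. A consequence
kept deliberately (not "fixed") is that the normalized length can exceed 1
for broad curves, because the normalizer is r_max rather than Σr. A curve
whose vector sum vanishes (symmetric tuning) is flagged `defined = FALSE`
rather than given an arbitrary angle.

Two ND conventions coexist in practice and both are implemented in
`null_and_preferred_from_inhibition`: `argmax` (ND = direction of the
largest inhibitory peak) and `vector` (ND = vector-sum angle of the IPSC
curve). The convention is recorded in the result. Argmax ties resolve to
the candidate closest to the vector-sum angle, then to the smallest angle.
PD = ND + 180°, snapped to the nearest sampled direction for response
lookup since responses exist only on the sampled grid. For spiking and
subthreshold-potential curves the PD is the vector-sum angle directly
(`preferred_from_output`). `dsi` is (PD − ND)/(PD + ND) on response
magnitudes; `asymmetric_inhibition` is the signed ND − PD difference of
IPSC peaks. Angles are degrees, counterclockwise; the package fixes only
the landmark conventions (nasal = 180°, dorsal = 90°) and leaves absolute
retinal orientation to metadata.

## The parallel-conductance model

`simulate_vm` integrates

$$\frac{dV}{dt} = -\frac{G_{Exc}(t)(V - E_{Exc}) + G_{Inh}(t)(V - E_{Inh})
  + G_{Leak}(V - E_{Leak})}{C_m}$$

by forward Euler. Defaults are the empirically determined population
constants: $C_m = 80$ pF, $G_{Leak} = 3.3$ nS, $E_{Leak} = -55$ mV, with
$E_{Exc} = 0$ mV and $E_{Inh} = -60$ mV; a per-cell leak can be supplied.
Units are chosen so nS · mV / pF = mV/ms. The sign convention (relaxation
toward the conductance-weighted reversal) is the physically consistent
form; shorthand renderings of this expression sometimes drop the grouping.

Numerical choices:

* Δt defaults to 0.1 ms, a >20× stability margin at default parameters
  (the forward-Euler bound is Δt < C_m / ΣG ≈ 4–24 ms for physiological
  conductances). Divergence (|V| > 200 mV) raises an error that names the
  required bound rather than returning garbage.
* At Δt = 0.1 ms the peak depolarization agrees with a 100×-finer
  reference to <0.1 % for conductance transients on the 150 ms timescale
  of the synthetic inputs (the test suite verifies this, and the
  steady-state plateau against the closed form ΣG_iE_i/ΣG_i to 0.01 mV).
* `fit_membrane_tau` recovers relaxation time constants through the exact
  discrete form V(t+Δt) = a + bV(t), τ = −Δt/log b, which remains
  well-posed on noiseless data where nonlinear least squares has zero
  residual.

Conductance extraction (`extract_conductance`) divides baseline-subtracted
mean currents by the driving force at the recording hold — the holds sit at
the opposing reversals, so extraction and simulation are mutually
consistent — and rectifies negative values to zero after trial averaging.
Rectifying before or after averaging differs only at noise level; the
implemented order treats the printed sequence as operations on the averaged
input.

## Paired recordings and dendritic overlap

`build_iv` averages trials per holding potential and takes the largest
absolute deflection from the pre-stimulation baseline within the
depolarization epoch (the search window is not standardised in the
literature; it comes from stimulus metadata here). Commanded holds are
shifted by the liquid junction correction (−10 mV default for the
dual-recording solutions). `fit_iv` is ordinary least squares; slope in nS,
reversal −b/a (undefined and flagged when the slope is numerically zero),
and a strict R² > 0.80 quality gate — "above 0.80" is read as a strict
inequality. The tests verify the gate is monotone: added noise never flips
a failing recording to passing.

Convex hulls use the standard planar hull of traced points with shoelace
areas; intersections use Sutherland–Hodgman convex–convex clipping, which
is exact for convex inputs. `overlap_conductance_relation` reports the
squared Pearson correlation of raw values (not a regression through the
origin — the literature is ambiguous; raw Pearson² is the default).

## Eye tracking and OKR gain

Per frame, the 8 pupil markers above the likelihood threshold (default
0.9; pose-estimation networks emit a confidence per marker but the cutoff
itself is a free choice) are fitted by the Coope circle — the linear
least-squares solution of x² + y² = 2ax + 2by + c — which is exact on
noiseless circles and O(σ/√n) in center error for small marker noise.
Frames with fewer than three confident markers (three points being the
minimum that defines a circle) carry the last known center forward and are
flagged. Pupil centers are referenced to the centroid of the confident
corneal reflections, making the trace invariant to global frame
translation.

The degrees-per-pixel scale comes from the two-camera geometry: the same
pupil viewed from cameras 12° apart is displaced by a fixed pixel
distance, so scale = 12° / mean inter-camera center distance, recalibrated
per presentation (session mean; per-frame pairing makes no difference for
rigid offsets). The camera with more high-confidence frames is analysed,
with a manual override.

Positions are Gaussian-smoothed (σ = 2 frames = 20 ms at 100 fps; applied
to position, not velocity), velocity is the central-difference gradient ×
frame rate, and frames with total velocity above 30 °/s are saccades.
Camera x maps to the horizontal (nasal–temporal) axis and y to vertical;
stimulus directions 0°/90°/180°/270° are anterior/superior/posterior/
inferior.

Cumulative slow pursuit and gain involve one deliberate design choice.
Classification runs on the smoothed velocity, but the displacement
integral runs on the raw (imputed, unsmoothed) positions, excluding
saccade-labeled frames plus a one-frame margin, and keeping low-confidence
frames. Rationale: smoothing conserves total displacement but
redistributes a saccade's displacement into neighbouring slow-labeled
frames, so integrating the smoothed trace either leaks saccadic
displacement into the slow integral or (with a wide exclusion margin)
discards genuine slow pursuit — a systematic downward gain bias of up to
≈0.1 at high gains under the end-to-end recovery conditions the tests run.
On the raw trace the saccade's displacement is confined to the frames the
classifier already labels, and under last-value imputation a
low-confidence frame carries zero displacement of its own (the tracking
catch-up lands on the next confident frame), so only saccadic displacement
is excluded. `include_low_confidence = FALSE` restores the stricter
slow-frames-only reading. Gain is the signed cumulative slow displacement
along the stimulus axis divided by the total stimulus displacement
(velocity × duration, 2 °/s × 45 s = 90° per presentation); positive means
pursuit with the stimulus.

Known residual bias: slow-pursuit displacement genuinely absent during
saccades and in the frames adjacent to them is lost from the numerator
while the denominator keeps the full stimulus displacement, so recovered
gain underestimates the slow-phase velocity ratio by ~2–3 % of its value
at typical saccade rates. The end-to-end tests bound the total error at
<0.05 across gains 0.1–1.0 with saccades at 0.3 /s, 0.05° tracking noise
and 5 % dropout.

## The synthetic-data generators

Every generator is seeded, deterministic, and returns the latent
parameters downstream stages are supposed to recover.

* **PSC sweeps** (`gen_psc_sweeps`): ON and OFF alpha-function transients
  (g(t) = (t/τ)e^{1−t/τ}, τ = 150 ms default) whose noiseless peak follows
  a von-Mises-shaped tuning law rescaled to 1 at the preferred direction
  and 0 at its opposite, parameterised by a half-width (default 60°), plus
  white noise (10 pA default). Real PSC waveforms are not parameterised in
  the literature; the alpha function is the conventional stand-in.
* **Spike sweeps** (`gen_spike_sweeps`): dead-time-corrected Poisson
  trains within the response windows — an absolute 2 ms refractory period
  plus an exponential interval at the compensated rate, so the window-mean
  rate equals the tuning-law rate while no two spikes fall closer than a
  detector's refractory window can resolve, as in real trains. Spikes are
  smooth biphasic waveforms peaking at the nominal time.
* **IV datasets** (`gen_iv_currents`): I = g(V − E) plus trial noise on
  the −80…−40 mV grid (10 mV steps; the published grids leave the step
  unstated).
* **Eye sessions** (`gen_eye_markers`): the latent eye follows the
  stimulus at `gain_true` and is *interrupted* by resetting saccades —
  slow pursuit pauses while a minimum-jerk displacement (5°, 200 °/s peak
  by default) executes opposite the stimulus, the physiological sawtooth.
  Rendering is an orthographic pixel projection at a configurable scale
  with the second camera's centers offset by the pixel equivalent of 12°;
  8 pupil markers lie exactly on a circle, 3 reflections at fixed pixels;
  dropout frames get sub-threshold likelihoods. Trial-to-trial noise
  magnitudes are not reported for the real recordings, so the defaults
  (0.05° tracking noise, 5 % dropout) are free parameters exposed in the
  spec.
* **Dendritic fields** (`gen_dendrite_fields`): rectangular point clouds
  with an exactly known hull-intersection area.

What the generators do **not** emulate — and hence what passing tests do
not establish about real data: electrode drift and series-resistance
artefacts, correlated (non-white) recording noise, pupil-size dynamics and
torsional eye movements, perspective distortion in the camera projection,
pose-estimation failure modes beyond uniform likelihood dropout, and
non-convex dendritic geometry. The pipeline's parameter recovery on
synthetic data demonstrates correctness of the computations, not
robustness to every artefact of acquisition.

## Problem sizes

The test suite and the analysis scripts run at desk scale by choice:
3 trials × 8 directions per cell at 10 kHz (down-sampled to 0.5–2 kHz
where only peaks matter), 45 s eye sessions at 100 fps, 100 seeded
sessions for the end-to-end gain-recovery bound, 500 seeds for IV slope
recovery, 1,000 random curves for the vector-sum oracle, and 10⁵
rejection samples for the geometry oracle.

## Limitations

* The membrane model is a point neuron: no dendritic cable, spiking
  mechanism, NMDA voltage dependence, or conductance noise.
* ND/PD from inhibition presumes inhibition defines the null axis; cells
  whose tuning arises elsewhere need the output-based convention.
* The OKR gain estimator inherits the method's structural bias (slow
  displacement during excluded frames is unrecoverable), bounded as
  described above.
* The pose-marker reader handles the three-header-row CSV dialect only;
  vendor binary formats are out of scope.
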