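---
title: "pairpatch: models, estimators and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{pairpatch: models, estimators and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pairpatch)
```

pairpatch analyzes paired intracellular recordings from cortical neurons:
how excitable each cell is, whether the two cells are monosynaptically
connected, how strong and how reliable that connection is, how much
spontaneous synaptic input each cell receives, and how correlated the two
cells' spontaneous activity is.  The scientific setting is ensemble
formation: repeated co-stimulation of nearby pyramidal neurons raises their
input resistance, lowers their firing threshold, increases spontaneous
EPSP rates, and increases pairwise correlation - changes the pipeline is
designed to detect and quantify.  Every estimator in the package is
validated against a synthetic-trace generator that emits exact ground
truth.

All units are fixed internally: mV, pA, ms, MOhm (seal resistance in
GOhm).  Sampling is 10 kHz (`dt = 0.1` ms) unless stated otherwise.  Every
sample `i` covers the half-open interval `[t0 + i*dt, t0 + (i+1)*dt)`, and
all time windows are half-open, so windowing composes without off-by-one
ambiguity.

## The membrane model

Simulated cells are exponential integrate-and-fire (EIF) neurons,

$$\tau \frac{dV}{dt} = -(V - E_\mathrm{rest}) + 10^{-3} R I(t)
  + \Delta_T e^{(V - V_T)/\Delta_T}, \qquad \tau = RC/1000,$$

integrated by forward Euler at the sampling step.  When the trajectory
escapes past $V_T + 5\Delta_T$ it is rewound to the take-off sample (the
first sample at or above $V_T$) and a stereotyped action-potential
template is spliced in; the template's first sample equals $V_T$ exactly
and its initial slope (2 mV/ms) sits just above the spike-detection
criterion.  The take-off sample is the ground-truth spike time and $V_T$
the ground-truth threshold, which is what makes phase-plot threshold
estimation testable to 0.01 mV.  A plain leaky integrate-and-fire cell was
rejected because it has no dV/dt loop for the phase plot to latch onto.

Two deliberate departures from a literal biophysical reading:

* **Observation noise, not process noise.**  Gaussian noise (default SD
  0.1 mV, chosen so the 0.3 mV EPSP detection floor is a 3 SD event) is
  added to the *recorded* trace.  The noiseless dynamics therefore remain
  exact, which gives clean analytic oracles (Ohmic steady states, exact
  take-off voltages) while detectors still face realistic noise.
* **Linear superposition for spontaneous segments.**  Zero-command
  spontaneous activity is a Poisson barrage of PSP kernels added to
  $E_\mathrm{rest}$.  In the subthreshold regime the membrane is Ohmic and
  the superposition *is* the closed-form solution, so every event's
  amplitude is exact ground truth.  Spiking protocols always run through
  the EIF integrator.

### Parameter defaults and an honest inconsistency

Default passive parameters are the group values the analyses must recover:
$R = 278$ MOhm, $E_\mathrm{rest} = -73$ mV, $V_T = -41$ mV, $C = 40$ pF
(membrane time constant ~11 ms, which also lets 5 ms / 400-600 pA
presynaptic pulses trigger spikes, as the stimulation protocol requires).
These values are jointly inconsistent for an Ohmic membrane: with a 32 mV
gap between rest and threshold, a 278 MOhm cell needs ~115 pA to fire, yet
the threshold assay reads the first spike of the *60 pA* step.  Real
neurons square this circle with voltage-dependent conductances the EIF
does not model.  Rather than distort the printed passive values, the
threshold and F-I assays use a high-Rm configuration (`R = 650` MOhm,
rheobase ~48 pA, suprathreshold at 60 pA across the tested $V_T$ grid)
while passive-property assays keep $R = 278$.  Both configurations are
plain `neuron_params()` calls; nothing is hidden in the estimators.

## Synapses and short-term depression

A monosynaptic connection is a double-exponential current (or voltage)
kernel triggered at `latency` (default 2 ms) after each presynaptic spike
take-off.  Mean amplitudes within a 20 Hz train follow the
Tsodyks-Markram depletion recursion

$$A_n = q U R_n, \qquad R_1 = 1,\quad
  R_{n+1} = 1 - \bigl(1 - (1-U)R_n\bigr)e^{-\Delta t/\tau_\mathrm{rec}},$$

with defaults $q = 28$ pA, $U = 0.5$ (so $A_1 = qU = 14$ pA, the reported
baseline unitary EPSC), $\tau_\mathrm{rec} = 200$ ms, and independent
per-pulse failures at probability 0.3.  At 20 Hz this gives the frozen
oracle $\mathrm{PPR} = A_2/A_1 = 1 - 0.5e^{-0.25} \approx 0.611$.

The biphasic effect of prolonged stimulation on evoked amplitudes
(depression during stimulation, rebound potentiation after rest) is
modeled *phenomenologically*: `effect_spec()` scales the synaptic gain by
condition, default $1 \to 8/14 \to 20/14$ across before / after
stimulation / rest, matching the printed group means (14, 8, 20 pA).  No
mechanistic vesicle-pool model across conditions is attempted because the
source analysis reports only the group means.  The same `effect_spec()`
carries the intrinsic shifts (Rm x 305/278, threshold -2.7 mV) and the
spontaneous-EPSP shifts (rate x 127/90, amplitude x 0.41/0.38); `drug`
(an ERG-channel blocker) and `unstim_control` revert to identity.

## Spike detection and the threshold criterion

The published criterion is a bare number: a first-derivative threshold of
"0.00015".  At 10 kHz, 0.00015 V per sample is 1.5 mV/ms, which is also a
physiologically standard onset criterion; the package exposes it as
`dvdt_threshold = 1.5` (mV/ms) and documents the unit reading as an
interpretation.  The derivative is computed by central differences after
3-point smoothing.

A literal "first sample where dV/dt exceeds the criterion" rule fails in
two ways we verified during development: it re-fires inside a single AP
upstroke once a short lockout expires, and it triggers on the charging
slope of strong current pulses (~12 mV/ms for a 5 ms, 500 pA pulse).  The
implemented detector therefore anchors on unambiguous AP rising phases
(dV/dt crossing 30 mV/ms, unreachable by noise or passive charging),
backtracks to the first sample at or above the onset criterion since the
last sub-criterion sample - which is *exactly* the literal rule whenever
the subthreshold approach obeys it, i.e. for every I-V protocol step - and
falls back to the local slope minimum for pulse-driven approaches.  A
20 mV peak gate within 2 ms rejects residual noise, and re-arming requires
repolarization below the spike's own threshold so one upstroke can never
count twice.  `phase_plot()` uses the matching rule: the threshold point
is the first sample of the contiguous super-criterion run containing the
upstroke, which ignores isolated noise crossings earlier in the window.

Per-cell firing threshold is read from the first spike of the 60 pA sweep
(`firing_threshold_60pA()`); if that sweep has no spike the function
returns `NA` with a diagnostic rather than silently substituting another
step.

## Passive properties

Input resistance is the ordinary least-squares slope of steady-state
voltage against injected current over spike-free steps in [-100, +40] pA;
steady state is the mean over the last 100 ms of the 500 ms step (the
charging transient at tau ~11-28 ms is below 1e-6 by then).  The fit is
not forced through the resting point.  Resting potential is the sample
median of zero-command activity - the median is what makes the estimate
robust to a 100/min EPSP barrage riding on the baseline.

## Evoked responses and connection classification

For each presynaptic AP, the postsynaptic baseline is the trace value at
the AP take-off time (implemented as the mean of the 0.5 ms ending at
take-off: the single-sample reading injects a per-session offset of SD
$\sigma/\sqrt{n_\mathrm{trials}}$ for no benefit).  The per-pulse *mean*
amplitude is measured on the trial-averaged waveform - peak located on a
0.5 ms-smoothed copy, amplitude read as a short average of the raw mean
waveform around that peak.  Averaging first is essential: the extremum of
white noise over a 10 ms window has expectation ~2.5 SD, so per-trial
extremum means would push every unconnected pair past the 1.5 SD
criterion.  Failure trials are averaged in as recorded ("including
failures"); per-trial amplitudes and 2-SD failure flags are kept as
diagnostics only.

A pair is called connected when the mean first response exceeds
`k = 1.5` baseline-noise SDs *and* its latency lies within 2 +/- 1 ms of
the presynaptic spike.  Latency is the median 10%-of-peak onset across
non-failure trials.  For population responses to field stimulation the
latency criterion inverts (`rule = "population"`: accept latency > 2 ms),
excluding direct opsin-driven currents.  The paired-pulse ratio is the
ratio of means (EPSC2/EPSC1), failures included; a mean-of-ratios variant
exists but is not the default because single-trial EPSC1 failures make
ratios unstable.  Noise SD is pooled across the 50 ms pre-train windows of
all trials of a session.

## Spontaneous EPSP detection

The slow baseline (membrane potential oscillations) is removed by a
zero-phase low pass, default 1 Hz: the trace is block-mean decimated to
100 Hz, smoothed with a symmetric Gaussian (-3 dB at the cutoff), and
interpolated back - O(n), symmetric, and equivalent to an FFT Gaussian
filter for sub-Hz content.  The residual is smoothed (2 ms boxcar) and
candidate events are its local maxima, clustered within 5 ms keeping the
tallest.  An event is accepted when

* its amplitude - peak minus a *low-quantile* local baseline (25% quantile
  of the residual since the previous accepted event, at most 20 ms back) -
  lies in [0.3, 10] mV, and
* its 10-90% rise time, estimated as $0.8\,\mathrm{amp}/\max(\text{rising
  slope})$, is at most 5 ms.

Two estimator choices here came from failures of the naive versions on
synthetic data: a minimum-statistic baseline inflates every amplitude by
the extreme-value bias of the noise (enough to push 0.2 mV events past the
0.3 mV floor), and level-crossing rise-time estimators are confounded by
noise wiggles on the event crown, while the slope-maximum form rejects
slow oscillations identically.  Detections mark the event crown, ~3.5-8 ms
after kernel onset, so truth matching in tests accepts detections in
`[t_event, t_event + 12 ms]`.  With the acceptance settings (100
events/min at 0.4-2 mV, 0.1 mV noise) the detector achieves recall and
precision above 0.9 with a false-positive budget of ~0/min on flat traces.

## Pairwise correlation

`pair_correlation()` defaults to the product-moment correlation of
baseline-subtracted voltages (same 1 Hz rule) over the first minutes of
simultaneous zero-command recording; binned spike counts (100 ms bins) are
a selectable alternative, and the pipeline records which method produced
each number.  The generator realizes correlated activity through *shared
input*: a fraction of the barrage is common to both cells.  With
independent 0.1 mV observation noise the coefficient at full sharing is
structurally below 1 (~0.5-0.65 under defaults); the r = 1 limiting case
holds exactly at zero observation noise, and that is how the limiting-case
test is written.  Correlation is monotone in the shared fraction, which is
the property the acceptance suite checks, alongside contrast power at the
7-connected / 21-unconnected design.

## Statistics

Group data are summarized as median +/- SEM with a *mean-based* SEM
(sd/sqrt(n)) - reproducing the reporting convention as printed, odd as the
pairing is; a bootstrap SE of the median would be straightforward but is
deliberately not the default.  The two tests are exact small-sample
implementations:

* Wilcoxon signed-rank: zero differences dropped, mid-ranks for ties,
  exact two-sided p by dynamic programming over the distribution of the
  signed-rank sum (identical to enumerating all $2^n$ sign assignments)
  for n <= 25, normal approximation with tie and continuity correction
  above.
* Mann-Whitney: exact by subset-sum DP over all group assignments of the
  mid-ranks for combined n <= 20, approximation with tie correction above.

Two-sided p is `2 * min(lower, upper)` capped at 1.  Exactness is tested
against brute-force enumeration (an independent oracle transcribed
separately in the test helpers) on random integer data with ties and
zeros.  One calibration subtlety: exact tests have *discrete* p-value
distributions, so their sup-distance from the continuous uniform equals
the largest support gap (~0.08 at n = 10) no matter how correct the test
is.  The calibration check therefore compares the empirical p distribution
with the exact discrete null CDF and verifies super-uniformity of the tail
probabilities; the 7-vs-21 approximate path is checked for a ~5% type-I
rate directly.  No multiple-testing correction is applied, matching
per-comparison reporting.

## What a green test establishes, and what it does not

The generator emulates protocol structure (10 kHz sampling, 500 ms / 20 pA
I-V steps from -100 to 160 pA, 20 Hz / 10-pulse presynaptic trains, 4 s
on / 10 s off stimulation trains), reported effect sizes, measurement
noise, synaptic failures, and shared-input correlation.  It does not
emulate: electrode/access-resistance artifacts, slow drift or the
post-stimulation instability window (analyses are defined on stable
segments), spike-frequency adaptation or bursting (simulated F-I slopes
are steeper than real ones), conductance-based synaptic interactions,
correlated (non-white) recording noise, or network activity beyond a pair
with common input.  Green acceptance tests therefore establish that the
estimators recover known truth under the stated world - not that the
stated world captures every failure mode of perforated-patch data.

## Degenerate inputs and numerical conventions

Empty recordings, non-finite samples, dt mismatches, windows outside the
trace, negative seal resistances, dead (zero-variance) channels, groups of
size < 2, all-zero difference vectors, and undefined PPR (mean EPSC1 at or
below the noise floor) are errors or flagged diagnostics, never silent
NAs.  Correlations exceeding |1| by numerical error are clamped after
asserting the excess is below 1e-9.  QC thresholds are strict inequalities
(leak > 25 pA, seal < 1 GOhm fail), so boundary values pass.  Round-trip
IO is full-precision; write -> read -> write is byte-identical.  All
randomness flows through R's RNG from user-supplied seeds; per-pair seeds
are derived below 2^31.
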