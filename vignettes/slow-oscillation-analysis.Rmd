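---
title: "Up/Down state detection and evoked-response quantification for in vivo LFP"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Up/Down state detection and evoked-response quantification for in vivo LFP}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(slowosc)
```

## The problem

Under deep anesthesia, cortical and striatal networks alternate between
active, depolarized **Up states** — with vigorous population firing and
gamma-band activity — and silent **Down states**, at roughly 1 Hz (the slow
oscillation). A single extracellular electrode records this as a local field
potential (LFP): a low-frequency voltage trace in which the Up/Down
alternation is visible but not trivially segmentable, because no single
feature (raw voltage, high-frequency power, gamma content) separates the two
states reliably on its own. The same preparations are probed with electrical
stimulation of the thalamus (here, of the ventral posteromedial nucleus),
which evokes short-latency positive/negative deflections in striatum and
cortex whose latency, amplitude and area scale with stimulus intensity.

`slowosc` implements the full analysis chain for such recordings, plus a
seeded simulator that generates recordings with known ground truth, so every
stage of the chain can be verified quantitatively rather than by eye.

## The detection model

Detection combines three time-aligned features of the LFP, sampled on a
common 5 ms grid:

* **z-scored raw LFP** — the slow deflection itself;
* **logMUA** — the natural log of the moving 200–1500 Hz band power. Power
  in this band tracks local population spiking (multi-unit activity), and
  the log makes the Up/Down contrast approximately additive and
  gain-invariant;
* **gamma-variance envelope** — the smoothed moving variance of the 30–100
  Hz filtered LFP, capturing the gamma activity that rides on Up states.

Each feature is z-scored over the analyzed span and the three-column matrix
is projected onto the leading eigenvector of its 3×3 covariance (PCA). The
first principal component concentrates the shared Up/Down contrast — on
simulated recordings it typically explains over 80% of the feature variance
— and its distribution over time samples is bimodal: one mode per state.

A two-component Gaussian mixture (unequal variances) is fitted to the PC1
values and the threshold is placed at the density crossing between the two
component means (midpoint fallback if no crossing lies between them). Two
diagnostics replace the original interactive, visual validation of each
detection:

* **separation index** — Ashman's D, $|m_1-m_2| / \sqrt{2(s_1^2+s_2^2)}$,
  with floor 2, the conventional cutoff below which a mixture is not
  considered bimodal;
* **valley ratio** — mixture density at the threshold relative to the lower
  mode peak; a genuine bimodal density has a valley (< 0.9 required).

Recordings failing either check are rejected as not bistable rather than
segmented arbitrarily.

Samples above threshold become Up (1), below become Down (0). A minimum
state duration of 80 ms is then enforced to suppress random threshold
crossings: interior intervals shorter than the minimum are merged into the
surrounding state, shortest first (earliest on ties), iterating until none
remain. Intervals truncated by the record edges are exempt, since their true
duration is unknown. The same rule is implemented twice in the test suite —
once on the run-length encoding (the package) and once by brute-force label
flipping — and the two must agree exactly.

One textual ambiguity is resolved by a switch: the threshold is derived from
the PC1 bimodal distribution, and by default the PC1 series is also the one
binarized (`detection_signal = "pc1"`), since PC1 is the quantity whose
bimodality justifies the threshold; `detection_signal = "logmua"` thresholds
the z-scored logMUA directly, preserving the alternative reading. On
simulated recordings both exceed 90% sample-wise agreement with ground
truth; PC1 is the default because it pools all three features.

## Spectral analysis

The power spectral density of the z-scored LFP uses Welch's
averaged-periodogram method with 2 s windows and 0.1 Hz bins. The taper,
overlap and padding are not dictated by those two constants, so the package
fixes them as: Hann taper, 50% overlap, segments zero-padded to 10 s so a
2 s window yields the 0.1 Hz grid. Band power is the mean PSD over each
half-open band: alpha 8–12, beta 12–30, low-gamma 30–60, high-gamma
60–100 Hz. A Parseval check (unit-variance white noise integrates to 1) and
a pure-tone check (10 Hz sinusoid peaks in the 10.0 Hz bin) pin the
calibration.

## Evoked-response quantification

Responses to 50 stimuli per intensity are averaged pointwise per channel
(the median is stored alongside for QC; metrics use the mean), and the
scalar mean of a pre-stimulus baseline window (default [−100, 0) ms) is
subtracted per channel.

**Peaks.** The first positive peak is the earliest local maximum above
+20 µV with latency in 3–50 ms after stimulus onset; the first negative peak
the earliest local minimum below −20 µV in the same window. Both criteria
are hard filters — detections violating them are never emitted, and the
package asserts this on every call. Samples before 3 ms (the stimulus
artifact span) are excluded from the search. Candidates are located on a
2 ms-smoothed trace and refined on the raw trace within ±1 ms, which keeps
noiseless latencies exact to the sample while preventing single-sample noise
extrema from masquerading as "first" peaks. Each detection carries a QC
record (prominence, baseline SD) in place of interactive review.

**Transitions.** The onset of a deflection is the point where the response
starts to rise or fall. Operationally: find the last pre-peak sample where
the 2 ms-smoothed magnitude is below max(2 × baseline SD, 5% of the peak),
then walk further back on the raw waveform while its magnitude still
strictly decreases, and stop there. The threshold alone places the onset of
a clean ramp about half a smoothing window late; the walk-back recovers the
exact foot of a noiseless ramp while, under noise, stopping within the noise
scale of the threshold crossing. The offset is symmetric after the peak.

**Amplitude and AUC.** Amplitude is |waveform(peak) − waveform(onset)|; AUC
is the absolute trapezoidal integral of the waveform between the bracketing
transitions (µV·ms). A triangular test deflection (100 µV peak, 20 ms base)
must give amplitude 100 µV and AUC 1000 µV·ms to within discretization
error.

**Long-lasting responses.** Each channel's average is z-scored against its
baseline mean/SD and |z| is integrated over the 600 ms post-stimulus window.
The phrase "AUC and the standard deviation of the 32-channel-averaged
evoked response" admits two readings, so both are reported: the AUC of the
channel-averaged z trace plus the SD across the 32 per-channel AUCs, and
additionally the temporal SD of the channel-averaged trace. Note that
baseline z-scoring cancels any pure gain, so on the simulated array the
spatial decay manifests as a falling signal-to-noise ratio, not a
proportional AUC decay.

## The simulator

The generator produces the statistical structure the detector assumes,
without biophysical modeling:

* **State sequence** — alternating Up/Down durations from a normal
  distribution truncated below at 100 ms (just above the 80 ms filter, so
  states are detectable yet the filter can be exercised by lowering the
  floor). Defaults: Up 0.5 ± 0.15 s, Down 0.5 ± 0.15 s, i.e. a ~1 Hz slow
  oscillation. No duration statistics were available to fit, so these are
  conventional values for deep urethane anesthesia.
* **Broadband MUA surrogate** — Gaussian noise band-passed 200–1500 Hz
  (zero-phase Butterworth order 4), amplitude 10 µV in Down states and
  `up_mua_gain` (default 4) times that in Up states. Spikes are not
  modeled; only the band power the detector measures is.
* **Gamma surrogate** — 30–100 Hz band-limited noise (15 µV) added during
  Up states; the band is the union of the low/high gamma analysis bands.
* **LFP deflection** — an 80 µV low-pass-smoothed Up-state offset over a
  1/f background (30 µV) plus 5 µV white noise.
* **Evoked templates** — sums of Gaussian-shaped components (polarity,
  latency, amplitude, FWHM), scaled across intensities by a logistic gain in
  log-intensity anchored to 1 at the 80 µA reference — a saturating,
  monotone intensity–response curve. Trials add i.i.d. Gaussian noise;
  arrays attenuate the template as exp(−distance/decay length) with
  independent noise per channel.
* **Seeding** — one top-level integer seed; each component derives its own
  stream deterministically, so every `simulate_*` call is a pure function of
  (parameters, seed).

What the simulator does **not** emulate: spike waveforms and refractoriness,
state-transition ramps (transitions are instantaneous up to filter
smoothing), non-stationary anesthesia depth, stimulus artifacts, line noise,
and electrode drift. Passing recovery tests on these simulations therefore
demonstrates that the analysis correctly measures the structure it claims to
measure — not that detection would be flawless on every real recording.

## Numerical choices and degenerate inputs

* Feature series are decimated to a 5 ms step (200 Hz), which resolves the
  80 ms minimum duration (16 samples) while keeping mixture fitting cheap;
  the logMUA power window is 50 ms, the gamma variance window 100 ms
  (several gamma cycles), smoothed at 20 Hz.
* Power is floored at 10⁻¹² µV² before the log, so logMUA is finite for
  silent inputs.
* Zero-phase filtering leaves edge transients of roughly one filter time
  constant at the record boundaries; steady-state tests evaluate the
  interior.
* PC1's sign is fixed by positive correlation with logMUA, so Up states are
  always the high mode; rank-deficient feature covariances fall back to the
  dominant surviving direction with a warning.
* A zero-variance feature column, a unimodal PC1 distribution, a baseline
  window with no samples, non-positive section spacing, and p-values
  outside (0, 1] are all rejected with named errors rather than propagated.
* A segmentation with no Up intervals reports `NA` durations, not zero.
* All intervals are half-open `[start, end)` in seconds; epoch time is ms
  relative to stimulus onset, half-open `[−baseline, +post)`.

## Multiple testing

`benjamini_hochberg()` implements the step-up rule directly (sorted
p-values, largest rank *i* with `p_(i) <= i q / m`, adjusted values as
running minima capped at 1). The FDR level `q` is a parameter — an overall
FDR near 0.125 is a property of a particular dataset's p-values, not of the
procedure — and exact zeros are rejected as invalid input to catch upstream
errors. The test suite checks the implementation against an exhaustive
every-rank oracle and against `stats::p.adjust`, and verifies error control
on global-null simulations.

## Problem sizes

The bundled analyses and tests use a 200 s recording at 5 kHz (10⁶ samples,
~200 slow-oscillation cycles), 50 trials per intensity, 8 intensities, and a
32-channel array — the protocol's own scales — with shorter records (10–30 s)
for the many per-operation unit tests. At these sizes the full workflow runs
in well under a minute on a single core.

## Known limitations

* The mixture threshold assumes exactly two states; recordings with
  intermediate micro-states will fail the bimodality gate rather than be
  segmented into three regimes.
* Duration statistics exclude edge-truncated intervals; very short records
  (a few cycles) therefore estimate durations from few intervals and carry a
  warning flag.
* Peak detection reports the *first* criteria-satisfying extremum, by
  design; if a small early component rides above 20 µV it, not the largest
  deflection, defines the first wave.
* The 600 ms long-lasting metrics inherit the z-scoring caveat above: they
  are SNR-like quantities, not absolute voltages.
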