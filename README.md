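# slowosc

Analysis of slow-oscillation local field potentials (LFP) recorded in vivo
under deep anesthesia, and of thalamically evoked responses in striatum and
cortex — with a seeded synthetic-data generator that provides ground truth
for every stage.

The package is written for electrophysiologists who have (or want to
emulate) continuous LFP recordings digitized at ~5 kHz and stimulus-locked
trial sets, and need reproducible, scriptable versions of analyses that are
often done interactively:

* **Up/Down state detection.** The detector builds a z-scored multivariate
  time series from three features of the LFP — the raw signal, the log of
  its moving 200–1500 Hz band power (logMUA, a population-firing proxy), and
  the envelope of the variance of the gamma-filtered (30–100 Hz) signal —
  and projects it onto its first principal component,
  $y_t = \mathbf{w}^\top \mathbf{z}_t$, with $\mathbf{w}$ the leading
  eigenvector of the 3×3 feature covariance. The distribution of $y_t$ is
  bimodal; a two-component Gaussian-mixture fit places the threshold at the
  density crossing between the modes, samples above it are labeled Up, and a
  minimum state duration of 80 ms is enforced by iterative shortest-first
  merging. Bimodality diagnostics (Ashman's D, valley ratio) replace visual
  validation.
* **Spectra.** Welch PSD of the z-scored LFP (2 s Hann windows, 50%
  overlap, 0.1 Hz bins) and mean band power over alpha (8–12), beta
  (12–30), low-gamma (30–60) and high-gamma (60–100 Hz).
* **Evoked responses.** Trial averaging with baseline normalization; first
  positive/negative peak detection (|amplitude| > 20 µV, latency 3–50 ms);
  transition (onset/offset) times; amplitude = |peak − onset| and AUC = the
  absolute trapezoidal integral between transitions; intensity–response
  curves; 600 ms long-lasting response metrics (baseline z-scored AUC and
  its spread across a 32-channel array).
* **Scalar quantifications and FDR.** Traced-inputs-per-starter-neuron
  normalization, dendritic spine density (spines/µm, > 20 µm segments),
  Cavalieri volumes (spacing × Σ areas), microdialysis percent-of-baseline
  (mean of 5 pre-drug fractions), and the Benjamini–Hochberg step-up
  procedure.
* **Simulator.** `simulate_slow_oscillation()` and
  `simulate_evoked_trials()` generate recordings with exported ground truth
  (state labels/intervals, noiseless templates), so recovery can be measured
  instead of assumed.

## Worked example

```r
library(slowosc)

sim <- simulate_slow_oscillation(
  slow_osc_params(duration = 200, up_mua_gain = 4, seed = 11))
det <- detect_states(sim$recording, min_duration = 0.080)

det$threshold$separation_index
#> [1] 2.56
det$stats$mean_up_duration
#> [1] 0.527
c(det$stats$firing_rate_up, det$stats$firing_rate_down)
#> [1] 7.34 5.58

lab <- intervals_to_labels(det$segmentation$intervals, 5000,
                           length(sim$truth$state_labels))
mean(lab == sim$truth$state_labels)
#> [1] 0.9739
```

A separation index of 2.56 says the PC1 distribution is clearly bimodal
(values below 2 are rejected as not bistable). The detected mean Up-state
duration, 0.527 s, is within 5% of the realized true mean; the mean logMUA
is higher during Up (7.34) than Down (5.58) states, as it must be; and
97.4% of the 10⁶ samples carry the correct label.

The `analysis/` directory holds the numbered workflow drivers
(`01_simulate.R` … `05_quant_stats.R`); each prints what it found and writes
its tables under `results/`. Run them in order from the repository root
after installing the package.

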