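# obhfo

Analysis of respiration-coupled high-frequency oscillations (HFO) in
laminar local field potential (LFP) recordings from the olfactory bulb.

Under ketamine-xylazine anesthesia the olfactory bulb generates a prominent
80–130 Hz rhythm that appears as ~100 ms bursts nested on the
respiration-tracking delta rhythm (0.3–3 Hz), reverses polarity across a
current dipole near the mitral layer, and is driven by trough-locked
multi-unit spiking — while classical 30–65 Hz gamma power falls. `obhfo`
is for electrophysiologists who need to quantify this phenomenology:
burst detection, cross-frequency coupling, laminar source localisation and
gated condition statistics, plus a fully parameterised forward model so
every estimator can be validated against known ground truth.

## What it computes

* **Spectral**: zero-phase Butterworth band filters, Welch power spectra
  (`sum(power)*df = variance`), dominant frequency and power per band,
  sliding band-power timecourses.
* **Bursts**: Hilbert envelope, 3-SD threshold detection with robust
  (median/MAD) baseline, cycle-based duration/merge rules.
* **Coupling**: burst phase relative to delta peaks (time-rescaling or
  Hilbert mode); intertrial phase clustering
  `ITPC = |n^-1 Σ_r exp(i k_r)|`; Pearson envelope correlations; the Tort
  modulation index `MI = (log N − H(P)) / log N` over phase-binned
  amplitudes; comodulograms over band grids; and a seeded group resampling
  test for MI matrices (pool, redraw with replacement, add-one smoothed
  p-values).
* **Laminar**: depth power profiles; burst-triggered maximum-correlation
  phase-shift profiles and reversal-depth estimation; 1D kernel
  current-source-density (kCSD: Gaussian basis sources, quasi-1D forward
  integral, ridge inversion with leave-one-electrode-out cross-validated
  regularisation); band-filtered CSD maps; >500 Hz multi-unit spike
  detection and burst-aligned MUA–HFO correlation.
* **Statistics**: Shapiro-Wilk-gated choice among paired t, Wilcoxon,
  one-way ANOVA and Friedman + Nemenyi post-hoc, for two-condition and
  repeated-epoch designs.
* **Synthesis**: a laminar forward model (dipole projections of delta, HFO
  bursts with von Mises respiration-phase gating, gamma, phase-locked
  spikes, 1/f + white noise) with explicit seeds and a two-condition
  contrast generator with exact per-band power multipliers.

## Worked example

Simulate one minute of strongly coupled activity on a 16-channel probe and
run the coupling chain:

```r
library(obhfo)

gt  <- ground_truth(seed = 42, fs = 1000, duration = 60,
                    coupling_kappa = 8, mua_rate = 0)
sim <- generate_laminar_recording(gt, probe_geometry(16, 200, 100))
sim
#> synth_lfp: 16 channels, 60 s, 67 true bursts, no spikes

x   <- recording(sim$lfp$samples[sim$reference_channel, ], gt$fs)
env <- analytic_envelope_phase(bandpass(x, band_hfo_kx()))$envelope
bursts <- detect_bursts(env, gt$fs, band = band_hfo_kx())
nrow(bursts)
#> [1] 67

ps <- burst_delta_phase(bursts, bandpass(x, band_delta()))
ps
#> phase_set: n = 67, circular mean 0.713 rad, ITPC 0.929 (delta peak = 0)

cm <- comodulogram(x, band_grid(c(0.75, 1.5, 2.5, 3.5), 1),
                   band_grid(c(65, 85, 105, 125), 20))
cm
#> comodulogram: 4 x 4 cells, max MI 0.1244 at (1.5 Hz phase, 105 Hz amp)

dominant_frequency(welch_psd(x, window_s = 30), band_hfo_kx())$freq
#> [1] 104.7333
```

Every detected burst matches the generator's event table; the circular mean
burst phase (0.713 rad) recovers the configured lock phase (π/4 ≈ 0.785)
within the sampling error of 67 bursts; the comodulogram's hottest cell is
the configured (respiration 1.5 Hz, HFO 105 Hz) pair; and the dominant
frequency lands on the 105 Hz carrier to within one spectral bin.

The end-to-end driver runs simulate → spectra → bursts → coupling →
laminar (kCSD, MUA) → condition statistics and writes all intermediates
plus a manifest:

```r
res <- run_full_pipeline(system.file("config", "demo.json", package = "obhfo"),
                         out_dir = "demo_run", seed = 2)
res$report$reversal_depth_um   # laminar phase-reversal estimate
```

A thin command-line wrapper for simulation and the full run is installed at
`inst/cli/obhfo.R`:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli", "obhfo.R", package = "obhfo"))')" \
    run --config inst/config/demo.json --out demo_run --seed 2
```

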