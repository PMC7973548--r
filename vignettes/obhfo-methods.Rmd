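---
title: "Respiration-coupled high-frequency oscillations in laminar LFPs: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Respiration-coupled high-frequency oscillations in laminar LFPs: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Under ketamine-xylazine anesthesia the olfactory bulb produces a prominent
80-130 Hz rhythm (a ketamine-dependent high-frequency oscillation, HFO) that
rides on a respiration-tracking delta rhythm (0.3-3 Hz), while classical
30-65 Hz gamma power falls. The HFO appears as ~100 ms bursts nested at a
preferred phase of the delta cycle, reverses polarity across a laminar
current dipole near the mitral layer, and is driven by local multi-unit
spiking locked to the oscillation trough. `obhfo` implements the complete
analysis chain needed to quantify this phenomenology from multichannel LFP
recordings — and, because no public recordings accompany the phenomenon, a
laminar forward model that synthesizes recordings with every generative
parameter known, so each analysis stage can be validated against ground
truth.

## The forward model

`ground_truth()` + `generate_laminar_recording()` render, per channel $c$ at
depth $z_c$:

$$V_c(t) = w_\delta(z_c)\, s_\delta(t) + w_h(z_c)\,[s_{hfo}(t) + s_\gamma(t)]
  + \text{spikes}_c(t) + \varepsilon_c(t)$$

* **Respiration** is a phase oscillator: each cycle's period is lognormal
  with a configurable coefficient of variation (default 0.1), and the trace
  is the cosine of accumulated phase, trough = inhalation. A phase
  oscillator (rather than filtered noise) gives an exact ground-truth phase
  reference, which the ITPC/MI recovery tests require.
* **Delta source** $s_\delta$ follows the respiration phase lagged by
  `delta_phase_lag` (default $\pi$, so the delta peak falls at inhalation —
  matching the empirical observation that HFO bursts co-occur with delta
  peaks and thermocouple troughs).
* **HFO bursts** are Hann-windowed sinusoids (default 100 ms, 105 Hz with a
  $\pm 5$ Hz per-burst jitter, because the rhythm occupies a band, not a
  line). Burst counts per respiration cycle are Poisson with rate
  `burst_rate`; each burst's peak is placed at a delta phase drawn from a
  von Mises distribution with mean `lock_phase` (default $\pi/4$, the early
  descending phase) and concentration `coupling_kappa`. $\kappa = 0$
  reproduces uncoupled bursting; $\kappa \geq 4$ gives strong phase gating.
* **Dipoles**: each source projects through a difference of two Gaussians of
  opposite sign centred `halfwidth` above/below the dipole depth. The
  projection changes sign exactly at the dipole centre, giving the laminar
  phase reversal; it is a smooth, generic stand-in, not an anatomical claim.
  The continuous gamma tone shares the HFO (mitral-layer) dipole.
* **Spiking**: within bursts, spikes are drawn at von Mises-distributed
  phases of the burst's own cycle (mean `mua_lock_phase`, default $\pi$ =
  trough), at `mua_rate` (default 300 Hz) scaled per channel by the dipole
  weight magnitude, with a 1 ms absolute refractory floor — closer doublets
  would superimpose into a single waveform that no threshold detector could
  resolve, so the generator does not pretend they are separate events. Note
  the phase locking concentrates draws within each cycle, so the refractory
  floor leaves the realised rate noticeably below `mua_rate`; tests
  therefore bound the count rather than asserting the nominal product.
  Spikes are injected as brief negative-going biphasic transients
  (0.2 ms scale, 0.08 mV — a typical perisomatic multi-unit amplitude,
  about 15 dB above the high-band noise floor) so the >500 Hz detector can
  recover them. Spike analyses assume a sampling rate of at least 10 kHz,
  standard for extracellular spike work; at 2.5-5 kHz the transient is only
  1-2 samples wide and detection becomes marginal.
* **Noise**: per-channel white noise (0.01 mV) plus 1/f noise (0.02 mV)
  built by spectral shaping, with half of the 1/f power common across
  channels — LFPs share volume-conducted noise, and the common-mode term
  exercises the CSD's spatial filtering. The default burst SNR at the best
  channel is high (~20 dB); SNR is deliberately an exposed parameter, since
  no in-vivo value is available to pin it.

`generate_condition_pair()` renders the same seed twice with per-band
amplitudes scaled by $\sqrt{\text{multiplier}}$, so band powers differ by
exactly the stated factors — the machinery used to emulate drug contrasts
(gamma power down, HFO power up) when exercising the statistics.

All randomness flows from explicit integer seeds through an internal
splitter; identical inputs give bit-identical outputs, and no global RNG
state is touched.

## Spectral and analytic-signal operations

Band filtering is zero-phase (forward-backward) Butterworth, order 4 per
pass, so all phase statistics see undistorted timing. One practical
numerical point drove the implementation: a direct transfer-function
bandpass design for very low relative bands (0.3-3 Hz at 1 kHz) has poles
effectively on the unit circle and diverges in double precision. The filter
backend therefore probes each design with an impulse and falls back to an
equal-order high-pass + low-pass cascade when the direct bandpass is
unstable; the cascade is monotone and stable at all rates used here. For
narrow bands the direct form is stable and preserves the passband centre
within 5%.

The Welch estimator uses Hann windows with 50% overlap and one-sided
density scaling (`sum(power) * df` equals the variance). The default 60 s
window matches standard practice for stationary anesthesia recordings;
short inputs can opt into a single-segment estimate. `dominant_frequency()`
reports the argmax within a band (ties break toward the lower frequency)
and its in-bin power in mV². The analytic signal is computed by FFT
spectrum one-siding; envelope and phase follow.

Filter settling segments (3x the 99%-energy width of the impulse response)
are attached to filtered recordings as an `edge_s` attribute; the burst and
profile statistics operate far from edges at the durations used.

## Burst detection and coupling statistics

`detect_bursts()` thresholds the HFO-band Hilbert envelope at
mean + 3 SD of a baseline. The default baseline is the median/MAD robust
estimate over the whole trace, because bursts inflate a plain SD; a marked
quiet segment is available as an alternative. Runs shorter than 3
band-centre cycles are dropped and gaps shorter than 1 cycle merged —
cycle-based defaults consistent with ~100 ms bursts at ~105 Hz.

Burst-to-delta phase uses the literal time-rescaling definition: locate
delta peaks (local maxima separated by at least half the fastest delta
period), then map each burst peak to
$2\pi\,(t - t_{peak}) / T_{cycle}$, wrapped to $(-\pi, \pi]$ with the delta
peak at zero. An instantaneous Hilbert-phase mode is provided as an
alternative; on sinusoidal delta the two coincide. ITPC is the modulus of
the mean unit phasor of the burst phases.

The Tort modulation index bins phases into 18 equal bins, normalises the
per-bin mean amplitudes to a distribution $P$, and reports
$MI = (\log N - H(P))/\log N$ with natural logs (the ratio is base
invariant). If a bin is empty the binning is coarsened by halving the bin
count — with the recommended ≥ 10 cycles of the slowest phase frequency
this never triggers. `comodulogram()` evaluates MI over a (phase band x
amplitude band) grid, flagging overlapping band pairs invalid rather than
computing a meaningless self-coupling. The argmax cell recovers the
configured (respiration, HFO) pair on synthetic data.

`mi_resampling_test()` compares two groups of MI matrices cell-wise: the
observed statistic is the absolute difference of group means; the null
pools both groups' per-subject values and redraws pseudo-groups of the
original sizes with replacement (default 100,000 draws), with add-one
smoothing of the p-value. The resampling unit is the per-subject cell value
— subjects are exchangeable under the null, time points are not. No
multiple-comparison correction is applied across cells; this matches
per-band reporting practice and is stated rather than hidden.

## Laminar analyses

The depth power profile is the per-channel dominant-band power. Note a
difference-of-Gaussians dipole has lobes at roughly $\pm 1.4\times$ the
halfwidth from the centre; a channel grid coarser than the halfwidth
cannot show the inter-lobe minimum, so profile tests use 50 um spacing.

The phase-shift profile follows the maximum-correlation definition: per
burst window (default ±100 ms) and channel, the lag maximising the
cross-correlation with the reference channel within ± half a band-centre
cycle, converted to degrees via the band-centre period and averaged
circularly across bursts. Channels whose per-burst lags are inconsistent
(mean resultant < 0.5 — in practice channels with no dipole signal, i.e.
noise) are excluded from the reversal-depth estimate, which is the midpoint
of the largest adjacent jump in absolute phase. A Hilbert phase-difference
mode of reversal estimation is implicitly available through
`burst_delta_phase`-style analyses, but the lag-based route is the primary
one.

### Kernel CSD

`kcsd_reconstruct()` implements 1D kernel current-source-density
estimation: CSD is modelled as a sum of Gaussian basis sources (2x the
channel count, halfwidth = electrode spacing, grid overshooting the probe
by two basis widths); each basis source maps to electrode potentials
through a quasi-1D line-source integral with an assumed source radius of
500 um (the olfactory-bulb layer curvature scale, exposed as a parameter);
and the estimate is kernel ridge regression
$\hat C = K_{cross}(K + \lambda I)^{-1} V$ evaluated on a fine depth grid.
$\lambda$ is selected from a logarithmic grid ($10^{-6}$ to $1$, 10 points,
scaled by the kernel diagonal) by leave-one-electrode-out cross-validation
on potential prediction error — fully deterministic. Reconstruction is
linear at fixed $\lambda$, maps zero potentials to zero CSD, suppresses
depth-uniform (common-mode) offsets, and inverts its own forward model with
$r > 0.95$ and peak-depth error under one electrode spacing. A traditional
three-point second-difference CSD is included purely as an independent
cross-check. Band-filtering of CSD maps is done after reconstruction
(reconstruct-then-filter), each depth row zero-phase filtered in time.

### Multi-unit activity

`detect_mua()` high-passes at 500 Hz (upper edge = Nyquist), estimates a
robust noise SD (median/MAD), and takes negative-going crossings of 3
robust SDs (polarity configurable) with spike times at the local extremum
and a 1 ms dead time. At a 3 SD criterion the false-positive rate on pure
noise is set by the Rice upcrossing rate
$f_{eff} e^{-9/2}$ (tens per second for a multi-kilohertz band) — the
detector is a candidate extractor, as in standard MUA practice, not a
spike sorter; recall against ground truth, not precision, is the relevant
fidelity metric, and exceeds 0.9 at the default spike SNR.
`mua_hfo_correlation()` aggregates spike histograms (1 ms bins) across
burst-aligned windows, averages the band-filtered HFO waveform the same
way, and reports the per-channel Pearson correlation between the two:
trough-locked spiking yields $r < 0$ against the peak-positive waveform
convention.

## Condition statistics

`select_test()` implements a Shapiro-Wilk-gated test choice: all groups
normal (p ≥ 0.05) routes to paired t (paired/repeated designs) or one-way
ANOVA (independent); any group non-normal routes to the Wilcoxon
signed-rank (2 paired groups) or Friedman with Nemenyi post-hoc (≥ 3
repeated epochs). Two cases the gate description leaves open are resolved
as follows: normal repeated measures with ≥ 3 epochs use paired t against
the baseline epoch (consistent with common practice on n = 8 repeated
samples), and non-normal independent groups use the rank-sum Wilcoxon (2
groups) or Kruskal-Wallis (more). The Nemenyi post-hoc uses the
studentized-range formulation on within-block mean ranks,
$q = |\bar R_i - \bar R_j| / \sqrt{k(k+1)/(12n)}$ with
$p = P_{tukey}(q\sqrt 2; k, \infty)$. The degenerate all-tie design (every
subject identical across epochs) is reported as statistic 0, p = 1. No
correction is applied across metrics (gamma and HFO are reported per band).

Calibration is checked by simulation: with independent null epochs (equal
generator settings, different seeds) the paired design rejects at
5% ± 2% over 1000 reduced-size replicates (8 subjects, 8 s two-channel
recordings at 500 Hz — sizes chosen so the whole calibration runs in a few
minutes); with the HFO power multiplier at 4 the same design is significant
at $\alpha = 0.01$ in well over 90% of replicates.

## What the synthetic data do and do not show

The generator reproduces the statistical structure the analyses assume:
narrowband bursts with von Mises phase gating, sign-reversing laminar
projections, trough-locked point-process spiking, 1/f + white noise with a
common-mode share, and exact per-band power contrasts. It does not emulate
non-stationary drug onset dynamics, respiration-rate drift, movement or
line-noise artifacts, spatially heterogeneous noise, electrode drift, or
any biophysically detailed bulb circuitry. Passing the recovery suite
therefore demonstrates that the estimators are correct and well-calibrated
on data satisfying their assumptions — it does not certify performance on
recordings that violate them, and the robust-baseline and edge-exclusion
choices are mitigations, not guarantees.

## Numerical choices and degenerate inputs

* Filter order 4 per pass (8th-order magnitude after the double pass);
  stability decided empirically per design, as above.
* Welch: Hann, 50% overlap; the white-noise flatness check uses 5 s
  segments so enough segments average down the periodogram scatter.
* Burst detection on an all-constant envelope returns an empty table, not
  an error; zero signals propagate to zero spectra, zero profiles and zero
  CSD maps.
* Tie-breaks: dominant frequency takes the lowest tied bin; the
  cross-correlation lag takes the first maximum (most negative lag).
* `tort_mi` on all-zero amplitude returns 0 (uniform by convention).
* kCSD with a singular kernel and no positive $\lambda$ available fails
  with a message advising a nonzero grid; duplicate electrode depths are
  rejected.
* Problem sizes in the test-suite: 60 s / 1 kHz / 16 channels for coupling
  and laminar recovery, 300 s for the strong-coupling recovery and MI
  monotonicity, 30 s / 10 kHz for spike analyses, 1000 small replicates
  for the type-I calibration — sizes at which every stochastic check has
  comfortable margin while the suite stays quick.

## Known limitations

* The kCSD variant is 1D; it attributes all spatial structure to depth and
  assumes a fixed source radius. 2D/3D variants are out of scope.
* The phase-shift-to-degrees conversion uses the band-centre period;
  signals far from the band centre acquire a proportional bias (the
  reversal location, a sign flip, is unaffected).
* The resampling test validates against synthetic groups only; no claim is
  made about any specific in-vivo contrast.
* MUA analysis extracts threshold candidates without sorting; precision at
  3 SD is intentionally low and burst-triggered averaging carries the
  inferential weight.
* In-vivo numerical values (band frequencies/powers under specific drugs)
  derive from recordings that are not available; the package reproduces
  the analysis machinery and its ground-truth recovery, not those numbers.
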