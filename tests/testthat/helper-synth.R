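# Shared small fixtures, generated in code and cached per test run.

.fixtures <- new.env(parent = emptyenv())

# 60 s, 16-channel, 1 kHz simulation with moderate coupling (no spiking;
# spike fixtures are built separately at a higher sampling rate).
fixture_sim <- function() {
  if (is.null(.fixtures$sim)) {
    gt <- ground_truth(seed = 42L, fs = 1000, duration = 60,
                       coupling_kappa = 8, mua_rate = 0)
    .fixtures$sim <- generate_laminar_recording(gt, probe_geometry(16, 200, 100))
  }
  .fixtures$sim
}

# 30 s, 10 kHz simulation with spiking, for MUA analyses.
fixture_sim_mua <- function() {
  if (is.null(.fixtures$sim_mua)) {
    gt <- ground_truth(seed = 7L, fs = 10000, duration = 30,
                       coupling_kappa = 4)
    .fixtures$sim_mua <- generate_laminar_recording(gt, probe_geometry(16, 200, 100))
  }
  .fixtures$sim_mua
}

# 300 s strongly coupled recording for the coupling-recovery checks.
fixture_sim_long <- function() {
  if (is.null(.fixtures$sim_long)) {
    gt <- ground_truth(seed = 3L, fs = 1000, duration = 300,
                       coupling_kappa = 8, mua_rate = 0)
    .fixtures$sim_long <- generate_laminar_recording(gt, probe_geometry(8, 400, 100))
  }
  .fixtures$sim_long
}

# HFO-band dominant power of a small two-channel simulation; the working
# unit of the condition-statistics calibration checks.
small_band_power <- function(seed, hfo_amp = 0.1) {
  gt <- ground_truth(seed = seed, fs = 500, duration = 8, coupling_kappa = 4,
                     mua_rate = 0, hfo_amp = hfo_amp)
  sim <- generate_laminar_recording(gt, probe_geometry(2, 1600, 1000), seed = seed)
  x <- sim$lfp$samples[sim$reference_channel, ]
  dominant_frequency(welch_psd(x, 500, window_s = 4), band_hfo_kx())$power
}

ref_channel_trace <- function(sim) {
  recording(sim$lfp$samples[sim$reference_channel, ], sim$lfp$fs)
}

# Independent brute-force Tort MI oracle: explicit loop binning and the
# direct KL-divergence formula (kept free of the package's tort_mi path).
tort_mi_oracle <- function(phase, amplitude, n_bins = 18L) {
  phase <- ((phase + pi) %% (2 * pi)) - pi
  phase[phase == -pi] <- pi
  width <- 2 * pi / n_bins
  means <- numeric(n_bins)
  for (j in seq_len(n_bins)) {
    lo <- -pi + (j - 1) * width
    hi <- if (j == n_bins) pi else lo + width   # exact closing edge
    inbin <- phase > lo & phase <= hi
    if (!any(inbin)) stop("oracle: empty bin")
    means[j] <- mean(amplitude[inbin])
  }
  p <- means / sum(means)
  kl <- sum(p[p > 0] * log(p[p > 0] * n_bins))
  kl / log(n_bins)
}

# Match detected event times to truth within a tolerance; returns precision
# and recall.
match_events <- function(detected, truth, tol_s) {
  if (length(truth) == 0L) return(list(precision = NA, recall = NA))
  recall <- mean(vapply(truth, function(s) any(abs(detected - s) <= tol_s), TRUE))
  precision <- if (length(detected) == 0L) NA_real_ else
    mean(vapply(detected, function(s) any(abs(truth - s) <= tol_s), TRUE))
  list(precision = precision, recall = recall)
}
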