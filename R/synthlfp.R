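#' Ground-truth parameter set for the laminar LFP forward model
#'
#' Collects every generative parameter of a synthetic olfactory-bulb
#' recording: a respiration-locked delta dipole, respiration-gated
#' high-frequency-oscillation (HFO) bursts arising from a second dipole, a
#' continuous gamma source sharing the HFO dipole, phase-locked multi-unit
#' spiking, and 1/f + white channel noise. The returned object is the single
#' source of truth against which every analysis stage can be validated.
#'
#' Phase conventions: respiration is `cos(phi)` with the trough (phi = pi)
#' marking inhalation; the LFP delta source lags respiration by
#' `delta_phase_lag` (default pi, putting the delta peak at inhalation, where
#' HFO bursts cluster). `lock_phase` is the delta phase (peak = 0, increasing
#' with time) of maximal burst probability. `mua_lock_phase` is the HFO-cycle
#' phase of spiking with the oscillation peak at 0, so the default pi locks
#' spikes to the trough.
#'
#' @param seed integer seed; all generator randomness derives from it.
#' @param fs sampling rate in Hz (must exceed `2 * f_hfo`).
#' @param duration recording length in seconds.
#' @param f_resp respiration rate in Hz.
#' @param f_hfo HFO carrier frequency in Hz (band 80-130).
#' @param f_gamma gamma frequency in Hz (band 30-65).
#' @param burst_rate mean HFO burst rate in bursts/s.
#' @param burst_duration burst length in seconds (~100 ms bursts).
#' @param burst_freq_jitter per-burst carrier jitter half-range in Hz.
#' @param coupling_kappa von Mises concentration of burst-phase gating
#'   (0 = no respiration coupling).
#' @param lock_phase delta phase of maximal burst probability, radians.
#' @param hfo_dipole_depth,hfo_dipole_halfwidth HFO dipole centre and lobe
#'   half-separation in micrometres (mitral-layer generator).
#' @param delta_dipole_depth,delta_dipole_halfwidth delta dipole centre and
#'   half-separation in micrometres.
#' @param delta_phase_lag phase lag of the LFP delta source behind the
#'   respiration trace, radians.
#' @param mua_lock_phase HFO phase of spiking, radians (pi = trough).
#' @param mua_kappa von Mises concentration of spike phase locking.
#' @param mua_rate within-burst multi-unit rate in Hz at the best channel
#'   (0 disables spiking).
#' @param mua_min_isi minimum inter-spike separation per channel in seconds
#'   (default 1 ms, the spike transient width): closer doublets would
#'   superimpose into a single unresolvable waveform.
#' @param delta_amp,hfo_amp,gamma_amp,spike_amp source amplitudes in mV.
#' @param noise_white_sd,noise_pink_scale white / 1-over-f noise levels in mV.
#' @param resp_jitter_cv coefficient of variation of respiration cycle length.
#' @param condition_scalers named per-band power multipliers used by
#'   [generate_condition_pair()].
#' @return an object of class `ground_truth`.
#' @export
ground_truth <- function(seed = 1L, fs = 1000, duration = 60,
                         f_resp = 1.5, f_hfo = 105, f_gamma = 50,
                         burst_rate = 1.5, burst_duration = 0.1,
                         burst_freq_jitter = 5,
                         coupling_kappa = 4, lock_phase = pi / 4,
                         hfo_dipole_depth = 1600, hfo_dipole_halfwidth = 200,
                         delta_dipole_depth = 2400, delta_dipole_halfwidth = 400,
                         delta_phase_lag = pi,
                         mua_lock_phase = pi, mua_kappa = 4, mua_rate = 300,
                         mua_min_isi = 1e-3,
                         delta_amp = 0.5, hfo_amp = 0.1, gamma_amp = 0.05,
                         spike_amp = 0.08,
                         noise_white_sd = 0.01, noise_pink_scale = 0.02,
                         resp_jitter_cv = 0.1,
                         condition_scalers = c(delta = 1, gamma = 1, hfo = 1)) {
  check_positive(fs, "fs"); check_positive(duration, "duration")
  check_positive(f_resp, "f_resp"); check_positive(f_hfo, "f_hfo")
  if (fs <= 2 * f_hfo)
    stop_param(sprintf("fs (%g) must exceed 2*f_hfo (%g): aliasing", fs, 2 * f_hfo))
  if (burst_rate < 0 || burst_duration <= 0)
    stop_param("burst_rate must be >= 0 and burst_duration > 0")
  if (burst_rate * burst_duration >= 1)
    stop_param("burst_rate * burst_duration must be < 1 (bursts would tile the trace)")
  if (coupling_kappa < 0) stop_param("coupling_kappa must be >= 0")
  if (mua_rate < 0) stop_param("mua_rate must be >= 0")
  structure(list(seed = as.integer(seed), fs = fs, duration = duration,
                 f_resp = f_resp, f_hfo = f_hfo, f_gamma = f_gamma,
                 burst_rate = burst_rate, burst_duration = burst_duration,
                 burst_freq_jitter = burst_freq_jitter,
                 coupling_kappa = coupling_kappa, lock_phase = lock_phase,
                 hfo_dipole_depth = hfo_dipole_depth,
                 hfo_dipole_halfwidth = hfo_dipole_halfwidth,
                 delta_dipole_depth = delta_dipole_depth,
                 delta_dipole_halfwidth = delta_dipole_halfwidth,
                 delta_phase_lag = delta_phase_lag,
                 mua_lock_phase = mua_lock_phase, mua_kappa = mua_kappa,
                 mua_rate = mua_rate, mua_min_isi = mua_min_isi,
                 delta_amp = delta_amp, hfo_amp = hfo_amp,
                 gamma_amp = gamma_amp, spike_amp = spike_amp,
                 noise_white_sd = noise_white_sd,
                 noise_pink_scale = noise_pink_scale,
                 resp_jitter_cv = resp_jitter_cv,
                 condition_scalers = condition_scalers),
            class = "ground_truth")
}

#' @export
print.ground_truth <- function(x, ...) {
  cat(sprintf(paste0("ground_truth: %gs at %g Hz | resp %g Hz, HFO %g Hz ",
                     "(rate %g/s, kappa %g, lock %.2f rad), seed %d\n"),
              x$duration, x$fs, x$f_resp, x$f_hfo, x$burst_rate,
              x$coupling_kappa, x$lock_phase, x$seed))
  invisible(x)
}

# Difference-of-Gaussians dipole weight over channel depths, normalised to
# unit peak magnitude; sign flips exactly at `center`.
dipole_weight <- function(depths_um, center, halfwidth) {
  w <- exp(-(depths_um - (center - halfwidth))^2 / (2 * halfwidth^2)) -
       exp(-(depths_um - (center + halfwidth))^2 / (2 * halfwidth^2))
  w / max(abs(w))
}

#' Synthesize a respiration trace
#'
#' Phase-oscillator model: each cycle has a lognormally jittered period with
#' the requested coefficient of variation, and the waveform is the cosine of
#' the accumulated phase. The trough of the trace marks inhalation. The exact
#' phase time series and cycle boundaries are attached as attributes
#' `"phase"` and `"cycle_bounds"` so coupling analyses can be validated
#' against ground truth.
#'
#' @param duration length in seconds (> 0).
#' @param fs sampling rate in Hz (>= 100).
#' @param f_resp mean respiration rate in Hz.
#' @param cycle_jitter_cv per-cycle period coefficient of variation in [0, 0.5).
#' @param seed integer seed.
#' @return a single-channel [recording()].
#' @export
generate_respiration <- function(duration, fs, f_resp = 1.5,
                                 cycle_jitter_cv = 0.1, seed = 1L) {
  check_positive(duration, "duration")
  check_positive(fs, "fs")
  if (fs < 100) stop_param("fs must be >= 100 Hz for a respiration trace")
  check_positive(f_resp, "f_resp")
  if (cycle_jitter_cv < 0 || cycle_jitter_cv >= 0.5)
    stop_param("cycle_jitter_cv must be in [0, 0.5)")
  n <- round(duration * fs)
  t <- (seq_len(n) - 1) / fs
  if (cycle_jitter_cv == 0) {
    phase <- 2 * pi * f_resp * t
    bounds <- seq(0, duration + 1 / f_resp, by = 1 / f_resp)
  } else {
    bounds <- with_seed(seed, {
      sdlog <- sqrt(log(1 + cycle_jitter_cv^2))
      meanlog <- log(1 / f_resp) - sdlog^2 / 2
      periods <- stats::rlnorm(ceiling(duration * f_resp * 2) + 10L,
                               meanlog, sdlog)
      while (sum(periods) < duration)
        periods <- c(periods, stats::rlnorm(5L, meanlog, sdlog))
      c(0, cumsum(periods))
    })
    periods <- diff(bounds)
    cyc <- findInterval(t, bounds, rightmost.closed = FALSE)
    phase <- 2 * pi * (cyc - 1 + (t - bounds[cyc]) / periods[cyc])
  }
  rec <- recording(cos(phase), fs, units = "a.u.",
                   channel_labels = "respiration")
  attr(rec, "phase") <- phase
  attr(rec, "cycle_bounds") <- bounds
  rec
}

#' Synthesize a laminar LFP recording with known ground truth
#'
#' Forward model: each channel is the sum of (i) a delta source following the
#' respiration phase, projected through a difference-of-Gaussians dipole
#' (phase reversal at the dipole centre), (ii) Hann-windowed HFO bursts whose
#' per-cycle timing is gated by a von Mises distribution over delta phase,
#' projected through a second dipole, (iii) a continuous gamma tone sharing
#' the HFO dipole, (iv) optional spike transients, and (v) white plus 1/f
#' noise with a 50% common-mode share.
#'
#' @param gt a [ground_truth()].
#' @param geometry a [probe_geometry()].
#' @param seed integer seed; defaults to `gt$seed`.
#' @return a list of class `synth_lfp` with elements `lfp` (multichannel
#'   [recording()]), `respiration` (single-channel [recording()]), `bursts`
#'   (true-event table with columns `onset_s`, `offset_s`, `peak_s`,
#'   `peak_env_mv`, `channel`, `kind`, `freq_hz`, `delta_phase`), `spikes`
#'   (per-channel spike time list or `NULL`), `weights` (dipole projection
#'   weights), and `ground_truth`.
#' @export
generate_laminar_recording <- function(gt, geometry = probe_geometry(),
                                       seed = gt$seed) {
  stopifnot(inherits(gt, "ground_truth"), inherits(geometry, "probe_geometry"))
  depths <- geometry$depths_um
  span <- range(depths)
  for (d in c(hfo = gt$hfo_dipole_depth, delta = gt$delta_dipole_depth))
    if (d < span[1] || d > span[2])
      stop_param(sprintf("dipole depth %g um outside probe span %g-%g um",
                         d, span[1], span[2]))
  fs <- gt$fs
  n <- round(gt$duration * fs)
  t <- (seq_len(n) - 1) / fs

  resp <- generate_respiration(gt$duration, fs, gt$f_resp, gt$resp_jitter_cv,
                               seed = derive_seed(seed, 11L))
  phi <- attr(resp, "phase")
  bounds <- attr(resp, "cycle_bounds")
  psi <- phi - gt$delta_phase_lag          # delta phase, peak = 0
  delta_src <- gt$delta_amp * cos(psi)

  bursts <- with_seed(derive_seed(seed, 23L), {
    periods <- diff(bounds)
    out <- list()
    for (j in seq_along(periods)) {
      nb <- stats::rpois(1L, gt$burst_rate * periods[j])
      if (nb == 0L) next
      ph <- rvonmises(nb, gt$lock_phase, gt$coupling_kappa)
      frac <- ((ph + gt$delta_phase_lag) / (2 * pi)) %% 1
      peak <- bounds[j] + periods[j] * frac
      out[[length(out) + 1L]] <- data.frame(peak_s = peak, delta_phase = ph)
    }
    if (length(out) == 0L) {
      data.frame(peak_s = numeric(0), delta_phase = numeric(0),
                 freq_hz = numeric(0))
    } else {
      b <- do.call(rbind, out)
      b <- b[order(b$peak_s), , drop = FALSE]
      b$freq_hz <- gt$f_hfo + stats::runif(nrow(b), -gt$burst_freq_jitter,
                                           gt$burst_freq_jitter)
      b
    }
  })
  if (nrow(bursts)) {
    bursts$onset_s <- bursts$peak_s - gt$burst_duration / 2
    bursts$offset_s <- bursts$peak_s + gt$burst_duration / 2
    keep <- bursts$onset_s > 0 & bursts$offset_s < gt$duration
    bursts <- bursts[keep, , drop = FALSE]
    # drop overlapping bursts, keeping the earlier one
    if (nrow(bursts) > 1) {
      keep <- rep(TRUE, nrow(bursts))
      last_off <- -Inf
      for (i in seq_len(nrow(bursts))) {
        if (bursts$onset_s[i] < last_off) keep[i] <- FALSE
        else last_off <- bursts$offset_s[i]
      }
      bursts <- bursts[keep, , drop = FALSE]
    }
  }

  hfo_src <- numeric(n)
  if (nrow(bursts)) {
    half <- gt$burst_duration / 2
    for (i in seq_len(nrow(bursts))) {
      i0 <- max(1L, floor(bursts$onset_s[i] * fs) + 1L)
      i1 <- min(n, ceiling(bursts$offset_s[i] * fs) + 1L)
      tt <- t[i0:i1] - bursts$peak_s[i]
      w <- ifelse(abs(tt) <= half, cos(pi * tt / gt$burst_duration)^2, 0)
      hfo_src[i0:i1] <- hfo_src[i0:i1] +
        gt$hfo_amp * w * cos(2 * pi * bursts$freq_hz[i] * tt)
    }
  }

  gamma_src <- with_seed(derive_seed(seed, 31L),
    gt$gamma_amp * cos(2 * pi * gt$f_gamma * t + stats::runif(1, 0, 2 * pi)))

  w_delta <- dipole_weight(depths, gt$delta_dipole_depth, gt$delta_dipole_halfwidth)
  w_hfo <- dipole_weight(depths, gt$hfo_dipole_depth, gt$hfo_dipole_halfwidth)

  samples <- outer(w_delta, delta_src) + outer(w_hfo, hfo_src + gamma_src)

  if (gt$noise_white_sd > 0 || gt$noise_pink_scale > 0) {
    samples <- samples + with_seed(derive_seed(seed, 47L), {
      nz <- matrix(0, nrow(samples), n)
      common <- if (gt$noise_pink_scale > 0) pink_noise(n) else numeric(n)
      for (ch in seq_len(nrow(samples))) {
        v <- stats::rnorm(n, sd = gt$noise_white_sd)
        if (gt$noise_pink_scale > 0)
          v <- v + gt$noise_pink_scale * (common + pink_noise(n)) / sqrt(2)
        nz[ch, ] <- v
      }
      nz
    })
  }

  ref_ch <- which.max(abs(w_hfo))
  spikes <- NULL
  if (gt$mua_rate > 0 && nrow(bursts)) {
    spikes <- generate_mua(bursts, gt, fs, channel_weights = abs(w_hfo),
                           seed = derive_seed(seed, 59L))
    samples <- inject_spikes(samples, spikes, fs, gt$spike_amp)
  }

  if (nrow(bursts)) {
    bursts <- data.frame(onset_s = bursts$onset_s, offset_s = bursts$offset_s,
                         peak_s = bursts$peak_s,
                         peak_env_mv = gt$hfo_amp * max(abs(w_hfo)),
                         channel = ref_ch, kind = "hfo",
                         freq_hz = bursts$freq_hz,
                         delta_phase = wrap_pi(bursts$delta_phase))
  } else {
    bursts <- data.frame(onset_s = numeric(0), offset_s = numeric(0),
                         peak_s = numeric(0), peak_env_mv = numeric(0),
                         channel = integer(0), kind = character(0),
                         freq_hz = numeric(0), delta_phase = numeric(0))
  }

  structure(list(lfp = recording(samples, fs, geometry = geometry),
                 respiration = resp, bursts = bursts, spikes = spikes,
                 weights = list(delta = w_delta, hfo = w_hfo),
                 reference_channel = ref_ch,
                 ground_truth = gt),
            class = "synth_lfp")
}

#' @export
print.synth_lfp <- function(x, ...) {
  cat(sprintf("synth_lfp: %d channels, %g s, %d true bursts, %s spikes\n",
              nrow(x$lfp$samples), rec_duration(x$lfp), nrow(x$bursts),
              if (is.null(x$spikes)) "no" else
                format(sum(lengths(x$spikes)))))
  invisible(x)
}

#' Draw phase-locked multi-unit spikes for a set of HFO bursts
#'
#' Within each burst, spike counts are Poisson with rate
#' `mua_rate * channel_weight`, and spike times sit at von Mises-distributed
#' phases of the burst's own HFO cycle (peak = 0; the default lock phase pi
#' targets the trough).
#'
#' @param true_bursts burst table with `onset_s`, `offset_s`, `peak_s` and
#'   `freq_hz` columns (as emitted by [generate_laminar_recording()]).
#' @param gt a [ground_truth()].
#' @param fs sampling rate in Hz (used only for time rounding of transients).
#' @param channel_weights per-channel rate multipliers in [0, 1]; length
#'   defines the number of channels.
#' @param seed integer seed.
#' @return list of sorted spike-time vectors, one per channel.
#' @export
generate_mua <- function(true_bursts, gt, fs = gt$fs, channel_weights = 1,
                         seed = gt$seed) {
  if (gt$mua_rate < 0) stop_param("mua_rate must be >= 0")
  n_ch <- length(channel_weights)
  if (gt$mua_rate == 0 || nrow(true_bursts) == 0L)
    return(rep(list(numeric(0)), n_ch))
  freq <- if ("freq_hz" %in% names(true_bursts)) true_bursts$freq_hz
          else rep(gt$f_hfo, nrow(true_bursts))
  with_seed(seed, {
    lapply(seq_len(n_ch), function(ch) {
      rate <- gt$mua_rate * channel_weights[ch]
      if (rate <= 0) return(numeric(0))
      out <- numeric(0)
      for (i in seq_len(nrow(true_bursts))) {
        dur <- true_bursts$offset_s[i] - true_bursts$onset_s[i]
        k <- stats::rpois(1L, rate * dur)
        if (k == 0L) next
        th <- rvonmises(k, gt$mua_lock_phase, gt$mua_kappa)
        fb <- freq[i]
        m_min <- ceiling((true_bursts$onset_s[i] - true_bursts$peak_s[i]) * fb -
                         th / (2 * pi))
        m_max <- floor((true_bursts$offset_s[i] - true_bursts$peak_s[i]) * fb -
                       th / (2 * pi))
        ok <- m_max >= m_min
        if (!any(ok)) next
        m <- m_min[ok] + floor(stats::runif(sum(ok)) * (m_max[ok] - m_min[ok] + 1))
        out <- c(out, true_bursts$peak_s[i] + (m + th[ok] / (2 * pi)) / fb)
      }
      out <- sort(out)
      # absolute refractory floor: unresolvable doublets collapse to one
      # event; drop a random member so the surviving phase is unbiased
      min_isi <- if (is.null(gt$mua_min_isi)) 1e-3 else gt$mua_min_isi
      repeat {
        v <- which(diff(out) < min_isi)
        if (length(v) == 0L) break
        j <- v[1] + (stats::runif(1) < 0.5)
        out <- out[-j]
      }
      out
    })
  })
}

# Add brief biphasic (Mexican-hat, negative main lobe) transients at spike
# times; energy concentrated above 500 Hz so the MUA detector can recover them.
inject_spikes <- function(samples, spikes, fs, amp, width_s = 2e-4) {
  n <- ncol(samples)
  hw <- max(3L, round(5 * width_s * fs))
  k <- (-hw):hw
  tt <- k / fs
  pulse <- -(1 - (tt / width_s)^2) * exp(-tt^2 / (2 * width_s^2))
  for (ch in seq_along(spikes)) {
    for (s in spikes[[ch]]) {
      i0 <- round(s * fs) + 1L
      idx <- i0 + k
      ok <- idx >= 1L & idx <= n
      samples[ch, idx[ok]] <- samples[ch, idx[ok]] + amp * pulse[ok]
    }
  }
  samples
}

#' Generate a matched two-condition recording pair
#'
#' Renders the same seeded forward model twice, with per-band source
#' amplitudes of the second recording scaled by the square root of the stated
#' power multipliers, so measured band powers differ by exactly the
#' multipliers while every random draw is shared. This emulates drug-contrast
#' experiments (gamma power down, HFO power up) for exercising the condition
#' statistics.
#'
#' @param gt a [ground_truth()].
#' @param scalers named power multipliers for `delta`, `gamma`, `hfo`
#'   (all > 0); defaults to `gt$condition_scalers`.
#' @param geometry a [probe_geometry()].
#' @param seed integer seed; defaults to `gt$seed`.
#' @return list with elements `a` and `b`, each a `synth_lfp`.
#' @export
generate_condition_pair <- function(gt, scalers = gt$condition_scalers,
                                    geometry = probe_geometry(), seed = gt$seed) {
  sc <- c(delta = 1, gamma = 1, hfo = 1)
  sc[names(scalers)] <- unlist(scalers)
  if (any(sc <= 0)) stop_param("all condition scalers must be > 0")
  gt_b <- gt
  gt_b$delta_amp <- gt$delta_amp * sqrt(sc[["delta"]])
  gt_b$gamma_amp <- gt$gamma_amp * sqrt(sc[["gamma"]])
  gt_b$hfo_amp <- gt$hfo_amp * sqrt(sc[["hfo"]])
  list(a = generate_laminar_recording(gt, geometry, seed = seed),
       b = generate_laminar_recording(gt_b, geometry, seed = seed))
}
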