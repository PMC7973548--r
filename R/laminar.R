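#' Depth profile of dominant-band power
#'
#' Per-channel Welch spectrum reduced to the dominant frequency and its power
#' inside the band: the laminar power profile whose sharp minimum marks the
#' generating dipole (power drops at the mitral layer for the KX HFO).
#'
#' @param rec multichannel [recording()] with geometry.
#' @param band a [band_spec()].
#' @param window_s Welch window in seconds (defaults to the whole recording
#'   when shorter than 60 s).
#' @return data frame of class `depth_profile`: `channel`, `depth_um`,
#'   `freq_hz`, `value` (power, mV^2), plus a `kind` attribute.
#' @export
depth_power_profile <- function(rec, band, window_s = min(60, rec_duration(rec))) {
  stopifnot(inherits(rec, "ob_recording"))
  if (is.null(rec$geometry)) stop_param("recording has no channel depths")
  n_ch <- nrow(rec$samples)
  if (n_ch < 2L) stop_param("need >= 2 channels for a depth profile")
  res <- lapply(seq_len(n_ch), function(ch) {
    p <- welch_psd(rec$samples[ch, ], rec$fs, window_s = window_s,
                   allow_short = TRUE)
    d <- dominant_frequency(p, band)
    c(freq_hz = d$freq, value = d$power)
  })
  out <- data.frame(channel = seq_len(n_ch),
                    depth_um = rec$geometry$depths_um,
                    do.call(rbind, res))
  attr(out, "kind") <- "power"
  class(out) <- c("depth_profile", "data.frame")
  out
}

#' Inter-channel phase shift of band-limited bursts
#'
#' For each burst window (default +/- 100 ms around the burst peak) and each
#' channel, the lag maximising the cross-correlation with the reference
#' channel is found within +/- half a band-centre cycle, converted to degrees
#' via the band-centre period, and averaged circularly across bursts. A step
#' from ~0 deg to ~180 deg along the probe marks the dipole phase reversal.
#'
#' @param rec multichannel [recording()] (raw; filtering applied internally).
#' @param band a [band_spec()].
#' @param reference_channel index of the reference contact.
#' @param bursts a `burst_events` table (at least one row).
#' @param window_s half-window around each burst peak in seconds.
#' @param order filter order.
#' @return data frame of class `depth_profile` with `value` = phase shift in
#'   degrees (NA for silent channels).
#' @export
interchannel_phase_shift <- function(rec, band, reference_channel, bursts,
                                     window_s = 0.1, order = 4L) {
  stopifnot(inherits(rec, "ob_recording"))
  n_ch <- nrow(rec$samples)
  if (reference_channel < 1 || reference_channel > n_ch)
    stop_param("reference channel outside the channel range")
  if (nrow(bursts) == 0L) stop_param("need at least one burst window")
  fs <- rec$fs
  fc <- (band$lo + min(band$hi, fs / 2)) / 2
  max_lag <- max(1L, round(fs / (2 * fc)))  # half a band-centre cycle each way
  filt <- bandpass(rec, band, order = order)
  n <- ncol(rec$samples)
  hw <- round(window_s * fs)
  lags_deg <- matrix(NA_real_, n_ch, nrow(bursts))
  for (b in seq_len(nrow(bursts))) {
    c0 <- round(bursts$peak_s[b] * fs) + 1L
    idx <- max(1L, c0 - hw):min(n, c0 + hw)
    if (length(idx) < 2L * max_lag + 8L) next
    ref <- filt$samples[reference_channel, idx]
    if (stats::sd(ref) == 0) next
    for (ch in seq_len(n_ch)) {
      x <- filt$samples[ch, idx]
      if (stats::sd(x) == 0) next
      cc <- vapply(-max_lag:max_lag, function(l) {
        if (l >= 0)
          stats::cor(ref[1:(length(ref) - l)], x[(1 + l):length(x)])
        else
          stats::cor(ref[(1 - l):length(ref)], x[1:(length(x) + l)])
      }, numeric(1))
      lag <- ((-max_lag:max_lag)[which.max(cc)]) / fs
      sgn <- if (max(cc) >= 0) 0 else 180  # anti-correlated: half-cycle flip
      lags_deg[ch, b] <- 360 * fc * lag + sgn
    }
  }
  val <- apply(lags_deg, 1L, function(v) {
    v <- v[is.finite(v)]
    if (length(v) == 0L) return(NA_real_)
    circ_mean(v * pi / 180) * 180 / pi
  })
  # consistency of the per-burst lags: low resultant marks noise channels
  consis <- apply(lags_deg, 1L, function(v) {
    v <- v[is.finite(v)]
    if (length(v) == 0L) return(NA_real_)
    circ_r(v * pi / 180)
  })
  out <- data.frame(channel = seq_len(n_ch),
                    depth_um = if (is.null(rec$geometry)) NA_real_
                               else rec$geometry$depths_um,
                    value = val, resultant = consis)
  attr(out, "kind") <- "phase_deg"
  class(out) <- c("depth_profile", "data.frame")
  out
}

#' Estimate the phase-reversal depth from a phase-shift profile
#'
#' Midpoint of the adjacent channel pair with the largest jump in absolute
#' phase shift (towards 180 deg). Channels whose per-burst lags are
#' inconsistent (mean resultant < `min_resultant`; pure-noise channels far
#' from the generator) are excluded first.
#'
#' @param profile a phase `depth_profile` from [interchannel_phase_shift()].
#' @param min_resultant consistency floor for including a channel.
#' @return depth in micrometres.
#' @export
reversal_depth <- function(profile, min_resultant = 0.5) {
  v <- circ_dist(profile$value * pi / 180, 0) * 180 / pi
  d <- profile$depth_um
  ok <- is.finite(v)
  if (!is.null(profile$resultant))
    ok <- ok & !is.na(profile$resultant) & profile$resultant >= min_resultant
  v <- v[ok]; d <- d[ok]
  if (length(v) < 2L) stop_param("too few consistent channels for a reversal estimate")
  jump <- abs(diff(v))
  i <- which.max(jump)
  (d[i] + d[i + 1]) / 2
}

# ---------------------------------------------------------------------------
# 1D kernel current source density
# ---------------------------------------------------------------------------

# Forward potential of a unit Gaussian source at centre z0 (width w) measured
# at electrode depth x, under a quasi-1D volume conductor with assumed source
# radius R: phi(x) = 1/(2 sigma) * Int g(z) (sqrt((x-z)^2 + R^2) - |x-z|) dz.
# Quadrature on a grid of step w/8 spanning +/- 5 w.
kcsd_forward_phi <- function(x, z0, w, R, sigma = 1) {
  z <- seq(z0 - 5 * w, z0 + 5 * w, by = w / 8)
  g <- exp(-(z - z0)^2 / (2 * w^2))
  dz <- z[2] - z[1]
  vapply(x, function(xi) {
    sum(g * (sqrt((xi - z)^2 + R^2) - abs(xi - z))) * dz / (2 * sigma)
  }, numeric(1))
}

#' 1D kernel current-source-density reconstruction
#'
#' Models the laminar CSD as a sum of Gaussian basis sources on a grid
#' spanning (and slightly overshooting) the probe, maps each basis source to
#' electrode potentials through a quasi-1D line-source forward integral with
#' a fixed assumed source radius, and inverts with kernel ridge regression:
#' `CSD = K_cross (K + lambda I)^-1 V`, evaluated on a fine depth grid.
#' The regularisation weight is chosen from `lambda_grid` by deterministic
#' leave-one-electrode-out cross-validation on potential prediction error.
#'
#' @param snapshot multichannel [recording()] window (>= 4 channels with
#'   strictly monotone depths).
#' @param basis_count number of basis sources (default 2x channels).
#' @param basis_halfwidth_um Gaussian basis width, default = electrode
#'   spacing.
#' @param lambda_grid candidate ridge weights, or a single fixed value to
#'   skip cross-validation.
#' @param source_radius_um assumed cylindrical source radius of the forward
#'   integral (default 500 um, the olfactory-bulb layer curvature scale).
#' @param n_estm fine depth-grid points for evaluation.
#' @return object of class `csd_map`: `depths_um`, `times_s`, `csd`
#'   (depth x time, a.u. proportional to uA/mm^3), `lambda`, `cv_error`,
#'   `basis` parameters.
#' @export
kcsd_reconstruct <- function(snapshot,
                             basis_count = 2L * nrow(snapshot$samples),
                             basis_halfwidth_um = NULL,
                             lambda_grid = 10^seq(-6, 0, length.out = 10),
                             source_radius_um = 500,
                             n_estm = 200L) {
  stopifnot(inherits(snapshot, "ob_recording"))
  if (is.null(snapshot$geometry)) stop_param("snapshot needs channel depths")
  x <- snapshot$geometry$depths_um
  if (length(x) < 4L) stop_param("kCSD needs >= 4 channels")
  if (anyDuplicated(x)) stop_param("duplicate electrode depths")
  if (is.unsorted(x, strictly = TRUE)) stop_param("depths must be strictly monotone")
  if (any(lambda_grid < 0)) stop_param("lambda must be >= 0")
  w <- if (is.null(basis_halfwidth_um)) x[2] - x[1] else basis_halfwidth_um
  V <- snapshot$samples
  n_el <- length(x)
  zb <- seq(min(x) - 2 * w, max(x) + 2 * w, length.out = basis_count)
  z_est <- seq(min(x) - 2 * w, max(x) + 2 * w, length.out = n_estm)

  # Phi[b, i]: potential of basis b at electrode i; G[b, f]: basis CSD on grid
  Phi <- t(vapply(zb, function(z0) kcsd_forward_phi(x, z0, w, source_radius_um),
                  numeric(n_el)))
  G <- t(vapply(zb, function(z0) exp(-(z_est - z0)^2 / (2 * w^2)),
                numeric(length(z_est))))
  K <- crossprod(Phi)          # n_el x n_el
  Kt <- t(G) %*% Phi           # n_estm x n_el
  scale_k <- mean(diag(K))     # lambda on the scale of the kernel diagonal

  solve_lambda <- function(lam) {
    A <- K + lam * scale_k * diag(n_el)
    tryCatch(solve(A, V), error = function(e)
      stop_param(paste0("kernel matrix singular; include a nonzero lambda ",
                        "in `lambda_grid`")))
  }

  if (length(lambda_grid) == 1L) {
    lambda <- lambda_grid
    cv <- NA_real_
  } else {
    cv <- vapply(lambda_grid, function(lam) {
      err <- 0
      for (i in seq_len(n_el)) {
        Ki <- K[-i, -i] + lam * scale_k * diag(n_el - 1L)
        pred <- K[i, -i, drop = FALSE] %*%
          tryCatch(solve(Ki, V[-i, , drop = FALSE]),
                   error = function(e) matrix(Inf, n_el - 1L, ncol(V)))
        err <- err + sum((pred - V[i, ])^2)
      }
      err
    }, numeric(1))
    if (all(!is.finite(cv)))
      stop_param("kernel matrix singular for every lambda; include a nonzero lambda")
    lambda <- lambda_grid[which.min(cv)]   # deterministic: first minimum
  }
  beta <- solve_lambda(lambda)
  csd <- Kt %*% beta
  structure(list(depths_um = z_est, times_s = rec_times(snapshot),
                 csd = csd, lambda = lambda, cv_error = cv,
                 lambda_grid = lambda_grid,
                 basis = list(count = basis_count, halfwidth_um = w,
                              source_radius_um = source_radius_um,
                              centers_um = zb)),
            class = "csd_map")
}

#' @export
print.csd_map <- function(x, ...) {
  cat(sprintf("csd_map: %d depths x %d times, lambda = %.3g, basis %d x %g um\n",
              nrow(x$csd), ncol(x$csd), x$lambda, x$basis$count,
              x$basis$halfwidth_um))
  invisible(x)
}

#' @export
plot.csd_map <- function(x, ...) {
  lim <- max(abs(x$csd))
  graphics::image(x$times_s, x$depths_um, t(x$csd),
                  xlab = "time (s)", ylab = "depth (um)", ylim = rev(range(x$depths_um)),
                  zlim = c(-lim, lim),
                  col = grDevices::hcl.colors(64, "RdBu", rev = TRUE), ...)
  invisible(x)
}

#' Band-filter a CSD map in time
#'
#' Zero-phase band-pass of every depth row of the reconstructed CSD
#' (reconstruct-then-filter order). Used to separate the delta and HFO
#' dipoles of the spatiotemporal CSD picture.
#'
#' @param csd a `csd_map`.
#' @param band a [band_spec()].
#' @param order filter order.
#' @return filtered `csd_map`.
#' @export
band_filtered_csd <- function(csd, band, order = 4L) {
  stopifnot(inherits(csd, "csd_map"))
  if (ncol(csd$csd) < 24L) stop_param("CSD time axis too short for filtering")
  fs <- 1 / stats::median(diff(csd$times_s))
  out <- csd
  for (i in seq_len(nrow(csd$csd)))
    out$csd[i, ] <- butter_filtfilt(csd$csd[i, ], fs, band$lo,
                                    min(band$hi, fs / 2 * 0.999), order)
  out
}

#' Dipole sign-change depth of a CSD map
#'
#' At the time of the strongest CSD deflection, locates the zero crossing of
#' the depth profile between its largest positive and largest negative lobe
#' (linear interpolation). On a band-filtered map this estimates the depth of
#' the generating dipole.
#'
#' @param csd a `csd_map` (typically band-filtered).
#' @return depth in micrometres.
#' @export
csd_sign_change_depth <- function(csd) {
  stopifnot(inherits(csd, "csd_map"))
  tstar <- which.max(apply(abs(csd$csd), 2L, max))
  v <- csd$csd[, tstar]
  ip <- which.max(v); im <- which.min(v)
  if (v[ip] <= 0 || v[im] >= 0) stop_param("CSD profile has no opposite-sign lobes")
  lo <- min(ip, im); hi <- max(ip, im)
  seg <- v[lo:hi]
  cross <- which(seg[-length(seg)] * seg[-1] <= 0)[1]
  if (is.na(cross)) stop_param("no sign change between the CSD lobes")
  i <- lo + cross - 1L
  d <- csd$depths_um
  d[i] + (d[i + 1] - d[i]) * abs(v[i]) / (abs(v[i]) + abs(v[i + 1]))
}

#' Traditional second-spatial-difference CSD (internal oracle)
#'
#' Plain three-point second difference of the potential profile; provided as
#' an independent cross-check of the kernel method, not for analysis use.
#'
#' @param snapshot multichannel [recording()] with equidistant depths.
#' @return matrix (channels-2) x time.
#' @export
csd_second_difference <- function(snapshot) {
  V <- snapshot$samples
  h <- diff(snapshot$geometry$depths_um)[1]
  n <- nrow(V)
  -(V[-c(1, 2), , drop = FALSE] - 2 * V[-c(1, n), , drop = FALSE] +
      V[-c(n - 1, n), , drop = FALSE]) / h^2
}

# ---------------------------------------------------------------------------
# Multi-unit activity
# ---------------------------------------------------------------------------

#' Detect multi-unit spike candidates
#'
#' High-passes every channel (default 500 Hz), estimates a robust
#' (median/MAD) noise SD, and reports threshold crossings (negative-going by
#' extracellular convention, configurable) exceeding `threshold_sd` robust
#' SDs, with spike times at the local extremum and a refractory dead time.
#'
#' @param rec multichannel [recording()]; `fs` must be >= 2 kHz.
#' @param cutoff_hz high-pass edge (default 500).
#' @param threshold_sd threshold in robust SDs (default 3).
#' @param dead_time_s refractory period (default 1 ms).
#' @param polarity `"negative"` or `"positive"`.
#' @param order filter order.
#' @return list of spike-time vectors (seconds), one per channel.
#' @export
detect_mua <- function(rec, cutoff_hz = 500, threshold_sd = 3,
                       dead_time_s = 1e-3, polarity = c("negative", "positive"),
                       order = 4L) {
  stopifnot(inherits(rec, "ob_recording"))
  polarity <- match.arg(polarity)
  fs <- rec$fs
  if (fs < 2000) stop_param("MUA detection needs fs >= 2 kHz")
  dead <- max(1L, round(dead_time_s * fs))
  lapply(seq_len(nrow(rec$samples)), function(ch) {
    y <- butter_filtfilt(rec$samples[ch, ], fs, cutoff_hz, Inf, order)
    if (polarity == "negative") y <- -y
    sdv <- stats::mad(y)
    if (sdv == 0) return(numeric(0))
    thr <- stats::median(y) + threshold_sd * sdv
    above <- y > thr
    if (!any(above)) return(numeric(0))
    r <- rle(above)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    on <- starts[r$values]; off <- ends[r$values]
    pk <- mapply(function(a, b) a - 1L + which.max(y[a:b]), on, off)
    # dead time: keep the first crossing of each refractory cluster
    keep <- logical(length(pk))
    last <- -Inf
    for (i in seq_along(pk)) {
      if (pk[i] - last >= dead) { keep[i] <- TRUE; last <- pk[i] }
    }
    (pk[keep] - 1L) / fs
  })
}

#' MUA-HFO locking: burst-aligned spike density vs average HFO waveform
#'
#' Aligns spikes and the band-filtered HFO trace to every burst peak,
#' aggregates a spike-time histogram across events, averages the HFO
#' waveform across events, and computes the Pearson correlation between
#' histogram and waveform per channel on the common bin grid. Trough-locked
#' spiking gives r < 0 for the peak-positive waveform convention.
#'
#' @param spikes per-channel spike-time list (from [detect_mua()] or the
#'   generator).
#' @param bursts a `burst_events` table (>= 5 rows).
#' @param hfo band-filtered multichannel [recording()] (HFO band).
#' @param histogram_bin_s histogram bin (default 1 ms; must be <= half an
#'   HFO period).
#' @param window_s half-window around each burst peak (default 100 ms).
#' @return object of class `mua_hfo`: `r` per-channel correlation (NA where
#'   no spikes fell in any window), `density` (time grid x channel count
#'   matrix), `waveform` (average HFO per channel), `time_s` bin centres,
#'   `n_events`.
#' @export
mua_hfo_correlation <- function(spikes, bursts, hfo, histogram_bin_s = 1e-3,
                                window_s = 0.1) {
  stopifnot(inherits(hfo, "ob_recording"))
  if (nrow(bursts) < 5L) stop_param("need >= 5 bursts")
  fs <- hfo$fs
  n_ch <- nrow(hfo$samples)
  if (length(spikes) != n_ch)
    stop_param("spike list length must match channel count")
  edges <- seq(-window_s, window_s, by = histogram_bin_s)
  centres <- edges[-1] - histogram_bin_s / 2
  nb <- length(centres)
  n <- ncol(hfo$samples)
  counts <- matrix(0, nb, n_ch)
  wave <- matrix(0, nb, n_ch)
  n_used <- 0L
  for (b in seq_len(nrow(bursts))) {
    pk <- bursts$peak_s[b]
    i0 <- round((pk - window_s) * fs) + 1L
    i1 <- round((pk + window_s) * fs) + 1L
    if (i0 < 1L || i1 > n) next
    n_used <- n_used + 1L
    tt <- ((i0:i1) - 1L) / fs - pk
    for (ch in seq_len(n_ch)) {
      seg <- hfo$samples[ch, i0:i1]
      # bin-average the waveform onto the histogram grid
      bin <- pmin(nb, pmax(1L, findInterval(tt, edges, rightmost.closed = TRUE)))
      wave[, ch] <- wave[, ch] +
        as.numeric(tapply(seg, factor(bin, levels = seq_len(nb)), mean))
      rel <- spikes[[ch]] - pk
      rel <- rel[rel >= -window_s & rel < window_s]
      if (length(rel))
        counts[, ch] <- counts[, ch] + tabulate(
          findInterval(rel, edges, rightmost.closed = TRUE), nb)
    }
  }
  if (n_used == 0L) stop_param("no burst window fits inside the recording")
  wave <- wave / n_used
  r <- vapply(seq_len(n_ch), function(ch) {
    if (sum(counts[, ch]) == 0 || stats::sd(counts[, ch]) == 0 ||
        stats::sd(wave[, ch]) == 0) return(NA_real_)
    stats::cor(counts[, ch], wave[, ch])
  }, numeric(1))
  structure(list(r = r, density = counts, waveform = wave, time_s = centres,
                 n_events = n_used, bin_s = histogram_bin_s),
            class = "mua_hfo")
}

#' @export
print.mua_hfo <- function(x, ...) {
  cat(sprintf("mua_hfo: %d events, %d channels, r range [%.3f, %.3f]\n",
              x$n_events, length(x$r),
              suppressWarnings(min(x$r, na.rm = TRUE)),
              suppressWarnings(max(x$r, na.rm = TRUE))))
  invisible(x)
}
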