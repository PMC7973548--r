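#' Frequency band specification
#'
#' Canonical bands: delta 0.3-3 Hz (respiration-tracking), gamma 30-65 Hz,
#' KX-HFO 80-130 Hz, post-ketamine HFO 100-180 Hz, and MUA as a 500 Hz
#' high-pass (`hi = Inf`, clipped to Nyquist at use).
#'
#' @param lo,hi band edges in Hz (`0 < lo < hi`); `hi = Inf` means high-pass.
#' @param name optional label.
#' @return an object of class `band_spec`.
#' @export
band_spec <- function(lo, hi, name = sprintf("%g-%g Hz", lo, hi)) {
  if (!is.numeric(lo) || !is.numeric(hi) || lo <= 0 || hi <= lo)
    stop_param("band edges must satisfy 0 < lo < hi")
  structure(list(name = name, lo = lo, hi = hi), class = "band_spec")
}

#' @rdname band_spec
#' @export
band_delta <- function() band_spec(0.3, 3, "delta")
#' @rdname band_spec
#' @export
band_gamma <- function() band_spec(30, 65, "gamma")
#' @rdname band_spec
#' @export
band_hfo_kx <- function() band_spec(80, 130, "KX-HFO")
#' @rdname band_spec
#' @export
band_hfo_ket <- function() band_spec(100, 180, "ketamine-HFO")
#' @rdname band_spec
#' @export
band_mua <- function() band_spec(500, Inf, "MUA")

#' @export
print.band_spec <- function(x, ...) {
  cat(sprintf("band_spec %s: %g-%s Hz\n", x$name, x$lo,
              if (is.finite(x$hi)) format(x$hi) else "Nyquist"))
  invisible(x)
}

# Empirical stability check of an IIR design: run an impulse through the
# recursion and require a finite, decaying response. Nominal pole radii are
# not trustworthy here - low-relative-frequency bandpass designs with poles
# nominally at 0.9997 still diverge through coefficient quantisation.
filter_is_stable <- function(flt, n = 4096L) {
  h <- signal::filter(flt, c(1, numeric(n - 1L)))
  if (any(!is.finite(h))) return(FALSE)
  head_max <- max(abs(h[seq_len(n %/% 2)]))
  tail_max <- max(abs(h[(n %/% 2 + 1L):n]))
  tail_max <= head_max
}

.filter_plan_cache <- new.env(parent = emptyenv())

# Decide once per (fs, lo, hi, order) whether the direct bandpass design is
# usable or the equal-order high-pass + low-pass cascade must be used.
filter_plan <- function(fs, lo, hi, order) {
  key <- paste(fs, lo, hi, order, sep = "|")
  plan <- .filter_plan_cache[[key]]
  if (!is.null(plan)) return(plan)
  nyq <- fs / 2
  bp <- signal::butter(order, c(lo, hi) / nyq, type = "pass")
  plan <- if (filter_is_stable(bp)) list(type = "direct", flt = bp)
  else list(type = "cascade",
            hp = signal::butter(order, lo / nyq, type = "high"),
            lp = signal::butter(order, hi / nyq, type = "low"))
  .filter_plan_cache[[key]] <- plan
  plan
}

# Zero-phase Butterworth filtering of a numeric vector. A direct bandpass
# design is used when it is numerically stable; very low relative bands
# (e.g. 0.3-3 Hz at 1 kHz) make that design diverge, in which case an
# equal-order high-pass + low-pass cascade is applied instead (identical
# band edges, monotone response).
butter_filtfilt <- function(x, fs, lo, hi, order = 4L) {
  nyq <- fs / 2
  if (lo >= nyq) stop_param(sprintf("band low edge %g Hz >= Nyquist %g Hz", lo, nyq))
  highpass_only <- !is.finite(hi)   # hi = Inf is an explicit high-pass
  if (!highpass_only && hi >= nyq)
    stop_param(sprintf("band high edge %g Hz >= Nyquist %g Hz", hi, nyq))
  if (highpass_only) {
    flt <- signal::butter(order, lo / nyq, type = "high")
    return(signal::filtfilt(flt, x))
  }
  plan <- filter_plan(fs, lo, hi, order)
  if (plan$type == "direct") signal::filtfilt(plan$flt, x)
  else signal::filtfilt(plan$lp, signal::filtfilt(plan$hp, x))
}

# Seconds of filter settling to flag at each edge: 3x the effective impulse
# response width (99% energy) of the band filter, capped at a quarter of the
# trace.
filter_edge_s <- function(fs, lo, hi, order, duration) {
  probe_len <- min(duration, max(4 / lo, 1))
  imp <- numeric(round(probe_len * fs))
  imp[1] <- 1
  h <- tryCatch(butter_filtfilt(imp, fs, lo, hi, order),
                error = function(e) imp)
  e <- cumsum(h^2) / sum(h^2)
  w <- which(e >= 0.99)[1] / fs
  min(3 * w, duration / 4)
}

#' Zero-phase Butterworth band-pass filter
#'
#' Forward-backward (zero-phase) filtering of every channel; band-limited
#' components keep their timing exactly, which all downstream phase
#' statistics rely on. The effective magnitude response is the squared
#' filter response (order 4 -> 8th-order magnitude).
#'
#' The first/last settling segments (3x the filter impulse-response width)
#' are flagged in the attribute `"edge_s"` of the result; statistics
#' downstream exclude them.
#'
#' @param rec an [recording()] (or numeric vector with `fs` supplied).
#' @param band a [band_spec()]; `hi = Inf` gives a high-pass.
#' @param order Butterworth order per pass (default 4).
#' @param fs sampling rate, required when `rec` is a bare vector.
#' @return filtered recording of the same shape.
#' @export
bandpass <- function(rec, band, order = 4L, fs = NULL) {
  stopifnot(inherits(band, "band_spec"))
  vec_in <- !inherits(rec, "ob_recording")
  if (vec_in) {
    if (is.null(fs)) stop_param("`fs` is required when filtering a bare vector")
    rec <- recording(rec, fs)
  }
  fs <- rec$fs
  out <- rec
  for (ch in seq_len(nrow(rec$samples)))
    out$samples[ch, ] <- butter_filtfilt(rec$samples[ch, ], fs,
                                         band$lo, band$hi, order)
  attr(out, "edge_s") <- filter_edge_s(fs, band$lo,
                                       min(band$hi, fs / 2 * 0.999), order,
                                       rec_duration(rec))
  attr(out, "band") <- band
  if (vec_in) {
    v <- out$samples[1, ]
    attributes(v) <- NULL
    attr(v, "edge_s") <- attr(out, "edge_s")
    return(v)
  }
  out
}

#' Analytic envelope and instantaneous phase (Hilbert transform)
#'
#' Computes the analytic signal by one-sided FFT spectrum doubling. The
#' input must already be band-limited (narrowband) for envelope/phase to be
#' meaningful; [bandpass()] does that.
#'
#' @param x single-channel [recording()] or numeric vector.
#' @return list with numeric vectors `envelope` (>= 0) and `phase`
#'   (radians, in (-pi, pi]).
#' @export
analytic_envelope_phase <- function(x) {
  if (inherits(x, "ob_recording")) {
    if (nrow(x$samples) != 1L)
      stop_param("analytic_envelope_phase expects a single channel")
    x <- x$samples[1, ]
  }
  n <- length(x)
  if (n < 8L) stop_param("signal too short for an analytic signal (< 8 samples)")
  X <- stats::fft(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[c(1, n / 2 + 1)] <- 1
    h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1
    h[2:((n + 1) / 2)] <- 2
  }
  a <- stats::fft(X * h, inverse = TRUE) / n
  list(envelope = Mod(a), phase = Arg(a))
}

#' Welch power spectral density
#'
#' Averaged modified periodogram: Hann window, 50% overlap, one-sided
#' density scaling so that `sum(power) * df` equals the signal variance
#' (Parseval). The window defaults to 60 s.
#'
#' @param x single-channel [recording()] or numeric vector.
#' @param fs sampling rate, required for bare vectors.
#' @param window_s segment length in seconds (default 60).
#' @param allow_short if `TRUE` and the signal is shorter than one window,
#'   use the whole signal as a single segment instead of failing.
#' @return object of class `ob_psd` with `freq` (Hz), `power` (mV^2/Hz),
#'   `df`, `window_s`, `method`.
#' @export
welch_psd <- function(x, fs = NULL, window_s = 60, allow_short = FALSE) {
  if (inherits(x, "ob_recording")) {
    if (nrow(x$samples) != 1L)
      stop_param("welch_psd expects a single channel; subset first")
    fs <- x$fs
    x <- x$samples[1, ]
  }
  if (is.null(fs)) stop_param("`fs` is required for a bare vector")
  check_positive(window_s, "window_s")
  nw <- round(window_s * fs)
  if (nw > length(x)) {
    if (!allow_short)
      stop_param(sprintf(
        "signal (%.3g s) shorter than the Welch window (%g s); pass allow_short = TRUE or a shorter window",
        length(x) / fs, window_s))
    nw <- length(x)
  }
  step <- max(1L, floor(nw / 2))
  starts <- seq(1L, length(x) - nw + 1L, by = step)
  w <- 0.5 - 0.5 * cos(2 * pi * seq_len(nw) / (nw + 1))  # Hann
  U <- sum(w^2)
  nfreq <- nw %/% 2 + 1L
  acc <- numeric(nfreq)
  for (s in starts) {
    seg <- x[s:(s + nw - 1L)] * w
    P <- Mod(stats::fft(seg))^2
    acc <- acc + P[seq_len(nfreq)]
  }
  pxx <- acc / (length(starts) * fs * U)
  # one-sided: double everything except DC (and Nyquist when nw is even)
  if (nw %% 2 == 0) pxx[2:(nfreq - 1L)] <- 2 * pxx[2:(nfreq - 1L)]
  else pxx[2:nfreq] <- 2 * pxx[2:nfreq]
  df <- fs / nw
  structure(list(freq = (seq_len(nfreq) - 1L) * df, power = pxx, df = df,
                 window_s = nw / fs, n_segments = length(starts),
                 method = "welch-hann-50"),
            class = "ob_psd")
}

#' @export
print.ob_psd <- function(x, ...) {
  cat(sprintf("ob_psd: %d bins, df %.4g Hz, %d segments of %g s (%s)\n",
              length(x$freq), x$df, x$n_segments, x$window_s, x$method))
  invisible(x)
}

#' @export
plot.ob_psd <- function(x, xlim = NULL, log = "y", ...) {
  keep <- x$power > 0 | log == ""
  graphics::plot(x$freq[keep], x$power[keep], type = "l", log = log,
                 xlim = xlim, xlab = "frequency (Hz)",
                 ylab = "PSD (mV^2/Hz)", ...)
  invisible(x)
}

#' Write a spectral estimate to CSV (freq_hz, power_mv2)
#' @param psd an `ob_psd`.
#' @param path output file.
#' @export
write_psd <- function(psd, path) {
  utils::write.csv(data.frame(freq_hz = psd$freq, power_mv2 = psd$power),
                   path, row.names = FALSE)
  invisible(path)
}

#' Dominant frequency and its power within a band
#'
#' Argmax of the spectral estimate restricted to the band; ties break toward
#' the lower frequency. Power is reported as the in-bin power
#' (density x bin width, mV^2).
#'
#' @param psd an `ob_psd` from [welch_psd()].
#' @param band a [band_spec()].
#' @return list with `freq` (Hz) and `power` (mV^2).
#' @export
dominant_frequency <- function(psd, band) {
  stopifnot(inherits(psd, "ob_psd"), inherits(band, "band_spec"))
  sel <- which(psd$freq >= band$lo & psd$freq <= band$hi)
  if (length(sel) == 0L)
    stop_param(sprintf("band %s does not intersect the frequency grid", band$name))
  i <- sel[which.max(psd$power[sel])]   # which.max: first max -> lower freq
  list(freq = psd$freq[i], power = psd$power[i] * psd$df)
}

#' Sliding dominant-band power timecourse
#'
#' Welch spectrum in a sliding window, reduced per window to the dominant
#' frequency and its power in the band (the "power of dominant frequency"
#' timecourse of drug-injection spectrogram summaries).
#'
#' @param rec single-channel [recording()] or numeric vector.
#' @param band a [band_spec()].
#' @param window_s sliding window length in seconds.
#' @param step_s window step in seconds (> 0).
#' @param welch_window_s Welch segment length inside each window (defaults to
#'   `window_s / 4`).
#' @param fs sampling rate for bare vectors.
#' @return data frame with `time_s` (window centres), `freq_hz`, `power_mv2`.
#' @export
band_power_timecourse <- function(rec, band, window_s, step_s,
                                  welch_window_s = window_s / 4, fs = NULL) {
  if (inherits(rec, "ob_recording")) {
    if (nrow(rec$samples) != 1L)
      stop_param("band_power_timecourse expects a single channel")
    fs <- rec$fs
    x <- rec$samples[1, ]
  } else x <- rec
  if (is.null(fs)) stop_param("`fs` is required for a bare vector")
  if (step_s <= 0) stop_param("`step_s` must be > 0")
  nw <- round(window_s * fs)
  if (nw > length(x)) stop_param("window longer than the recording")
  starts <- seq(1L, length(x) - nw + 1L, by = max(1L, round(step_s * fs)))
  res <- lapply(starts, function(s) {
    p <- welch_psd(x[s:(s + nw - 1L)], fs, window_s = welch_window_s,
                   allow_short = TRUE)
    d <- dominant_frequency(p, band)
    c(time_s = (s - 1L + nw / 2) / fs, freq_hz = d$freq, power_mv2 = d$power)
  })
  as.data.frame(do.call(rbind, res))
}
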