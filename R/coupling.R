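#' Detect oscillatory bursts from an envelope by SD thresholding
#'
#' Maximal runs where the envelope exceeds `baseline mean + threshold_sd * SD`
#' are reported as bursts; runs shorter than `min_duration_s` are dropped and
#' gaps shorter than `merge_gap_s` are merged first. By default the baseline
#' centre/spread are the median and MAD-based robust SD of the whole
#' envelope, which bursts themselves barely inflate; alternatively a quiet
#' segment can be designated.
#'
#' @param env envelope vector (from [analytic_envelope_phase()]).
#' @param fs sampling rate in Hz.
#' @param band optional [band_spec()]; when given, `min_duration_s` defaults
#'   to 3 band-centre cycles and `merge_gap_s` to 1 cycle.
#' @param threshold_sd threshold in baseline SDs (default 3).
#' @param baseline `"robust"` (median/MAD over the trace) or `"segment"`.
#' @param baseline_segment numeric `c(t0, t1)` seconds, required for
#'   `baseline = "segment"`.
#' @param min_duration_s minimal burst duration in seconds.
#' @param merge_gap_s gaps shorter than this are merged.
#' @param channel channel index stored in the output table.
#' @return data frame of class `burst_events` with columns `onset_s`,
#'   `offset_s`, `peak_s`, `peak_env`, `channel`.
#' @export
detect_bursts <- function(env, fs, band = NULL, threshold_sd = 3,
                          baseline = c("robust", "segment"),
                          baseline_segment = NULL,
                          min_duration_s = NULL, merge_gap_s = NULL,
                          channel = 1L) {
  baseline <- match.arg(baseline)
  if (threshold_sd < 0) stop_param("`threshold_sd` must be >= 0")
  if (any(env < 0)) stop_param("envelope must be nonnegative")
  if (!is.null(band)) {
    fc <- (band$lo + min(band$hi, fs / 2)) / 2
    if (is.null(min_duration_s)) min_duration_s <- 3 / fc
    if (is.null(merge_gap_s)) merge_gap_s <- 1 / fc
  }
  if (is.null(min_duration_s) || is.null(merge_gap_s))
    stop_param("supply `band` or both `min_duration_s` and `merge_gap_s`")
  if (baseline == "robust") {
    mu <- stats::median(env)
    sdv <- stats::mad(env)
  } else {
    if (is.null(baseline_segment) || length(baseline_segment) != 2L)
      stop_param("`baseline_segment` = c(t0, t1) is required for baseline = \"segment\"")
    idx <- seq(max(1L, round(baseline_segment[1] * fs) + 1L),
               min(length(env), round(baseline_segment[2] * fs)))
    mu <- mean(env[idx])
    sdv <- stats::sd(env[idx])
  }
  empty <- data.frame(onset_s = numeric(0), offset_s = numeric(0),
                      peak_s = numeric(0), peak_env = numeric(0),
                      channel = integer(0))
  class(empty) <- c("burst_events", "data.frame")
  if (!is.finite(sdv) || sdv == 0) {
    above <- env > mu   # all-constant envelope -> no crossings
    if (!any(above)) return(empty)
  }
  thr <- mu + threshold_sd * sdv
  above <- env > thr
  if (!any(above)) return(empty)
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  on <- starts[r$values]
  off <- ends[r$values]
  # merge gaps shorter than merge_gap_s
  if (length(on) > 1L) {
    gap <- (on[-1L] - off[-length(off)] - 1L) / fs
    keep_sep <- gap >= merge_gap_s
    grp <- cumsum(c(TRUE, keep_sep))
    on <- tapply(on, grp, min)
    off <- tapply(off, grp, max)
  }
  dur <- (off - on + 1L) / fs
  sel <- dur >= min_duration_s
  on <- on[sel]; off <- off[sel]
  if (length(on) == 0L) return(empty)
  peak_i <- mapply(function(a, b) a - 1L + which.max(env[a:b]), on, off)
  out <- data.frame(onset_s = (on - 1L) / fs, offset_s = (off - 1L) / fs,
                    peak_s = (peak_i - 1L) / fs, peak_env = env[peak_i],
                    channel = channel)
  rownames(out) <- NULL
  class(out) <- c("burst_events", "data.frame")
  out
}

# Local maxima of a series with a minimum separation (seconds).
find_peaks <- function(x, fs, min_sep_s) {
  d <- diff(x)
  cand <- which(d[-length(d)] > 0 & d[-1L] <= 0) + 1L
  if (length(cand) == 0L) return(integer(0))
  min_sep <- round(min_sep_s * fs)
  ord <- cand[order(x[cand], decreasing = TRUE)]
  taken <- integer(0)
  for (i in ord)
    if (all(abs(i - taken) >= min_sep)) taken <- c(taken, i)
  sort(taken)
}

#' Burst phase relative to the delta rhythm
#'
#' The paper-literal "time rescaling" mode locates delta peaks (local maxima
#' with minimum separation of half the fastest delta period) and maps each
#' burst peak to phase `2*pi * (t - preceding peak) / cycle period`, wrapped
#' to (-pi, pi] with the delta peak at 0. Mode `"hilbert"` instead reads the
#' instantaneous Hilbert phase of the delta trace at the burst peak.
#'
#' Bursts occurring before the first delta peak are skipped; their count is
#' kept in the result.
#'
#' @param bursts a `burst_events` table.
#' @param delta band-filtered delta series (numeric vector or single-channel
#'   [recording()]).
#' @param fs sampling rate for bare vectors.
#' @param hi_delta upper delta band edge in Hz, sets the peak separation.
#' @param mode `"rescale"` (default) or `"hilbert"`.
#' @return object of class `phase_set`: list with `phases` (radians),
#'   `n_skipped`, `convention`.
#' @export
burst_delta_phase <- function(bursts, delta, fs = NULL, hi_delta = 3,
                              mode = c("rescale", "hilbert")) {
  mode <- match.arg(mode)
  if (inherits(delta, "ob_recording")) {
    fs <- delta$fs
    delta <- delta$samples[1, ]
  }
  if (is.null(fs)) stop_param("`fs` is required for a bare vector")
  if (nrow(bursts) == 0L)
    return(structure(list(phases = numeric(0), n_skipped = 0L,
                          convention = "delta peak = 0"), class = "phase_set"))
  if (mode == "hilbert") {
    ph <- analytic_envelope_phase(delta)$phase
    idx <- pmin(length(ph), pmax(1L, round(bursts$peak_s * fs) + 1L))
    return(structure(list(phases = wrap_pi(ph[idx]), n_skipped = 0L,
                          convention = "delta peak = 0 (hilbert)"),
                     class = "phase_set"))
  }
  pk <- find_peaks(delta, fs, min_sep_s = 1 / (2 * hi_delta))
  if (length(pk) < 2L) stop_param("need at least one full delta cycle")
  pk_t <- (pk - 1L) / fs
  periods <- diff(pk_t)
  phases <- numeric(0)
  n_skip <- 0L
  for (tb in bursts$peak_s) {
    j <- findInterval(tb, pk_t)
    if (j == 0L) { n_skip <- n_skip + 1L; next }
    per <- if (j <= length(periods)) periods[j] else periods[length(periods)]
    phases <- c(phases, wrap_pi(2 * pi * (tb - pk_t[j]) / per))
  }
  if (n_skip > 0L)
    message(sprintf("burst_delta_phase: %d burst(s) before the first delta peak skipped", n_skip))
  structure(list(phases = phases, n_skipped = n_skip,
                 convention = "delta peak = 0"), class = "phase_set")
}

#' @export
print.phase_set <- function(x, ...) {
  cat(sprintf("phase_set: n = %d, circular mean %.3f rad, ITPC %.3f (%s)\n",
              length(x$phases),
              if (length(x$phases)) circ_mean(x$phases) else NA_real_,
              if (length(x$phases)) circ_r(x$phases) else NA_real_,
              x$convention))
  invisible(x)
}

#' Intertrial phase clustering
#'
#' Modulus of the mean unit phasor, `|n^-1 sum exp(i k_r)|`: 1 when all
#' event phases coincide, ~0 for uniformly scattered phases. Invariant to a
#' global phase rotation.
#'
#' @param ps a `phase_set` or numeric vector of phases in radians.
#' @return ITPC value in [0, 1].
#' @export
itpc <- function(ps) {
  phases <- if (inherits(ps, "phase_set")) ps$phases else ps
  if (length(phases) == 0L) stop_param("ITPC of an empty phase set is undefined")
  circ_r(phases)
}

#' Pearson correlation between band-limited signals and/or envelopes
#'
#' Standard Pearson r after bringing both series to a common sampling rate:
#' the faster series is decimated (anti-aliased polyphase, via
#' `signal::decimate`) when rates differ by an integer factor, else both are
#' linearly interpolated onto the slower grid. Used for respiration-delta vs
#' LFP-delta and delta vs HFO-envelope correlations.
#'
#' @param x,y numeric vectors or single-channel [recording()]s.
#' @param fs_x,fs_y sampling rates for bare vectors.
#' @return Pearson correlation coefficient.
#' @export
envelope_correlation <- function(x, y, fs_x = NULL, fs_y = NULL) {
  if (inherits(x, "ob_recording")) { fs_x <- x$fs; x <- x$samples[1, ] }
  if (inherits(y, "ob_recording")) { fs_y <- y$fs; y <- y$samples[1, ] }
  if (is.null(fs_x) || is.null(fs_y)) {
    if (length(x) != length(y))
      stop_param("lengths differ and sampling rates were not supplied")
  } else if (fs_x != fs_y) {
    if (fs_x > fs_y) {
      r <- fs_x / fs_y
      x <- if (abs(r - round(r)) < 1e-9)
        signal::decimate(x, round(r)) else
        stats::approx(seq_along(x) / fs_x, x,
                      xout = seq_len(floor(length(x) * fs_y / fs_x)) / fs_y)$y
    } else {
      r <- fs_y / fs_x
      y <- if (abs(r - round(r)) < 1e-9)
        signal::decimate(y, round(r)) else
        stats::approx(seq_along(y) / fs_y, y,
                      xout = seq_len(floor(length(y) * fs_x / fs_y)) / fs_x)$y
    }
  }
  n <- min(length(x), length(y))
  x <- x[seq_len(n)]; y <- y[seq_len(n)]
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop_param("correlation undefined: an input has zero variance")
  stats::cor(x, y)
}

#' Tort modulation index
#'
#' Phase-amplitude coupling as the normalised Kullback-Leibler divergence of
#' the phase-binned mean-amplitude distribution from uniform:
#' `MI = (log N - H(P)) / log N` with `P_j` the mean amplitude in phase bin
#' `j` normalised to sum 1, natural logs, and N equal phase bins on
#' (-pi, pi]. 0 for phase-independent amplitude, 1 when all amplitude
#' concentrates in a single bin.
#'
#' If some bin receives no samples the binning is coarsened (bin count
#' halved) until all bins are occupied; fewer than 2 bins is an error.
#'
#' @param phase phase series in radians.
#' @param amplitude envelope series, same length, nonnegative.
#' @param n_bins number of phase bins (default 18).
#' @return modulation index in [0, 1].
#' @export
tort_mi <- function(phase, amplitude, n_bins = 18L) {
  if (length(phase) != length(amplitude))
    stop_param("phase and amplitude must have equal length")
  if (n_bins < 2L) stop_param("`n_bins` must be >= 2")
  if (any(amplitude < 0)) stop_param("amplitude must be nonnegative")
  phase <- wrap_pi(phase)
  nb <- as.integer(n_bins)
  repeat {
    edges <- seq(-pi, pi, length.out = nb + 1L)
    bin <- findInterval(phase, edges, rightmost.closed = TRUE,
                        left.open = TRUE)
    bin[bin == 0L] <- 1L    # phase exactly -pi
    counts <- tabulate(bin, nb)
    if (all(counts > 0L)) break
    if (nb <= 2L)
      stop_param("empty phase bin remains after coarsening; too few samples")
    nb <- max(2L, nb %/% 2L)
  }
  m <- as.numeric(tapply(amplitude, factor(bin, levels = seq_len(nb)), mean))
  s <- sum(m)
  if (s == 0) return(0)    # all-zero amplitude: uniform by convention
  p <- m / s
  h <- -sum(ifelse(p > 0, p * log(p), 0))
  (log(nb) - h) / log(nb)
}

#' Phase-amplitude comodulogram
#'
#' For every (phase band, amplitude band) cell: band-pass both, take the
#' Hilbert phase of the slow band and envelope of the fast band, and compute
#' the Tort modulation index. Cells whose bands overlap are flagged invalid
#' (NA). The phase signal may come from a second series (e.g. respiration)
#' via `phase_source`.
#'
#' @param x single-channel [recording()] or numeric vector (amplitude source).
#' @param phase_bands,amp_bands two-column matrices or data frames of band
#'   edges (`lo`, `hi`), e.g. from [band_grid()].
#' @param n_bins phase bins for [tort_mi()].
#' @param fs sampling rate for bare vectors.
#' @param phase_source optional second series providing the phase signal
#'   (same sampling rate and length).
#' @param order filter order.
#' @return object of class `comodulogram`: `mi` matrix (phase x amplitude),
#'   `phase_freqs`, `amp_freqs` (band centres), the band tables and `n_bins`.
#' @export
comodulogram <- function(x, phase_bands, amp_bands, n_bins = 18L, fs = NULL,
                         phase_source = NULL, order = 4L) {
  if (inherits(x, "ob_recording")) { fs <- x$fs; x <- x$samples[1, ] }
  if (is.null(fs)) stop_param("`fs` is required for a bare vector")
  pb <- as.matrix(as.data.frame(phase_bands)[, 1:2])
  ab <- as.matrix(as.data.frame(amp_bands)[, 1:2])
  if (any(pb[, 2] >= fs / 2) || any(ab[, 2] >= fs / 2))
    stop_param("band edges must lie below Nyquist")
  slowest <- min(pb[, 1])
  if (length(x) / fs < 10 / slowest)
    stop_param(sprintf("need >= 10 cycles of the slowest phase band (%.3g Hz)", slowest))
  y <- if (is.null(phase_source)) x else {
    if (inherits(phase_source, "ob_recording")) phase_source$samples[1, ]
    else phase_source
  }
  phases <- lapply(seq_len(nrow(pb)), function(i)
    analytic_envelope_phase(butter_filtfilt(y, fs, pb[i, 1], pb[i, 2], order))$phase)
  mi <- matrix(NA_real_, nrow(pb), nrow(ab))
  for (j in seq_len(nrow(ab))) {
    env <- analytic_envelope_phase(
      butter_filtfilt(x, fs, ab[j, 1], ab[j, 2], order))$envelope
    for (i in seq_len(nrow(pb))) {
      if (ab[j, 1] < pb[i, 2] && pb[i, 1] < ab[j, 2]) next  # overlap: invalid
      mi[i, j] <- tort_mi(phases[[i]], env, n_bins)
    }
  }
  structure(list(mi = mi, phase_freqs = rowMeans(pb), amp_freqs = rowMeans(ab),
                 phase_bands = pb, amp_bands = ab, n_bins = as.integer(n_bins)),
            class = "comodulogram")
}

#' Build a band grid from centres and a common bandwidth
#' @param centers band centres in Hz.
#' @param bandwidth full bandwidth in Hz.
#' @return data frame with `lo`, `hi`.
#' @export
band_grid <- function(centers, bandwidth) {
  data.frame(lo = centers - bandwidth / 2, hi = centers + bandwidth / 2)
}

#' @export
print.comodulogram <- function(x, ...) {
  i <- which(x$mi == max(x$mi, na.rm = TRUE), arr.ind = TRUE)[1, ]
  cat(sprintf("comodulogram: %d x %d cells, max MI %.4g at (%.3g Hz phase, %.3g Hz amp)\n",
              nrow(x$mi), ncol(x$mi), max(x$mi, na.rm = TRUE),
              x$phase_freqs[i[1]], x$amp_freqs[i[2]]))
  invisible(x)
}

#' @export
plot.comodulogram <- function(x, ...) {
  graphics::image(x$phase_freqs, x$amp_freqs, x$mi,
                  xlab = "phase frequency (Hz)",
                  ylab = "amplitude frequency (Hz)",
                  col = grDevices::hcl.colors(64, "viridis"), ...)
  invisible(x)
}

#' Cell of maximal modulation index
#' @param cm a `comodulogram`.
#' @return list with `phase_freq`, `amp_freq`, `mi`.
#' @export
comodulogram_argmax <- function(cm) {
  i <- which(cm$mi == max(cm$mi, na.rm = TRUE), arr.ind = TRUE)[1, ]
  list(phase_freq = cm$phase_freqs[i[1]], amp_freq = cm$amp_freqs[i[2]],
       mi = cm$mi[i[1], i[2]])
}

#' Write a comodulogram as CSV matrix + JSON axes
#' @param cm a `comodulogram`.
#' @param prefix path prefix; writes `<prefix>.csv` and `<prefix>.json`.
#' @export
write_comodulogram <- function(cm, prefix) {
  m <- cm$mi
  dimnames(m) <- list(sprintf("phase_%g", cm$phase_freqs),
                      sprintf("amp_%g", cm$amp_freqs))
  utils::write.csv(m, paste0(prefix, ".csv"))
  jsonlite::write_json(list(phase_freqs = cm$phase_freqs,
                            amp_freqs = cm$amp_freqs, n_bins = cm$n_bins),
                       paste0(prefix, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(prefix)
}

#' Group resampling test for modulation-index matrices
#'
#' For each cell the observed statistic is `|mean(group A) - mean(group B)|`
#' of the per-subject MI values. The null pools both groups' values for that
#' cell and redraws two pseudo-groups of the original sizes with replacement
#' `n_draws` times; the p-value is the add-one-smoothed fraction of null
#' differences at least as large as observed. The resampling unit is the
#' per-subject matrix cell (subjects are redrawn, not time points). No
#' multiple-comparison correction is applied.
#'
#' @param group_a,group_b lists of `comodulogram`s (or plain MI matrices)
#'   with congruent grids, >= 2 per group.
#' @param n_draws number of resampling draws (default 100000).
#' @param seed integer seed; results are bit-reproducible per seed.
#' @return object of class `mi_resampling`: `p` matrix, `observed` matrix,
#'   grid axes, `n_draws`, `seed`.
#' @export
mi_resampling_test <- function(group_a, group_b, n_draws = 100000L, seed = 1L) {
  as_mi <- function(g) if (inherits(g, "comodulogram")) g$mi else as.matrix(g)
  A <- lapply(group_a, as_mi)
  B <- lapply(group_b, as_mi)
  if (length(A) < 2L || length(B) < 2L)
    stop_param("need at least 2 matrices per group")
  dims <- unique(lapply(c(A, B), dim))
  if (length(dims) != 1L) stop_param("incongruent comodulogram grids")
  na <- length(A); nb <- length(B)
  d <- dims[[1]]
  Am <- sapply(A, as.numeric)   # cells x subjects
  Bm <- sapply(B, as.numeric)
  obs <- abs(rowMeans(Am) - rowMeans(Bm))
  p <- with_seed(seed, {
    vapply(seq_len(nrow(Am)), function(cell) {
      pool <- c(Am[cell, ], Bm[cell, ])
      if (any(!is.finite(pool))) return(NA_real_)  # invalid (overlap) cells
      ia <- matrix(sample.int(na + nb, n_draws * na, replace = TRUE), n_draws)
      ib <- matrix(sample.int(na + nb, n_draws * nb, replace = TRUE), n_draws)
      null_d <- abs(rowMeans(matrix(pool[ia], n_draws)) -
                    rowMeans(matrix(pool[ib], n_draws)))
      (1 + sum(null_d >= obs[cell])) / (n_draws + 1)
    }, numeric(1))
  })
  axes <- if (inherits(group_a[[1]], "comodulogram"))
    list(phase_freqs = group_a[[1]]$phase_freqs,
         amp_freqs = group_a[[1]]$amp_freqs) else
    list(phase_freqs = NULL, amp_freqs = NULL)
  structure(list(p = matrix(p, d[1], d[2]),
                 observed = matrix(obs, d[1], d[2]),
                 phase_freqs = axes$phase_freqs, amp_freqs = axes$amp_freqs,
                 n_draws = n_draws, seed = seed),
            class = "mi_resampling")
}

#' @export
print.mi_resampling <- function(x, ...) {
  cat(sprintf("mi_resampling: %d x %d cells, %d draws, min p = %.4g\n",
              nrow(x$p), ncol(x$p), x$n_draws, min(x$p, na.rm = TRUE)))
  invisible(x)
}
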