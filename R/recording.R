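#' Laminar probe geometry
#'
#' Describes a linear silicon probe: number of contacts, inter-contact spacing
#' and the depth of the most dorsal contact. Depth is measured in micrometres
#' and increases ventrally; channel 1 is the most dorsal site.
#'
#' @param n_channels number of contacts (>= 2).
#' @param spacing_um inter-contact distance in micrometres (e.g. 20 or 100).
#' @param depth_first_um depth of channel 1 in micrometres.
#' @return an object of class `probe_geometry` with a `depths_um` vector.
#' @export
probe_geometry <- function(n_channels = 32L, spacing_um = 100, depth_first_um = 100) {
  if (!is.numeric(n_channels) || n_channels < 2)
    stop_param("`n_channels` must be an integer >= 2")
  check_positive(spacing_um, "spacing_um")
  depths <- depth_first_um + (seq_len(n_channels) - 1) * spacing_um
  structure(list(n_channels = as.integer(n_channels),
                 spacing_um = spacing_um,
                 depth_first_um = depth_first_um,
                 depths_um = depths),
            class = "probe_geometry")
}

#' @export
print.probe_geometry <- function(x, ...) {
  cat(sprintf("Linear probe: %d channels, %g um spacing, span %g-%g um\n",
              x$n_channels, x$spacing_um, min(x$depths_um), max(x$depths_um)))
  invisible(x)
}

#' Multichannel recording container
#'
#' Holds a channels x time sample matrix in millivolts together with the
#' sampling rate and (optionally) per-channel depths from a [probe_geometry()].
#' Single-channel signals such as a thermocouple respiration trace use the same
#' container with `geometry = NULL`.
#'
#' @param samples numeric matrix, channels in rows, samples in columns, or a
#'   numeric vector for a single channel.
#' @param fs sampling rate in Hz.
#' @param geometry a [probe_geometry()] or `NULL`.
#' @param channel_labels optional character vector of channel names.
#' @param t0 time of the first sample in seconds.
#' @param units sample units, `"mV"` by default.
#' @return an object of class `ob_recording`.
#' @export
recording <- function(samples, fs, geometry = NULL, channel_labels = NULL,
                      t0 = 0, units = "mV") {
  if (is.vector(samples)) samples <- matrix(samples, nrow = 1L)
  if (!is.matrix(samples) || !is.numeric(samples))
    stop_param("`samples` must be a numeric matrix (channels x time)")
  if (any(!is.finite(samples)))
    stop_param("`samples` contains non-finite values")
  check_positive(fs, "fs")
  if (!is.null(geometry) && geometry$n_channels != nrow(samples))
    stop_param("geometry channel count does not match sample matrix")
  if (is.null(channel_labels))
    channel_labels <- sprintf("ch%02d", seq_len(nrow(samples)))
  structure(list(samples = samples, fs = fs, geometry = geometry,
                 channel_labels = channel_labels, t0 = t0, units = units),
            class = "ob_recording")
}

#' @export
print.ob_recording <- function(x, ...) {
  cat(sprintf("ob_recording: %d channel(s), %.6g s at %g Hz (%s)\n",
              nrow(x$samples), ncol(x$samples) / x$fs, x$fs, x$units))
  if (!is.null(x$geometry))
    cat(sprintf("  depths %g-%g um (%g um spacing)\n",
                min(x$geometry$depths_um), max(x$geometry$depths_um),
                x$geometry$spacing_um))
  invisible(x)
}

#' @export
plot.ob_recording <- function(x, channels = NULL, tlim = NULL, offset = NULL, ...) {
  ch <- if (is.null(channels)) seq_len(nrow(x$samples)) else channels
  t <- rec_times(x)
  keep <- if (is.null(tlim)) rep(TRUE, length(t)) else t >= tlim[1] & t <= tlim[2]
  if (is.null(offset)) offset <- 4 * stats::sd(x$samples[ch, keep])
  graphics::plot(NA, xlim = range(t[keep]),
                 ylim = c(-offset, offset * length(ch)),
                 xlab = "time (s)", ylab = "", yaxt = "n", ...)
  for (i in seq_along(ch))
    graphics::lines(t[keep], x$samples[ch[i], keep] + offset * (length(ch) - i))
  invisible(x)
}

# time axis of a recording
rec_times <- function(rec) rec$t0 + (seq_len(ncol(rec$samples)) - 1) / rec$fs

# duration in seconds
rec_duration <- function(rec) ncol(rec$samples) / rec$fs

# pull one channel as a numeric vector
rec_channel <- function(rec, channel = 1L) {
  if (channel < 1 || channel > nrow(rec$samples))
    stop_param(sprintf("channel %d outside 1..%d", channel, nrow(rec$samples)))
  rec$samples[channel, ]
}

#' Write a recording as flat binary + JSON sidecar
#'
#' Samples are stored channel-major (all samples of channel 1, then channel 2,
#' ...) as little-endian float32 in `<prefix>.bin`; metadata (`fs_hz`,
#' `n_channels`, `depths_um`, `units`, `t0`) goes to `<prefix>.json`.
#'
#' @param rec an [recording()].
#' @param prefix file path without extension.
#' @return `prefix`, invisibly.
#' @export
write_recording <- function(rec, prefix) {
  stopifnot(inherits(rec, "ob_recording"))
  con <- file(paste0(prefix, ".bin"), "wb")
  on.exit(close(con))
  # channel-major: write each row contiguously
  writeBin(as.numeric(t(rec$samples)), con, size = 4L, endian = "little")
  meta <- list(fs_hz = rec$fs, n_channels = nrow(rec$samples),
               depths_um = if (is.null(rec$geometry)) NULL else rec$geometry$depths_um,
               units = rec$units, t0 = rec$t0,
               channel_labels = rec$channel_labels,
               n_samples = ncol(rec$samples))
  jsonlite::write_json(meta, paste0(prefix, ".json"), auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(prefix)
}

#' Read a recording written by [write_recording()]
#' @param prefix file path without extension.
#' @return an [recording()].
#' @export
read_recording <- function(prefix) {
  meta <- jsonlite::read_json(paste0(prefix, ".json"), simplifyVector = TRUE)
  n <- meta$n_channels * meta$n_samples
  con <- file(paste0(prefix, ".bin"), "rb")
  on.exit(close(con))
  x <- readBin(con, numeric(), n = n, size = 4L, endian = "little")
  samples <- matrix(x, nrow = meta$n_channels, byrow = TRUE)
  geom <- NULL
  if (!is.null(meta$depths_um) && length(meta$depths_um) >= 2) {
    d <- meta$depths_um
    geom <- probe_geometry(length(d), d[2] - d[1], d[1])
  }
  recording(samples, meta$fs_hz, geometry = geom,
            channel_labels = meta$channel_labels, t0 = meta$t0,
            units = meta$units)
}

#' Write / read a burst or spike event table as CSV
#'
#' Event tables are data frames with at least `onset_s`, `offset_s`, `peak_s`,
#' `channel`, `kind` columns.
#'
#' @param events event data frame.
#' @param path CSV file path.
#' @export
write_events <- function(events, path) {
  utils::write.csv(events, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_events
#' @export
read_events <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}
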