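#' Multi-channel physiological recording
#'
#' A `gcg_recording` bundles one or more uniformly sampled channels (e.g.
#' ECG lead II in mV and the cranio-caudal gyroscope component GCGy in
#' deg/s) with their common sampling rate. All channels must have the same
#' length and contain only finite values.
#'
#' @param channels Named list of numeric vectors, one per channel.
#' @param fs Sampling rate in Hz (positive scalar).
#' @param start_time_ms Time of the first sample in ms (default 0).
#' @param meta Optional free-form list of subject/source tags.
#'
#' @return An object of class `gcg_recording` with elements `channels`,
#'   `fs`, `start_time_ms` and `meta`.
#' @examples
#' rec <- gcg_recording(list(ecg = sin(1:100), gcgy = cos(1:100)), fs = 100)
#' rec
#' @export
gcg_recording <- function(channels, fs, start_time_ms = 0, meta = list()) {
  if (!is.list(channels) || is.null(names(channels)) ||
      any(!nzchar(names(channels))))
    stop("'channels' must be a named list of numeric vectors", call. = FALSE)
  if (!is.numeric(fs) || length(fs) != 1 || fs <= 0)
    stop("'fs' must be a positive scalar (Hz)", call. = FALSE)
  lens <- vapply(channels, length, integer(1))
  if (length(unique(lens)) > 1) {
    bad <- names(lens)[lens != lens[1]][1]
    stop(sprintf("channel '%s' has length %d, expected %d",
                 bad, lens[[bad]], lens[[1]]), call. = FALSE)
  }
  channels <- lapply(seq_along(channels), function(i)
    assert_numeric_vector(channels[[i]], names(channels)[i]))
  names(channels) <- names(lens)
  structure(list(channels = channels, fs = as.numeric(fs),
                 start_time_ms = as.numeric(start_time_ms), meta = meta),
            class = "gcg_recording")
}

#' @export
print.gcg_recording <- function(x, ...) {
  n <- length(x$channels[[1]])
  cat(sprintf("<gcg_recording> %d channel(s) [%s], %d samples @ %g Hz (%.2f s)\n",
              length(x$channels), paste(names(x$channels), collapse = ", "),
              n, x$fs, (n - 1) / x$fs))
  invisible(x)
}

#' Number of samples per channel
#' @param rec A [gcg_recording()].
#' @return Integer sample count.
#' @export
n_samples <- function(rec) length(rec$channels[[1]])

#' Ordered beat-event times
#'
#' A `beat_series` is a strictly increasing vector of event times in
#' milliseconds from recording start, tagged with the fiducial type:
#' `"R_PEAK"` (ECG R waves), `"NCC_PEAK"` (template-matching detections)
#' or `"GROUND_TRUTH"` (simulated fiducials). Empty series are allowed.
#'
#' @param times_ms Numeric vector of non-negative, strictly increasing
#'   event times (ms).
#' @param label One of `"R_PEAK"`, `"NCC_PEAK"`, `"GROUND_TRUTH"`.
#' @return An object of class `beat_series`.
#' @examples
#' beat_series(c(500, 1300, 2100), "R_PEAK")
#' @export
beat_series <- function(times_ms, label = c("R_PEAK", "NCC_PEAK", "GROUND_TRUTH")) {
  label <- match.arg(label)
  times_ms <- as.numeric(times_ms)
  if (length(times_ms)) {
    if (anyNA(times_ms) || any(!is.finite(times_ms)))
      stop("beat times must be finite", call. = FALSE)
    if (any(times_ms < 0))
      stop("beat times must be non-negative", call. = FALSE)
    if (any(diff(times_ms) <= 0))
      stop("beat times must be strictly increasing", call. = FALSE)
  }
  structure(list(times_ms = times_ms, label = label), class = "beat_series")
}

#' @export
print.beat_series <- function(x, ...) {
  cat(sprintf("<beat_series> %d %s events", length(x$times_ms), x$label))
  if (length(x$times_ms) >= 2)
    cat(sprintf(", span %.0f-%.0f ms", min(x$times_ms), max(x$times_ms)))
  cat("\n")
  invisible(x)
}

#' @export
length.beat_series <- function(x) length(x$times_ms)

#' Read a recording from a delimited-text file
#'
#' The canonical on-disk format is a CSV with a header row; each requested
#' channel is a column. An optional `time_ms` column is ignored for sample
#' values (the grid is assumed uniform at `fs`).
#'
#' @param path Path to a CSV file.
#' @param channels Character vector of required channel column names.
#' @param fs Declared sampling rate in Hz.
#' @inheritParams gcg_recording
#' @return A [gcg_recording()].
#' @seealso [write_recording()]
#' @export
read_recording <- function(path, channels = c("ecg", "gcgy"), fs,
                           start_time_ms = 0, meta = list()) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  df <- read.csv(path, check.names = FALSE)
  missing <- setdiff(channels, names(df))
  if (length(missing))
    stop(sprintf("channel(s) not found in %s: %s", path,
                 paste(missing, collapse = ", ")), call. = FALSE)
  gcg_recording(stats::setNames(lapply(channels, function(ch) df[[ch]]), channels),
                fs = fs, start_time_ms = start_time_ms,
                meta = c(meta, list(source = path)))
}

#' Write a recording to CSV
#'
#' Writes a `time_ms` column plus one column per channel. Values are
#' written with full double precision so that a read/write round trip
#' reproduces the samples to better than 1e-9 relative error.
#'
#' @param rec A [gcg_recording()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_recording <- function(rec, path) {
  stopifnot(inherits(rec, "gcg_recording"))
  n <- n_samples(rec)
  df <- data.frame(time_ms = format(rec$start_time_ms + idx_to_ms(seq_len(n), rec$fs),
                                    digits = 17, trim = TRUE, scientific = FALSE))
  for (ch in names(rec$channels))
    df[[ch]] <- format(rec$channels[[ch]], digits = 17, trim = TRUE)
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Linearly resample a recording to a higher rate
#'
#' Interpolates every channel onto the uniform grid `t_k = k / target_fs`,
#' `k = 0..floor(duration * target_fs)`, spanning the original duration
#' (no extrapolation); when the grid stops short of the final original
#' sample, that sample is appended so both endpoints are preserved
#' exactly. Typical use is oversampling 256/512 Hz recordings to the 1
#' kHz working rate to improve temporal resolution of fiducials.
#'
#' @param rec A [gcg_recording()].
#' @param target_fs Target sampling rate in Hz; must be at least `rec$fs`.
#' @return A [gcg_recording()] at `target_fs`.
#' @examples
#' rec <- gcg_recording(list(x = c(0, 1, 2)), fs = 2)
#' resample_linear(rec, 4)$channels$x
#' @export
resample_linear <- function(rec, target_fs) {
  stopifnot(inherits(rec, "gcg_recording"))
  if (!is.numeric(target_fs) || length(target_fs) != 1 || target_fs <= 0)
    stop("'target_fs' must be a positive scalar (Hz)", call. = FALSE)
  if (target_fs < rec$fs)
    stop("'target_fs' must not be below the recording rate (no decimation)",
         call. = FALSE)
  if (target_fs == rec$fs) return(rec)
  n <- n_samples(rec)
  duration <- (n - 1) / rec$fs
  t_old <- (seq_len(n) - 1) / rec$fs
  t_new <- seq(0, floor(duration * target_fs + 1e-9)) / target_fs
  t_new <- pmin(t_new, duration)   # clamp against fp overshoot
  # keep the exact final sample when the grid stops short of it
  if (tail(t_new, 1) < duration - 1e-12) t_new <- c(t_new, duration)
  ch <- lapply(rec$channels, function(x) approx(t_old, x, xout = t_new)$y)
  gcg_recording(ch, fs = target_fs, start_time_ms = rec$start_time_ms,
                meta = rec$meta)
}

#' Read/write beat annotations
#'
#' Annotation files are CSVs with columns `time_ms,label`, one event per
#' row; an empty series produces a header-only file.
#'
#' @param beats A [beat_series()].
#' @param path CSV path.
#' @return `write_beats()` returns `path` invisibly; `read_beats()` a
#'   [beat_series()].
#' @export
write_beats <- function(beats, path) {
  stopifnot(inherits(beats, "beat_series"))
  df <- data.frame(time_ms = format(beats$times_ms, digits = 17, trim = TRUE),
                   label = rep(beats$label, length(beats$times_ms)))
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_beats
#' @export
read_beats <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  df <- read.csv(path)
  if (!all(c("time_ms", "label") %in% names(df)))
    stop("annotation file must have columns time_ms,label", call. = FALSE)
  label <- if (nrow(df)) as.character(df$label[1]) else "R_PEAK"
  beat_series(df$time_ms, label)
}
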