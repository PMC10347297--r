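# Heartbeat localization by template matching: a single-beat template is
# slid over the band-passed GCG signal, the zero-normalized
# cross-correlation (NCC) is evaluated at every valid alignment, and
# heartbeats are reported at NCC local maxima passing a prominence
# threshold and a minimum mutual distance.

#' Single-heartbeat GCG template
#'
#' A waveform segment spanning one heartbeat -- ideally starting two or
#' three waves before the highest systolic peak, where wave amplitude is
#' well below the systolic magnitude, and ending after the last wave of
#' the diastolic complex. Provenance (source interval and channel) is kept
#' for reporting.
#'
#' @param samples Numeric waveform segment (>= 2 samples, non-constant).
#' @param fs Sampling rate in Hz.
#' @param start_ms,end_ms Interval of the segment in the source recording
#'   (ms).
#' @param channel Source channel label.
#' @return An object of class `gcg_template`.
#' @export
gcg_template <- function(samples, fs, start_ms = NA_real_, end_ms = NA_real_,
                         channel = "gcgy") {
  samples <- assert_numeric_vector(samples, "samples")
  if (length(samples) < 2)
    stop("template must have at least 2 samples", call. = FALSE)
  if (var(samples) == 0)
    stop("template has zero variance (constant segment)", call. = FALSE)
  structure(list(samples = samples, fs = as.numeric(fs),
                 start_ms = start_ms, end_ms = end_ms, channel = channel),
            class = "gcg_template")
}

#' @export
print.gcg_template <- function(x, ...) {
  cat(sprintf("<gcg_template> %d samples @ %g Hz (%.0f ms), channel '%s'",
              length(x$samples), x$fs,
              (length(x$samples) - 1) / x$fs * 1000, x$channel))
  if (!is.na(x$start_ms))
    cat(sprintf(", from [%.0f, %.0f] ms", x$start_ms, x$end_ms))
  cat("\n")
  invisible(x)
}

# Sample index (0-based offset) of the template's systolic anchor: the
# maximum-absolute sample. NCC-peak times are reported at alignment +
# anchor so they are comparable across templates and to ground truth.
#' @noRd
template_anchor_offset <- function(template) {
  which.max(abs(template$samples)) - 1L
}

#' Carve a template from a recording
#'
#' Extracts the segment `[start_ms, end_ms]` (inclusive, sample-aligned)
#' of a channel. The recording should already be preprocessed (see
#' [preprocess_gcg()]); the template is used as-is.
#'
#' @param rec A [gcg_recording()].
#' @param channel Channel label to carve from.
#' @param start_ms,end_ms Template interval in ms; `end_ms > start_ms`,
#'   both within the recording.
#' @return A [gcg_template()].
#' @export
select_template <- function(rec, channel, start_ms, end_ms) {
  stopifnot(inherits(rec, "gcg_recording"))
  if (!channel %in% names(rec$channels))
    stop(sprintf("channel '%s' not present in recording", channel), call. = FALSE)
  if (end_ms <= start_ms)
    stop("'end_ms' must be greater than 'start_ms'", call. = FALSE)
  n <- n_samples(rec)
  i0 <- ms_to_idx(start_ms, rec$fs)
  i1 <- ms_to_idx(end_ms, rec$fs)
  if (i0 < 1 || i1 > n)
    stop(sprintf("template interval [%g, %g] ms outside recording (0..%g ms)",
                 start_ms, end_ms, idx_to_ms(n, rec$fs)), call. = FALSE)
  gcg_template(rec$channels[[channel]][i0:i1], fs = rec$fs,
               start_ms = start_ms, end_ms = end_ms, channel = channel)
}

#' NCC peak-picking parameters
#'
#' @param min_prominence Minimum topographic prominence of an NCC peak
#'   (dimensionless, in `(0, 2]`; default 0.5).
#' @param min_distance_ms Minimum distance between retained peaks in ms
#'   (default 500).
#' @return An object of class `peak_params`.
#' @export
peak_params <- function(min_prominence = 0.5, min_distance_ms = 500) {
  if (!(min_prominence > 0 && min_prominence <= 2))
    stop("'min_prominence' must be in (0, 2]", call. = FALSE)
  if (min_distance_ms <= 0)
    stop("'min_distance_ms' must be positive", call. = FALSE)
  structure(list(min_prominence = min_prominence,
                 min_distance_ms = min_distance_ms), class = "peak_params")
}

#' NCC series container
#'
#' Holds the normalized-cross-correlation coefficient per alignment: the
#' value at index `i` corresponds to the template aligned with the signal
#' window starting at sample `i`. All finite values lie in `[-1, 1]`.
#'
#' @param values Numeric NCC values.
#' @param fs Sampling rate in Hz.
#' @param anchor_offset_samples 0-based offset added to the alignment
#'   index when reporting beat times (the template's systolic anchor).
#' @return An object of class `ncc_series`.
#' @export
ncc_series <- function(values, fs, anchor_offset_samples = 0L) {
  values <- assert_numeric_vector(values, "values")
  if (length(values) && (max(values) > 1 + 1e-9 || min(values) < -1 - 1e-9))
    stop("NCC values must lie in [-1, 1]", call. = FALSE)
  structure(list(values = values, fs = as.numeric(fs),
                 anchor_offset_samples = as.integer(anchor_offset_samples)),
            class = "ncc_series")
}

#' Normalized cross-correlation of a template against a signal
#'
#' Computes the zero-normalized cross-correlation at every valid
#' alignment: for a template `w` of length `m` and signal window starting
#' at sample `i`,
#' \deqn{NCC(i) = \frac{\sum_k (x_{i+k} - \bar x_i)(w_k - \bar w)}
#'   {\sqrt{\sum_k (x_{i+k} - \bar x_i)^2 \sum_k (w_k - \bar w)^2}}}
#' with the local window mean \eqn{\bar x_i} removed, so the result is
#' invariant to positive affine transforms of the signal and bounded in
#' \eqn{[-1, 1]}. Windows with zero variance return 0 by convention. The
#' cross term is evaluated by FFT, the window moments by running sums.
#'
#' @param x Signal sample vector (length >= template length).
#' @param template A [gcg_template()] (or plain numeric vector).
#' @param fs Sampling rate in Hz; defaults to the template's.
#' @return An object of class `ncc_series` with elements `values` (length
#'   `length(x) - m + 1`; value at index `i` corresponds to the window
#'   starting at sample `i`), `fs` and `anchor_offset_samples`.
#' @export
ncc <- function(x, template, fs = NULL) {
  if (!inherits(template, "gcg_template"))
    template <- gcg_template(template, fs = fs %||% 1)
  fs <- fs %||% template$fs
  x <- assert_numeric_vector(x, "x")
  w <- template$samples
  m <- length(w)
  n <- length(x)
  if (m > n) stop("template is longer than the signal", call. = FALSE)
  xc <- x - mean(x)                 # global centering improves conditioning
  wc <- w - mean(w)
  ssw <- sum(wc^2)
  L <- n - m + 1L

  # cross-correlation sum_k x[i+k-1] * wc[k] via FFT convolution
  N <- nextn(n + m - 1L, 2)
  X <- fft(c(xc, rep(0, N - n)))
  W <- fft(c(rev(wc), rep(0, N - m)))
  conv <- Re(fft(X * W, inverse = TRUE)) / N
  cross <- conv[m:(m + L - 1L)]

  cs <- c(0, cumsum(xc))
  cs2 <- c(0, cumsum(xc^2))
  S <- cs[(m + 1):(m + L)] - cs[1:L]
  S2 <- cs2[(m + 1):(m + L)] - cs2[1:L]
  varx <- pmax(S2 - S^2 / m, 0)

  # zero-variance guard scaled to the worst-case running-sum cancellation
  tol <- 8 * .Machine$double.eps * n * max(abs(xc), 1e-300)^2
  den <- sqrt(varx * ssw)
  vals <- ifelse(varx <= tol, 0, cross / den)
  vals <- pmin(1, pmax(-1, vals))
  ncc_series(vals, fs, template_anchor_offset(template))
}

#' @export
print.ncc_series <- function(x, ...) {
  cat(sprintf("<ncc_series> %d alignments @ %g Hz, range [%.3f, %.3f]\n",
              length(x$values), x$fs, min(x$values), max(x$values)))
  invisible(x)
}

#' Pick heartbeat peaks from an NCC series
#'
#' Identifies strict local maxima, computes their topographic prominence
#' (height above the higher of the two bases reached before strictly
#' higher ground or the series edge), discards peaks below
#' `min_prominence`, and greedily retains peaks in descending height order
#' (ties: earlier index first) subject to a pairwise spacing of at least
#' `min_distance_ms`. Returned times are the alignment index plus the
#' template's systolic-anchor offset, in ms.
#'
#' @param nccs An [ncc()] result.
#' @param params A [peak_params()].
#' @return A [beat_series()] with label `"NCC_PEAK"` (possibly empty).
#' @export
detect_ncc_peaks <- function(nccs, params = peak_params()) {
  stopifnot(inherits(nccs, "ncc_series"), inherits(params, "peak_params"))
  v <- nccs$values
  idx <- cpp_local_maxima(v)
  if (!length(idx)) return(beat_series(numeric(0), "NCC_PEAK"))
  prom <- cpp_peak_prominence(v, idx)
  idx <- idx[prom >= params$min_prominence]
  if (!length(idx)) return(beat_series(numeric(0), "NCC_PEAK"))
  min_dist <- params$min_distance_ms / 1000 * nccs$fs
  ord <- idx[order(-v[idx], idx)]
  kept <- integer(0)
  for (p in ord) {
    if (!length(kept) || all(abs(p - kept) >= min_dist - 1e-9))
      kept <- c(kept, p)
  }
  kept <- sort(kept)
  beat_series(idx_to_ms(kept + nccs$anchor_offset_samples, nccs$fs), "NCC_PEAK")
}

#' Detect heartbeats in a raw GCG signal
#'
#' Full detection chain: 7--30 Hz zero-phase band-pass
#' ([preprocess_gcg()]), NCC against the template ([ncc()]), constrained
#' peak picking ([detect_ncc_peaks()]), and refinement of each detection
#' onto the local systolic maximum of the band-passed waveform. The
#' refinement step exists because the delay between an NCC peak and the
#' beat's actual AO peak varies with beat-to-beat morphology, which
#' inflates inter-beat-interval error; snapping to the waveform maximum
#' (exactly as R peaks are snapped on the ECG side) makes the fiducial
#' the AO peak itself. Set `refine_ms = 0` to keep raw NCC-alignment
#' times.
#'
#' @param gcg_raw Raw GCG sample vector.
#' @param fs Sampling rate in Hz.
#' @param template A [gcg_template()] carved from the *preprocessed*
#'   signal at the same rate.
#' @param params A [peak_params()].
#' @param refine_ms Half-width (ms) of the waveform-refinement window
#'   (default 40; 0 disables).
#' @return A [beat_series()] of NCC-peak times.
#' @export
detect_heartbeats <- function(gcg_raw, fs, template, params = peak_params(),
                              refine_ms = 40) {
  stopifnot(inherits(template, "gcg_template"))
  if (!isTRUE(all.equal(fs, template$fs)))
    stop("template sampling rate does not match the signal", call. = FALSE)
  y <- preprocess_gcg(gcg_raw, fs)
  beats <- detect_ncc_peaks(ncc(y, template, fs = fs), params)
  if (refine_ms > 0 && length(beats))
    beats <- refine_rpeaks(y, fs, beats, window_ms = refine_ms)
  beats
}

# Smoothed amplitude envelope: moving mean of |x| over ~window_ms,
# rescaled by pi/2 so a pure sinusoid's envelope equals its amplitude.
#' @noRd
amp_envelope <- function(x, fs, window_ms = 40) {
  w <- max(3L, round(window_ms / 1000 * fs))
  if (w %% 2 == 0) w <- w + 1L
  e <- as.numeric(stats::filter(abs(x), rep(1 / w, w), sides = 2))
  e[is.na(e)] <- 0
  e * pi / 2
}

#' Suggest a heartbeat template automatically
#'
#' Heuristic implementation of the manual selection guideline: locate the
#' globally dominant positive systolic peak; walk backward over local
#' extrema until their amplitude drops below 30% of the systolic
#' magnitude and step back past one or two zero crossings for the template
#' start; walk forward, locate the diastolic complex as the next
#' oscillation burst whose envelope exceeds 20% of the systolic magnitude,
#' and end one zero crossing after its last excursion, capped at
#' `min(0.9 * median RR, 700 ms)` past the systolic peak.
#'
#' These thresholds are validated on synthetic signals only; on real
#' recordings manual selection via [select_template()] remains the
#' reference procedure.
#'
#' @param gcg Preprocessed GCG sample vector (>= 3 s).
#' @param fs Sampling rate in Hz.
#' @param rr_hint_ms Optional RR-interval estimate in ms; when absent it
#'   is estimated from the envelope autocorrelation.
#' @param min_peak_factor Minimum ratio of the systolic peak to the median
#'   absolute signal amplitude for the peak to qualify (default 10); a
#'   beat-free signal (stationary noise) stays near 7 while quasi-periodic
#'   beat trains with quiet diastasis exceed it by an order of magnitude.
#'   Below the threshold an error is raised.
#' @return A [gcg_template()].
#' @export
suggest_template <- function(gcg, fs, rr_hint_ms = NULL, min_peak_factor = 10) {
  x <- assert_numeric_vector(gcg, "gcg")
  n <- length(x)
  if (n < 3 * fs)
    stop("signal must be at least 3 s long for template suggestion", call. = FALSE)
  p <- which.max(x)
  mag <- x[p]
  if (!(mag > 0) || mag < min_peak_factor * median(abs(x)))
    stop(paste("no qualifying systolic peak found;",
               "select the template manually with select_template()"),
         call. = FALSE)

  sgn <- ifelse(x >= 0, 1, -1)
  zc <- which(diff(sgn) != 0)   # crossing between sample i and i+1

  # backward: local extrema of |x| before the systolic peak
  ext <- cpp_local_maxima(abs(x))
  ext_b <- rev(ext[ext < p])
  e0 <- NA_integer_
  for (e in ext_b) {
    if (p - e > 0.25 * fs) break   # do not walk into the previous beat
    if (abs(x[e]) < 0.3 * mag) { e0 <- e; break }
  }
  if (is.na(e0)) e0 <- max(1L, p - as.integer(round(0.10 * fs)))
  back <- zc[zc < e0 & zc > e0 - 0.06 * fs]
  start <- if (length(back) >= 2) back[length(back) - 1L]
           else if (length(back) == 1) back[1]
           else max(1L, e0 - as.integer(round(0.02 * fs)))

  # forward: find the diastolic burst on the envelope
  env <- amp_envelope(x, fs)
  rr_est <- rr_hint_ms %||% estimate_rr_ms(env, fs)
  cap <- min(0.9 * rr_est, 700)
  cap_idx <- min(n, p + as.integer(round(cap / 1000 * fs)))
  seg <- env[p:cap_idx]
  below <- which(seg < 0.2 * mag)
  if (length(below)) {
    g <- p + below[1] - 1L
    # first envelope excursion above threshold after the gap = the
    # diastolic burst; stop at its trailing edge so a following beat
    # inside the cap never extends the template
    above <- env[g:cap_idx] >= 0.2 * mag
    d0 <- which(above)[1]
    if (!is.na(d0)) {
      d1 <- which(!above & seq_along(above) > d0)[1]
      last_d <- g + (if (is.na(d1)) length(above) else d1 - 1L) - 1L
    } else {
      last_d <- g
    }
  } else {
    last_d <- cap_idx
  }
  fwd <- zc[zc > last_d & zc < last_d + 0.05 * fs]
  end <- if (length(fwd)) fwd[1] + 1L
         else min(n, last_d + as.integer(round(0.02 * fs)))
  if (end <= start + 1L) end <- min(n, start + as.integer(round(0.3 * fs)))

  gcg_template(x[start:end], fs = fs,
               start_ms = idx_to_ms(start, fs), end_ms = idx_to_ms(end, fs))
}

# Median RR estimate (ms) from the envelope autocorrelation, searched in
# the 400-2000 ms lag range.
#' @noRd
estimate_rr_ms <- function(env, fs, lo_ms = 400, hi_ms = 2000) {
  dec <- max(1L, as.integer(round(fs / 100)))   # ~100 Hz is ample
  e <- env[seq(1, length(env), by = dec)]
  fsd <- fs / dec
  e <- e - mean(e)
  lo <- as.integer(round(lo_ms / 1000 * fsd))
  hi <- min(length(e) - 2L, as.integer(round(hi_ms / 1000 * fsd)))
  if (hi <= lo) return(800)
  ac <- vapply(lo:hi, function(k) {
    a <- e[1:(length(e) - k)]; b <- e[(k + 1):length(e)]
    sum(a * b)
  }, numeric(1))
  (lo + which.max(ac) - 1) / fsd * 1000
}
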