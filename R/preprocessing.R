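# Filtering chain: zero-phase Butterworth band-passes for ECG (0.5-40 Hz)
# and GCG (7-30 Hz), plus a comb notch for powerline interference. All
# filters are applied forward-backward so fiducial timing is undistorted.

# Steady-state initial filter state (direct-form II transposed) for a unit
# step input; scaled by the first sample to suppress edge transients.
#' @noRd
filter_zi <- function(b, a) {
  n <- max(length(b), length(a))
  b <- c(b, rep(0, n - length(b)))
  a <- c(a, rep(0, n - length(a)))
  b <- b / a[1]
  a <- a / a[1]
  if (n == 1) return(numeric(0))
  comp <- matrix(0, n - 1, n - 1)
  comp[1, ] <- -a[-1]
  if (n > 2) comp[cbind(2:(n - 1), 1:(n - 2))] <- 1
  B <- b[-1] - a[-1] * b[1]
  M <- diag(n - 1) - t(comp)
  # near-singular for very low normalized band edges; least squares is fine
  # because any bounded steady state suppresses the edge transient
  zi <- tryCatch(solve(M, B), error = function(e)
    qr.coef(qr(M, LAPACK = TRUE), B))
  zi[!is.finite(zi)] <- 0
  as.numeric(zi)
}

# Forward-backward IIR filtering with odd-symmetric signal extension of
# length 3*(nfilt-1) at each end and steady-state initial conditions
# (the MATLAB/SciPy filtfilt convention).
#' @noRd
filtfilt_pad <- function(b, a, x) {
  nfilt <- max(length(b), length(a))
  pad <- 3L * (nfilt - 1L)
  n <- length(x)
  if (n <= pad)
    stop(sprintf("signal too short for zero-phase filtering (need > %d samples)",
                 pad), call. = FALSE)
  ext <- c(2 * x[1] - x[(pad + 1):2], x, 2 * x[n] - x[(n - 1):(n - pad)])
  zi <- filter_zi(b, a)
  y <- cpp_iir_filter(b, a, ext, zi * ext[1])
  y <- rev(y)
  y <- cpp_iir_filter(b, a, y, zi * y[1])
  y <- rev(y)
  y[(pad + 1):(pad + n)]
}

# Butterworth band-pass in second-order sections (zpk design: analog
# prototype poles, band-pass transform, bilinear), the numerically robust
# form for narrow normalized bands where the expanded (b, a) polynomial
# is ill-conditioned. Returns list(sos = list of list(b, a), gain).
#' @noRd
butter_bandpass_sos <- function(fs, low_hz, high_hz, order) {
  # analog lowpass prototype poles (unit cutoff, left half-plane)
  k <- seq_len(order)
  p_proto <- exp(1i * pi * (2 * k + order - 1) / (2 * order))
  # prewarped band edges and lowpass->bandpass transform
  w1 <- 2 * fs * tan(pi * low_hz / fs)
  w2 <- 2 * fs * tan(pi * high_hz / fs)
  B <- w2 - w1
  w0 <- sqrt(w1 * w2)
  disc <- sqrt((B * p_proto)^2 / 4 - w0^2 + 0i)
  s_poles <- c(B * p_proto / 2 + disc, B * p_proto / 2 - disc)
  # bilinear transform
  z_poles <- (2 * fs + s_poles) / (2 * fs - s_poles)
  gain <- Re(B^order * (2 * fs)^order / prod(2 * fs - s_poles))
  # pair poles into conjugate biquads, each with zeros at z = +1 and -1
  upper <- z_poles[Im(z_poles) >= 0]
  upper <- upper[order(Re(upper))]
  sos <- lapply(upper, function(zp) {
    list(b = c(1, 0, -1),
         a = c(1, -2 * Re(zp), abs(zp)^2))
  })
  list(sos = sos, gain = gain)
}

# Zero-phase application of an SOS cascade: each pass runs every biquad
# with its own steady-state initial state over an odd-extended signal.
#' @noRd
sos_filtfilt <- function(sosg, x) {
  pad <- 3L * (2L * length(sosg$sos) + 1L)
  n <- length(x)
  if (n <= pad)
    stop(sprintf("signal too short for zero-phase filtering (need > %d samples)",
                 pad), call. = FALSE)
  one_pass <- function(v) {
    for (sec in sosg$sos) {
      zi <- filter_zi(sec$b, sec$a)
      v <- cpp_iir_filter(sec$b, sec$a, v, zi * v[1])
    }
    v * sosg$gain
  }
  ext <- c(2 * x[1] - x[(pad + 1):2], x, 2 * x[n] - x[(n - 1):(n - pad)])
  y <- rev(one_pass(ext))
  y <- rev(one_pass(y))
  y[(pad + 1):(pad + n)]
}

#' Zero-phase Butterworth band-pass filter
#'
#' Designs an `order`-th order Butterworth band-pass and applies it
#' forward-backward (zero phase; effective magnitude response of twice the
#' design order). Edge transients are controlled by odd-symmetric signal
#' extension and steady-state initial conditions.
#'
#' @param x Numeric sample vector.
#' @param fs Sampling rate in Hz.
#' @param low_hz,high_hz Band edges in Hz; `0 < low_hz < high_hz < fs/2`.
#' @param order Design order of the Butterworth prototype (default 4).
#' @return Filtered vector, same length as `x`.
#' @examples
#' t <- seq(0, 2, by = 1e-3)
#' y <- butter_bandpass_zerophase(sin(2 * pi * 15 * t), 1000, 7, 30)
#' @export
butter_bandpass_zerophase <- function(x, fs, low_hz, high_hz, order = 4) {
  x <- assert_numeric_vector(x, "x")
  if (!(low_hz > 0 && low_hz < high_hz && high_hz < fs / 2))
    stop("band edges must satisfy 0 < low_hz < high_hz < fs/2", call. = FALSE)
  if (order < 1) stop("'order' must be >= 1", call. = FALSE)
  sos_filtfilt(butter_bandpass_sos(fs, low_hz, high_hz, order), x)
}

# Biquad notch coefficients at normalized frequency w0 with bandwidth set
# by alpha (RBJ audio-EQ cookbook form).
#' @noRd
notch_biquad <- function(f0, fs, bw_hz) {
  w0 <- 2 * pi * f0 / fs
  alpha <- sin(w0) / (2 * (f0 / bw_hz))
  b <- c(1, -2 * cos(w0), 1)
  a <- c(1 + alpha, -2 * cos(w0), 1 - alpha)
  list(b = b / a[1], a = a / a[1])
}

#' Comb notch filter for powerline interference
#'
#' Removes a powerline fundamental (default 50 Hz) and all of its
#' harmonics below Nyquist with a cascade of narrow zero-phase IIR
#' notches. Each tooth has the same absolute bandwidth `base_hz / q`, so
#' content more than a few Hz away from any harmonic is preserved.
#'
#' @param x Numeric sample vector.
#' @param fs Sampling rate in Hz.
#' @param base_hz Notch fundamental in Hz (default 50); must be below
#'   `fs/2`.
#' @param q Quality factor of the fundamental tooth (default 35, i.e.
#'   about 1.4 Hz bandwidth at 50 Hz).
#' @return Filtered vector, same length as `x`.
#' @export
comb_notch <- function(x, fs, base_hz = 50, q = 35) {
  x <- assert_numeric_vector(x, "x")
  if (base_hz <= 0 || base_hz >= fs / 2)
    stop("'base_hz' must lie in (0, fs/2)", call. = FALSE)
  if (q <= 0) stop("'q' must be positive", call. = FALSE)
  bw <- base_hz / q
  harmonics <- seq(base_hz, fs / 2 - 1e-9, by = base_hz)
  harmonics <- harmonics[harmonics < fs / 2 - bw]
  y <- x
  for (f0 in harmonics) {
    ba <- notch_biquad(f0, fs, bw)
    y <- filtfilt_pad(ba$b, ba$a, y)
  }
  y
}

#' Standard preprocessing of the ECG channel
#'
#' Zero-phase 4th-order Butterworth band-pass 0.5--40 Hz followed by a
#' 50 Hz comb notch, the conditioning applied before R-peak detection.
#'
#' @param x ECG sample vector.
#' @param fs Sampling rate in Hz (>= 100).
#' @param powerline_hz Powerline fundamental (default 50 Hz).
#' @return Filtered ECG, same length.
#' @export
preprocess_ecg <- function(x, fs, powerline_hz = 50) {
  if (fs < 100) stop("'fs' must be at least 100 Hz", call. = FALSE)
  y <- butter_bandpass_zerophase(x, fs, 0.5, 40, order = 4)
  comb_notch(y, fs, base_hz = powerline_hz)
}

#' Standard preprocessing of the GCG channel
#'
#' Zero-phase 4th-order Butterworth band-pass 7--30 Hz, the band that
#' retains the systolic and diastolic oscillatory complexes while
#' rejecting respiration and high-frequency noise.
#'
#' @param x GCG sample vector.
#' @param fs Sampling rate in Hz (>= 100).
#' @return Filtered GCG, same length.
#' @export
preprocess_gcg <- function(x, fs) {
  if (fs < 100) stop("'fs' must be at least 100 Hz", call. = FALSE)
  butter_bandpass_zerophase(x, fs, 7, 30, order = 4)
}
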