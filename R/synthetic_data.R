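# Synthetic paired ECG+GCG generator with exact ground truth. The GCG
# beat is modelled as two Hann-windowed sinusoid bursts -- a systolic
# complex near aortic valve opening and a smaller, later diastolic
# complex -- in the 10-25 Hz band the detector assumes, with per-beat
# morphology jitter, a variable R-to-AO delay, respiratory amplitude
# modulation and additive white Gaussian noise at a configurable SNR.

#' Configuration for the synthetic ECG+GCG generator
#'
#' Defaults describe a resting supine adult: heart rate 75 bpm (mean RR
#' 800 ms), SDNN 50 ms, R-to-AO delay 100 ms with 3 ms beat-to-beat
#' jitter, an 18 Hz / 120 ms systolic complex, a 15 Hz / 100 ms diastolic
#' complex at 60% relative amplitude starting 320 ms after systolic
#' onset, 5% per-beat morphology jitter, respiration at 0.25 Hz with 20%
#' amplitude modulation, and 10 dB SNR.
#'
#' @param n_beats Number of beats.
#' @param mean_rr_ms,sdnn_ms RR-interval mean and standard deviation (ms);
#'   intervals are Gaussian truncated at mean +/- 4 SD.
#' @param fs Sampling rate in Hz.
#' @param r_ao_delay_ms,r_ao_jitter_ms Mean and SD (ms) of the delay from
#'   the ECG R peak to the GCG systolic anchor (AO peak).
#' @param sys_freq_hz,sys_dur_ms Systolic-complex carrier frequency and
#'   duration.
#' @param dia_freq_hz,dia_dur_ms Diastolic-complex carrier frequency and
#'   duration.
#' @param dia_delay_ms Diastolic-complex onset after systolic onset (ms).
#' @param dia_rel_amp Diastolic amplitude relative to systolic (in (0,1)).
#' @param morphology_jitter Fractional per-beat SD of burst amplitude and
#'   frequency.
#' @param resp_rate_hz,resp_mod_depth Respiratory amplitude-modulation
#'   rate and depth.
#' @param snr_db Additive white Gaussian noise level, defined against the
#'   clean signal RMS (`Inf` = noise-free).
#' @param seed RNG seed (`NULL` = use the current stream).
#' @return An object of class `synth_config`.
#' @export
synth_config <- function(n_beats = 200, mean_rr_ms = 800, sdnn_ms = 50,
                         fs = 1000,
                         r_ao_delay_ms = 100, r_ao_jitter_ms = 3,
                         sys_freq_hz = 18, sys_dur_ms = 120,
                         dia_freq_hz = 15, dia_dur_ms = 100,
                         dia_delay_ms = 320, dia_rel_amp = 0.6,
                         morphology_jitter = 0.05,
                         resp_rate_hz = 0.25, resp_mod_depth = 0.2,
                         snr_db = 10, seed = NULL) {
  cfg <- as.list(environment())
  if (cfg$mean_rr_ms <= 2 * (cfg$sys_dur_ms + cfg$dia_dur_ms))
    stop("mean_rr_ms too short for the configured complex durations",
         call. = FALSE)
  if (cfg$mean_rr_ms <= 4 * cfg$sdnn_ms)
    stop("mean_rr_ms must exceed 4 * sdnn_ms", call. = FALSE)
  if (!(cfg$dia_rel_amp > 0 && cfg$dia_rel_amp < 1))
    stop("dia_rel_amp must be in (0, 1)", call. = FALSE)
  rates <- c(cfg$sys_freq_hz, cfg$dia_freq_hz, cfg$resp_rate_hz)
  if (any(rates >= cfg$fs / 2)) stop("all rates must be below fs/2", call. = FALSE)
  structure(cfg, class = "synth_config")
}

#' Generate a quasi-periodic RR-interval train
#'
#' Draws `n` intervals from Normal(mean, sdnn) truncated at mean +/- 4
#' sdnn (white heart-rate variability; no autocorrelation is modelled).
#'
#' @param n Number of intervals.
#' @param mean_rr_ms,sdnn_ms Mean and SD in ms; `mean_rr_ms > 4 * sdnn_ms`.
#' @param seed RNG seed.
#' @return Numeric vector of `n` intervals (ms).
#' @export
generate_rr <- function(n, mean_rr_ms = 800, sdnn_ms = 50, seed = NULL) {
  if (n < 0 || n != round(n)) stop("'n' must be a non-negative integer", call. = FALSE)
  if (sdnn_ms < 0) stop("'sdnn_ms' must be non-negative", call. = FALSE)
  if (mean_rr_ms <= 4 * sdnn_ms)
    stop("'mean_rr_ms' must exceed 4 * sdnn_ms", call. = FALSE)
  with_seed(seed, {
    rr <- rnorm(n, mean_rr_ms, sdnn_ms)
    bad <- which(abs(rr - mean_rr_ms) > 4 * sdnn_ms)
    while (length(bad)) {
      rr[bad] <- rnorm(length(bad), mean_rr_ms, sdnn_ms)
      bad <- bad[abs(rr[bad] - mean_rr_ms) > 4 * sdnn_ms]
    }
    rr
  })
}

# R-peak times (ms, snapped to the sample grid) from an RR train; the
# first beat sits at t0 and the recording extends one mean RR past the
# last beat.
#' @noRd
beat_times_from_rr <- function(rr, fs, t0_ms = 1000) {
  if (!length(rr)) return(numeric(0))
  t <- t0_ms + c(0, cumsum(rr[-length(rr)]))
  idx_to_ms(ms_to_idx(t, fs), fs)
}

# Gaussian bump helper for the ECG waveform.
#' @noRd
gauss_bump <- function(t_ms, center_ms, sigma_ms) {
  exp(-((t_ms - center_ms)^2) / (2 * sigma_ms^2))
}

#' Synthesize an ECG beat train
#'
#' Each beat is a narrow positive R spike (Gaussian, sigma 10 ms) with
#' small Q/S dips, a P hump 180 ms before and a T hump 300 ms after the R
#' peak; the recorded R time is exactly the spike apex sample. White
#' Gaussian noise is added at `snr_db` relative to the clean RMS.
#'
#' @param rr RR-interval train in ms (see [generate_rr()]).
#' @param fs Sampling rate in Hz (>= 250).
#' @param snr_db Noise level (`Inf` = clean).
#' @param seed RNG seed for the noise.
#' @param t0_ms Time of the first R peak (default 1000 ms).
#' @return List with `signal` (numeric vector) and `r_times_ms`.
#' @export
synth_ecg <- function(rr, fs = 1000, snr_db = Inf, seed = NULL, t0_ms = 1000) {
  if (fs < 250) stop("'fs' must be at least 250 Hz", call. = FALSE)
  r_times <- beat_times_from_rr(rr, fs, t0_ms)
  dur_ms <- if (length(rr)) t0_ms + sum(rr) + 500 else 5000
  n <- ms_to_idx(dur_ms, fs)
  t_ms <- idx_to_ms(seq_len(n), fs)
  x <- numeric(n)
  for (r in r_times) {
    lo <- max(1L, ms_to_idx(r - 400, fs)); hi <- min(n, ms_to_idx(r + 450, fs))
    tt <- t_ms[lo:hi]
    x[lo:hi] <- x[lo:hi] +
      gauss_bump(tt, r, 10) -
      0.15 * gauss_bump(tt, r - 25, 8) -
      0.25 * gauss_bump(tt, r + 25, 8) +
      0.15 * gauss_bump(tt, r - 180, 25) +
      0.35 * gauss_bump(tt, r + 300, 60)
  }
  if (is.finite(snr_db)) {
    sd_noise <- rms(x) / 10^(snr_db / 20)
    x <- x + with_seed(seed, rnorm(n, 0, sd_noise))
  }
  list(signal = x, r_times_ms = r_times)
}

#' Synthesize a GCG beat train with ground truth
#'
#' For each R time the systolic anchor (AO peak) is placed at `R +
#' delay_j` with `delay_j ~ Normal(r_ao_delay_ms, r_ao_jitter_ms)`; a
#' Hann-windowed systolic sinusoid burst is centred so its largest
#' excursion falls on the anchor, followed by a lower-amplitude diastolic
#' burst. The clean signal is amplitude-modulated by `1 + depth *
#' sin(2 pi resp_rate t)` and white Gaussian noise is added at `snr_db`
#' (relative to the clean, pre-filter RMS).
#'
#' @param rr RR-interval train (ms), shared with [synth_ecg()] so the two
#'   channels are paired.
#' @param cfg A [synth_config()].
#' @param seed RNG seed; defaults to `cfg$seed`.
#' @param t0_ms Time of the first R peak (default 1000 ms).
#' @return List with `signal` and `truth`, a data frame with one row per
#'   beat: `r_ms`, `ao_ms`, `sys_onset_ms`, `dia_offset_ms`.
#' @export
synth_gcg <- function(rr, cfg = synth_config(), seed = NULL, t0_ms = 1000) {
  stopifnot(inherits(cfg, "synth_config"))
  seed <- seed %||% cfg$seed
  fs <- cfg$fs
  if (length(rr) &&
      min(rr) <= cfg$dia_delay_ms + cfg$dia_dur_ms + cfg$r_ao_jitter_ms * 4)
    stop("RR intervals too short: systolic/diastolic complexes would overlap",
         call. = FALSE)
  r_times <- beat_times_from_rr(rr, fs, t0_ms)
  dur_ms <- if (length(rr)) t0_ms + sum(rr) + 500 else 5000
  n <- ms_to_idx(dur_ms, fs)
  nb <- length(r_times)

  with_seed(seed, {
    delays <- rnorm(nb, cfg$r_ao_delay_ms, cfg$r_ao_jitter_ms)
    amp_j <- 1 + cfg$morphology_jitter * rnorm(nb)
    frq_j <- 1 + cfg$morphology_jitter * rnorm(nb)
    dia_amp_j <- 1 + cfg$morphology_jitter * rnorm(nb)

    x <- numeric(n)
    ao <- syson <- diaoff <- numeric(nb)
    for (j in seq_len(nb)) {
      f_sys <- cfg$sys_freq_hz * max(0.5, frq_j[j])
      f_dia <- cfg$dia_freq_hz * max(0.5, frq_j[j])
      m_sys <- max(4L, as.integer(round(cfg$sys_dur_ms / 1000 * fs)))
      m_dia <- max(4L, as.integer(round(cfg$dia_dur_ms / 1000 * fs)))
      tt_s <- (seq_len(m_sys) - 1) / fs
      tt_d <- (seq_len(m_dia) - 1) / fs
      hann_s <- 0.5 * (1 - cos(2 * pi * seq(0, 1, length.out = m_sys)))
      hann_d <- 0.5 * (1 - cos(2 * pi * seq(0, 1, length.out = m_dia)))
      # carrier extremum centred on the envelope maximum: one dominant
      # positive lobe (the AO peak), flanked by clearly smaller lobes
      burst_s <- max(0.1, amp_j[j]) *
        cos(2 * pi * f_sys * (tt_s - tt_s[m_sys] / 2)) * hann_s
      burst_d <- cfg$dia_rel_amp * max(0.1, dia_amp_j[j]) *
        cos(2 * pi * f_dia * (tt_d - tt_d[m_dia] / 2)) * hann_d
      pk <- which.max(abs(burst_s))          # anchor within the burst
      anchor_idx <- ms_to_idx(r_times[j] + delays[j], fs)
      on_idx <- anchor_idx - pk + 1L
      dia_on_idx <- on_idx + as.integer(round(cfg$dia_delay_ms / 1000 * fs))
      if (on_idx < 1L || dia_on_idx + m_dia - 1L > n) next
      x[on_idx:(on_idx + m_sys - 1L)] <-
        x[on_idx:(on_idx + m_sys - 1L)] + burst_s
      x[dia_on_idx:(dia_on_idx + m_dia - 1L)] <-
        x[dia_on_idx:(dia_on_idx + m_dia - 1L)] + burst_d
      syson[j] <- idx_to_ms(on_idx, fs)
      ao[j] <- idx_to_ms(anchor_idx, fs)
      diaoff[j] <- idx_to_ms(dia_on_idx + m_dia - 1L, fs)
    }
    t_s <- idx_to_ms(seq_len(n), fs) / 1000
    if (cfg$resp_mod_depth > 0)
      x <- x * (1 + cfg$resp_mod_depth * sin(2 * pi * cfg$resp_rate_hz * t_s))
    if (is.finite(cfg$snr_db)) {
      sd_noise <- rms(x) / 10^(cfg$snr_db / 20)
      x <- x + rnorm(n, 0, sd_noise)
    }
    keep <- ao > 0
    list(signal = x,
         truth = data.frame(r_ms = r_times[keep], ao_ms = ao[keep],
                            sys_onset_ms = syson[keep],
                            dia_offset_ms = diaoff[keep]))
  })
}

#' Generate a paired synthetic recording in memory
#'
#' Draws an RR train and synthesizes the paired ECG and GCG channels from
#' it. A pure function of `(cfg, seed)`.
#'
#' @param cfg A [synth_config()].
#' @param seed Overrides `cfg$seed` when given.
#' @return List with `recording` (a [gcg_recording()] with channels `ecg`
#'   and `gcgy`) and `truth` (data frame as in [synth_gcg()]).
#' @export
synth_recording <- function(cfg = synth_config(), seed = NULL) {
  stopifnot(inherits(cfg, "synth_config"))
  seed <- seed %||% cfg$seed
  if (is.null(seed)) seed <- 1L
  rr <- generate_rr(cfg$n_beats, cfg$mean_rr_ms, cfg$sdnn_ms, seed = seed)
  ecg <- synth_ecg(rr, fs = cfg$fs, snr_db = cfg$snr_db, seed = seed + 1L)
  gcg <- synth_gcg(rr, cfg, seed = seed + 2L)
  nmin <- min(length(ecg$signal), length(gcg$signal))
  rec <- gcg_recording(list(ecg = ecg$signal[seq_len(nmin)],
                            gcgy = gcg$signal[seq_len(nmin)]),
                       fs = cfg$fs, meta = list(synthetic = TRUE, seed = seed))
  list(recording = rec, truth = gcg$truth)
}

#' Write a synthetic dataset to disk
#'
#' Produces `rec.csv` (columns `time_ms,ecg,gcgy`), `truth_r.csv` and
#' `truth_ao.csv` (beat-annotation CSVs) plus `truth.csv` with the full
#' per-beat ground truth. Byte-identical for identical `(cfg, seed)`.
#'
#' @param cfg A [synth_config()].
#' @param dir Output directory (created if absent).
#' @param seed Overrides `cfg$seed` when given.
#' @return Named character vector of file paths, invisibly; the generated
#'   objects are attached as attribute `"data"`.
#' @export
generate_dataset <- function(cfg = synth_config(), dir, seed = NULL) {
  stopifnot(inherits(cfg, "synth_config"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  dat <- synth_recording(cfg, seed = seed)
  paths <- c(rec = file.path(dir, "rec.csv"),
             truth_r = file.path(dir, "truth_r.csv"),
             truth_ao = file.path(dir, "truth_ao.csv"),
             truth = file.path(dir, "truth.csv"))
  write_recording(dat$recording, paths[["rec"]])
  write_beats(beat_series(dat$truth$r_ms, "GROUND_TRUTH"), paths[["truth_r"]])
  write_beats(beat_series(dat$truth$ao_ms, "GROUND_TRUTH"), paths[["truth_ao"]])
  write.csv(dat$truth, paths[["truth"]], row.names = FALSE, quote = FALSE)
  structure(invisible(paths), data = dat)
}

#' Match detected beats against ground truth
#'
#' Greedy one-to-one matching: each true time claims the nearest unused
#' detection within `tol_ms`. Used to score detectors on synthetic data.
#'
#' @param detected,truth_ms Numeric vectors of times (ms); `detected` may
#'   be a [beat_series()].
#' @param tol_ms Matching half-window in ms.
#' @return List with `n_true`, `n_detected`, `matched` (count),
#'   `sensitivity_pct`, `ppv_pct`, and `errors_ms` (signed detected -
#'   true for matched pairs).
#' @export
match_beats <- function(detected, truth_ms, tol_ms = 50) {
  if (inherits(detected, "beat_series")) detected <- detected$times_ms
  used <- rep(FALSE, length(detected))
  err <- numeric(0)
  matched <- 0L
  for (tt in truth_ms) {
    if (!length(detected)) break
    d <- abs(detected - tt)
    d[used] <- Inf
    k <- which.min(d)
    if (length(k) && is.finite(d[k]) && d[k] <= tol_ms) {
      used[k] <- TRUE
      matched <- matched + 1L
      err <- c(err, detected[k] - tt)
    }
  }
  list(n_true = length(truth_ms), n_detected = length(detected),
       matched = matched,
       sensitivity_pct = if (length(truth_ms)) 100 * matched / length(truth_ms) else NA_real_,
       ppv_pct = if (length(detected)) 100 * matched / length(detected) else NA_real_,
       errors_ms = err)
}
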