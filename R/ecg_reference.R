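# Reference R-peak detection: classic Pan-Tompkins stages (QRS band-pass,
# derivative, squaring, moving-window integration, dual adaptive
# thresholds with search-back and T-wave rejection), followed by fiducial
# refinement onto the band-passed ECG so reported times are
# waveform-accurate.

#' Pan-Tompkins R-peak detection
#'
#' Detects QRS complexes in a (preprocessed) ECG with the classic
#' Pan-Tompkins stages: 5--15 Hz zero-phase band-pass, 5-point derivative,
#' squaring, 150 ms moving-window integration, and dual adaptive
#' signal/noise thresholds with a 200 ms refractory period, 360 ms T-wave
#' slope discrimination and missed-beat search-back. Each accepted
#' fiducial is then refined to the local maximum of the band-passed ECG
#' within \eqn{\pm}`refine_ms`.
#'
#' @param ecg ECG sample vector (any calibration; the detector is
#'   amplitude-adaptive).
#' @param fs Sampling rate in Hz (>= 200).
#' @param refractory_ms Minimum spacing between accepted beats (default
#'   200 ms).
#' @param refine_ms Half-width of the refinement window (default 40 ms).
#' @return A [beat_series()] of R-peak times (label `"R_PEAK"`). A flat
#'   signal yields an empty series.
#' @references Pan J., Tompkins W.J. (1985) A real-time QRS detection
#'   algorithm. IEEE Trans. Biomed. Eng. 32(3):230-236.
#' @export
pan_tompkins <- function(ecg, fs, refractory_ms = 200, refine_ms = 40) {
  ecg <- assert_numeric_vector(ecg, "ecg")
  if (fs < 200) stop("'fs' must be at least 200 Hz", call. = FALSE)
  n <- length(ecg)
  if (n < 2 * fs) stop("signal must be at least 2 s long", call. = FALSE)
  if (all(ecg == ecg[1]))
    return(beat_series(numeric(0), "R_PEAK"))

  bp <- butter_bandpass_zerophase(ecg, fs, 5, 15, order = 2)
  # centered 5-point derivative (zero lag)
  k <- c(1, 2, 0, -2, -1) / 8
  der <- as.numeric(stats::filter(bp, k, sides = 2))
  der[is.na(der)] <- 0
  sq <- der^2
  # centered moving-window integration, 150 ms
  w <- max(1L, round(0.150 * fs))
  if (w %% 2 == 0) w <- w + 1L
  mwi <- as.numeric(stats::filter(sq, rep(1 / w, w), sides = 2))
  mwi[is.na(mwi)] <- 0

  refractory <- round(refractory_ms / 1000 * fs)
  cand <- cpp_local_maxima(mwi)
  if (length(cand) == 0) return(beat_series(numeric(0), "R_PEAK"))
  # thin candidates: keep local maxima at least refractory/2 apart,
  # preferring the taller of close pairs
  keep <- logical(length(cand))
  ord <- order(mwi[cand], decreasing = TRUE)
  taken <- integer(0)
  for (i in ord) {
    if (!length(taken) || all(abs(cand[i] - taken) >= refractory %/% 2)) {
      keep[i] <- TRUE
      taken <- c(taken, cand[i])
    }
  }
  cand <- cand[keep]
  cand <- sort(cand)

  init_n <- min(n, round(2 * fs))
  spki <- max(mwi[seq_len(init_n)]) / 3
  npki <- mean(mwi[seq_len(init_n)]) / 2
  thr <- npki + 0.25 * (spki - npki)

  qrs <- integer(0)
  rr_avg <- NA_real_
  last_slope <- NA_real_
  slope_at <- function(i) {
    lo <- max(1L, i - round(0.075 * fs)); hi <- min(n, i + round(0.075 * fs))
    max(abs(der[lo:hi]))
  }
  for (i in seq_along(cand)) {
    p <- cand[i]; h <- mwi[p]
    accept <- FALSE
    if (h > thr) {
      if (length(qrs) && (p - qrs[length(qrs)]) < refractory) {
        # within refractory: keep the larger of the two
        if (h > mwi[qrs[length(qrs)]]) qrs[length(qrs)] <- p
      } else if (length(qrs) &&
                 (p - qrs[length(qrs)]) < round(0.360 * fs) &&
                 !is.na(last_slope) && slope_at(p) < 0.5 * last_slope) {
        # T-wave: slope less than half of the previous QRS slope
        npki <- 0.125 * h + 0.875 * npki
      } else {
        accept <- TRUE
      }
    } else {
      npki <- 0.125 * h + 0.875 * npki
    }
    if (accept) {
      qrs <- c(qrs, p)
      spki <- 0.125 * h + 0.875 * spki
      last_slope <- slope_at(p)
      if (length(qrs) >= 2) {
        rrs <- diff(tail(qrs, 9))
        rr_avg <- mean(rrs)
      }
    }
    thr <- npki + 0.25 * (spki - npki)
    # search-back for a missed beat
    if (length(qrs) >= 2 && !is.na(rr_avg) && i < length(cand)) {
      gap_next <- cand[i + 1] - qrs[length(qrs)]
      if (gap_next > 1.66 * rr_avg) {
        miss <- cand[cand > qrs[length(qrs)] + refractory &
                     cand < cand[i + 1] - refractory %/% 2]
        if (length(miss)) {
          best <- miss[which.max(mwi[miss])]
          if (mwi[best] > 0.5 * thr) {
            qrs <- sort(c(qrs, best))
            spki <- 0.25 * mwi[best] + 0.75 * spki
          }
        }
      }
    }
  }
  if (!length(qrs)) return(beat_series(numeric(0), "R_PEAK"))

  coarse <- beat_series(idx_to_ms(sort(unique(qrs)), fs), "R_PEAK")
  refined <- refine_rpeaks(bp, fs, coarse, window_ms = refine_ms)
  # enforce refractory after refinement
  t <- refined$times_ms
  if (length(t) >= 2) {
    keep <- rep(TRUE, length(t))
    last <- t[1]
    for (j in 2:length(t)) {
      if (t[j] - last < refractory_ms) keep[j] <- FALSE else last <- t[j]
    }
    t <- t[keep]
  }
  beat_series(t, "R_PEAK")
}

#' Refine coarse beat times onto local waveform maxima
#'
#' Moves every coarse fiducial to the sample of maximum signal amplitude
#' within \eqn{\pm}`window_ms`, clamping at the signal boundaries and
#' collapsing duplicates that refine to the same sample.
#'
#' @param ecg Signal vector on which to refine (typically the band-passed
#'   ECG).
#' @param fs Sampling rate in Hz.
#' @param coarse A [beat_series()] of coarse times.
#' @param window_ms Half-width of the search window in ms.
#' @return A [beat_series()] with the same label.
#' @export
refine_rpeaks <- function(ecg, fs, coarse, window_ms = 40) {
  ecg <- assert_numeric_vector(ecg, "ecg")
  stopifnot(inherits(coarse, "beat_series"))
  if (!length(coarse$times_ms)) return(coarse)
  n <- length(ecg)
  hw <- as.integer(round(window_ms / 1000 * fs))
  idx <- vapply(coarse$times_ms, function(tm) {
    c0 <- min(max(ms_to_idx(tm, fs), 1L), n)
    lo <- max(1L, c0 - hw); hi <- min(n, c0 + hw)
    lo + which.max(ecg[lo:hi]) - 1L
  }, integer(1))
  idx <- sort(unique(idx))
  beat_series(idx_to_ms(idx, fs), coarse$label)
}
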