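# ECG-referenced evaluation of NCC detections. Each reference cardiac
# cycle (R-to-R window) is classified: no NCC peak -> false negative (FN);
# one in-tolerance peak -> true positive (TP), any extra peaks in the
# cycle -> false positives (FP); peaks present but none at a plausible
# delay from the R peak -> detection error (DE). DEs enter both the
# sensitivity and PPV denominators, so they are tallied separately from
# FP and FN rather than folded into them.

#' Detection count tallies
#'
#' @param tp,fp,fn,de Non-negative integer counts of true positives,
#'   false positives, false negatives and detection errors. A DE marks a
#'   cycle whose only detection(s) are temporally implausible; it is kept
#'   distinct because it appears in both metric denominators.
#' @return An object of class `detection_counts`.
#' @export
detection_counts <- function(tp = 0, fp = 0, fn = 0, de = 0) {
  vals <- c(tp = tp, fp = fp, fn = fn, de = de)
  if (any(vals < 0) || any(vals != round(vals)))
    stop("counts must be non-negative integers", call. = FALSE)
  structure(as.list(vals), class = "detection_counts")
}

#' @export
print.detection_counts <- function(x, ...) {
  cat(sprintf("<detection_counts> TP=%d FP=%d FN=%d DE=%d (cycles=%d)\n",
              x$tp, x$fp, x$fn, x$de, x$tp + x$fn + x$de))
  invisible(x)
}

#' Half-open cardiac-cycle windows from reference R peaks
#'
#' Window `j` spans `[R_j + delta, R_{j+1} + delta)`; with the default
#' `delta = 0` the windows run R-to-R and partition the span, so every
#' detection is attributed to exactly one cycle.
#'
#' @param rpeaks A [beat_series()] with at least 2 R peaks.
#' @param delta_ms Fixed boundary offset in ms (default 0).
#' @return A data frame with columns `cycle`, `start_ms`, `end_ms`,
#'   `r_ms` (the cycle's R-peak time).
#' @export
cycle_windows <- function(rpeaks, delta_ms = 0) {
  stopifnot(inherits(rpeaks, "beat_series"))
  t <- rpeaks$times_ms
  if (length(t) < 2)
    stop("at least 2 R peaks are required to form cycle windows", call. = FALSE)
  data.frame(cycle = seq_len(length(t) - 1),
             start_ms = t[-length(t)] + delta_ms,
             end_ms = t[-1] + delta_ms,
             r_ms = t[-length(t)])
}

#' Classify NCC peaks against reference cardiac cycles
#'
#' For each R-to-R cycle: 0 contained peaks gives FN; otherwise the peak
#' nearest to the expected position `R_j + expected_delay_ms` is the TP
#' candidate and all other contained peaks count as FP; if even the
#' nearest peak lies outside `±delay_tol_ms` of the expected position the
#' cycle is a DE (its peaks are not plausible template matches). The
#' expected R-to-NCC-peak delay is estimated, when not given, as the
#' median signed offset between each cycle's R peak and its nearest NCC
#' peak over the whole record.
#'
#' @param ncc_peaks A [beat_series()] of NCC-peak times.
#' @param rpeaks A [beat_series()] of reference R-peak times (>= 2).
#' @param expected_delay_ms Expected mechanical delay (ms) of the NCC peak
#'   after the R peak; `NULL` (default) estimates it from the record.
#' @param delay_tol_ms Plausibility tolerance around the expected position
#'   (default 150 ms).
#' @param delta_ms Cycle boundary offset passed to [cycle_windows()].
#' @return A list with `annotation` (data frame, one row per cycle:
#'   `cycle`, `start_ms`, `end_ms`, `r_ms`, `n_peaks`, `label`,
#'   `tp_time_ms`, `extra_fp`), `counts` (a [detection_counts()]) and
#'   `expected_delay_ms` (the value used).
#' @export
annotate_beats <- function(ncc_peaks, rpeaks, expected_delay_ms = NULL,
                           delay_tol_ms = 150, delta_ms = 0) {
  stopifnot(inherits(ncc_peaks, "beat_series"), inherits(rpeaks, "beat_series"))
  win <- cycle_windows(rpeaks, delta_ms)
  pk <- ncc_peaks$times_ms

  if (is.null(expected_delay_ms)) {
    if (length(pk)) {
      offs <- vapply(win$r_ms, function(r) pk[which.min(abs(pk - r))] - r,
                     numeric(1))
      expected_delay_ms <- median(offs)
    } else {
      expected_delay_ms <- 0
    }
  }

  ncyc <- nrow(win)
  label <- character(ncyc)
  tp_time <- rep(NA_real_, ncyc)
  n_peaks <- integer(ncyc)
  extra_fp <- integer(ncyc)
  for (j in seq_len(ncyc)) {
    inwin <- pk[pk >= win$start_ms[j] & pk < win$end_ms[j]]
    n_peaks[j] <- length(inwin)
    if (!length(inwin)) {
      label[j] <- "FN"
      next
    }
    expected <- win$r_ms[j] + expected_delay_ms
    cand <- inwin[which.min(abs(inwin - expected))]
    if (abs(cand - expected) <= delay_tol_ms) {
      label[j] <- "TP"
      tp_time[j] <- cand
      extra_fp[j] <- length(inwin) - 1L
    } else {
      label[j] <- "DE"
      extra_fp[j] <- length(inwin) - 1L
    }
  }
  counts <- detection_counts(tp = sum(label == "TP"),
                             fp = sum(extra_fp),
                             fn = sum(label == "FN"),
                             de = sum(label == "DE"))
  ann <- cbind(win, n_peaks = n_peaks, label = label,
               tp_time_ms = tp_time, extra_fp = extra_fp)
  list(annotation = ann, counts = counts,
       expected_delay_ms = expected_delay_ms)
}

#' Inter-beat intervals of a beat series
#'
#' @param beats A [beat_series()] with at least 2 events.
#' @return Numeric vector of first differences (ms), length `n - 1`.
#' @export
inter_beat_intervals <- function(beats) {
  stopifnot(inherits(beats, "beat_series"))
  if (length(beats$times_ms) < 2)
    stop("at least 2 beats are required for inter-beat intervals", call. = FALSE)
  diff(beats$times_ms)
}

#' Paired reference/test inter-beat intervals over valid cycles
#'
#' Emits the interval pair (`R_j -> R_{j+1}`, matched TP peak of cycle j
#' -> matched TP peak of cycle j+1) if and only if both flanking cycles
#' are TP, so intervals corrupted by FNs and DEs are removed; extra FP
#' peaks never enter interval construction.
#'
#' @param ann Result of [annotate_beats()].
#' @return A data frame with columns `ref_ibi_ms`, `test_ibi_ms` (possibly
#'   zero rows).
#' @export
pair_valid_ibis <- function(ann) {
  a <- ann$annotation
  ncyc <- nrow(a)
  if (ncyc < 2)
    return(data.frame(ref_ibi_ms = numeric(0), test_ibi_ms = numeric(0)))
  ok <- a$label[-ncyc] == "TP" & a$label[-1] == "TP"
  data.frame(
    ref_ibi_ms = (a$r_ms[-1] - a$r_ms[-ncyc])[ok],
    test_ibi_ms = (a$tp_time_ms[-1] - a$tp_time_ms[-ncyc])[ok]
  )
}
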