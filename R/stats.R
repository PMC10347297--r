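# Detection metrics and inter-beat-interval agreement statistics.
# Sensitivity = 100 * TP / (TP + FN + DE); PPV = 100 * TP / (TP + FP + DE):
# detection errors sit in both denominators because a DE cycle is at once
# a missed heartbeat and a spurious detection.

#' Heartbeat-detection sensitivity
#'
#' `100 * TP / (TP + FN + DE)`, the fraction of reference cardiac cycles
#' with a correctly localized detection.
#'
#' @param counts A [detection_counts()].
#' @return Percentage in `[0, 100]`.
#' @examples
#' sensitivity(detection_counts(tp = 35383, fn = 2486, de = 2656))
#' @export
sensitivity <- function(counts) {
  stopifnot(inherits(counts, "detection_counts"))
  den <- counts$tp + counts$fn + counts$de
  if (den == 0) stop("sensitivity undefined: TP + FN + DE is zero", call. = FALSE)
  100 * counts$tp / den
}

#' Heartbeat-detection positive predictive value
#'
#' `100 * TP / (TP + FP + DE)`, the fraction of emitted detections that
#' correspond to true heartbeats.
#'
#' @param counts A [detection_counts()].
#' @return Percentage in `[0, 100]`.
#' @examples
#' ppv(detection_counts(tp = 35383, fp = 526, de = 2656))
#' @export
ppv <- function(counts) {
  stopifnot(inherits(counts, "detection_counts"))
  den <- counts$tp + counts$fp + counts$de
  if (den == 0) stop("PPV undefined: TP + FP + DE is zero", call. = FALSE)
  100 * counts$tp / den
}

#' Ordinary least-squares regression of test on reference intervals
#'
#' @param ref,test Equal-length numeric vectors (n >= 3); `ref` must be
#'   non-constant.
#' @return List with `slope`, `intercept_ms`, `r_squared`.
#' @export
regress_ibis <- function(ref, test) {
  ref <- assert_numeric_vector(ref, "ref")
  test <- assert_numeric_vector(test, "test")
  if (length(ref) != length(test)) stop("unequal lengths", call. = FALSE)
  if (length(ref) < 3) stop("need at least 3 pairs", call. = FALSE)
  if (var(ref) == 0) stop("'ref' is constant; regression undefined", call. = FALSE)
  fit <- lm(test ~ ref)
  tss <- sum((test - mean(test))^2)
  rss <- sum(fit$residuals^2)
  list(slope = unname(coef(fit)[2]),
       intercept_ms = unname(coef(fit)[1]),
       r_squared = if (tss == 0) 1 else 1 - rss / tss)
}

#' Pearson correlation of paired intervals
#'
#' @param ref,test Equal-length numeric vectors (n >= 3), both
#'   non-constant.
#' @return List with `r` and two-sided `p` (t distribution with n-2 df).
#' @export
pearson_ibis <- function(ref, test) {
  ref <- assert_numeric_vector(ref, "ref")
  test <- assert_numeric_vector(test, "test")
  if (length(ref) != length(test)) stop("unequal lengths", call. = FALSE)
  if (length(ref) < 3) stop("need at least 3 pairs", call. = FALSE)
  if (var(ref) == 0 || var(test) == 0)
    stop("constant input; correlation undefined", call. = FALSE)
  ct <- cor.test(ref, test, method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value)
}

#' Bland-Altman agreement of paired intervals
#'
#' Classic (1986) formulation on differences `d = test - ref`: bias =
#' mean(d); limits of agreement (LoA) = bias +/- 1.96 sd(d); 95% CI of
#' the bias uses SE = sd/sqrt(n) and of each LoA uses SE = sd *
#' sqrt(3/n), both with the t quantile at n - 1 df. The bias p-value is a
#' one-sample t test of zero mean difference.
#'
#' @param ref,test Equal-length numeric vectors (n >= 3).
#' @return List with `n`, `bias_ms`, `bias_p`, `sd_ms`, `loa_low_ms`,
#'   `loa_high_ms`, `ci_bias_ms`, `ci_loa_low_ms`, `ci_loa_high_ms` (the
#'   CIs as length-2 vectors).
#' @references Bland J.M., Altman D.G. (1986) Statistical methods for
#'   assessing agreement between two methods of clinical measurement.
#'   Lancet 327:307-310.
#' @export
bland_altman <- function(ref, test) {
  ref <- assert_numeric_vector(ref, "ref")
  test <- assert_numeric_vector(test, "test")
  if (length(ref) != length(test)) stop("unequal lengths", call. = FALSE)
  n <- length(ref)
  if (n < 3) stop("need at least 3 pairs", call. = FALSE)
  d <- test - ref
  bias <- mean(d)
  s <- sd(d)
  loa <- bias + c(-1.96, 1.96) * s
  tq <- qt(0.975, n - 1)
  ci_bias <- bias + c(-1, 1) * tq * s / sqrt(n)
  se_loa <- s * sqrt(3 / n)
  bias_p <- if (s == 0) {
    if (bias == 0) 1 else 0
  } else {
    t.test(d)$p.value
  }
  list(n = n, bias_ms = bias, bias_p = bias_p, sd_ms = s,
       loa_low_ms = loa[1], loa_high_ms = loa[2],
       ci_bias_ms = ci_bias,
       ci_loa_low_ms = loa[1] + c(-1, 1) * tq * se_loa,
       ci_loa_high_ms = loa[2] + c(-1, 1) * tq * se_loa)
}

#' Combined agreement report for paired inter-beat intervals
#'
#' Bundles regression, Pearson correlation and Bland-Altman results for
#' reference (ECG) vs. test (GCG) inter-beat intervals.
#'
#' @param ref,test Equal-length interval vectors in ms (n >= 3).
#' @return An object of class `agreement_report` (a named list of all
#'   component statistics).
#' @export
agreement_report <- function(ref, test) {
  reg <- regress_ibis(ref, test)
  pea <- pearson_ibis(ref, test)
  ba <- bland_altman(ref, test)
  structure(c(reg, list(pearson_r = pea$r, pearson_p = pea$p), ba),
            class = "agreement_report")
}

#' @export
print.agreement_report <- function(x, ...) {
  cat("<agreement_report>\n")
  cat(sprintf("  n pairs     : %d\n", x$n))
  cat(sprintf("  slope       : %.4f   intercept: %.2f ms   R^2: %.4f\n",
              x$slope, x$intercept_ms, x$r_squared))
  cat(sprintf("  Pearson r   : %.4f (p = %.3g)\n", x$pearson_r, x$pearson_p))
  cat(sprintf("  bias        : %.3f ms (p = %.3g), 95%% CI [%.3f, %.3f]\n",
              x$bias_ms, x$bias_p, x$ci_bias_ms[1], x$ci_bias_ms[2]))
  cat(sprintf("  LoA         : [%.2f, %.2f] ms\n", x$loa_low_ms, x$loa_high_ms))
  cat(sprintf("  95%% CI LoA  : [%.2f, %.2f] ms\n",
              x$ci_loa_low_ms[1], x$ci_loa_high_ms[2]))
  invisible(x)
}

#' Bland-Altman plot of an agreement report
#'
#' @param ref,test The interval vectors used for the report.
#' @param report Optionally a precomputed [agreement_report()].
#' @param ... Passed to [graphics::plot()].
#' @return The report, invisibly.
#' @export
plot_bland_altman <- function(ref, test, report = NULL, ...) {
  report <- report %||% agreement_report(ref, test)
  m <- (ref + test) / 2
  d <- test - ref
  graphics::plot(m, d, pch = 16, cex = 0.4, col = "grey40",
                 xlab = "Mean of ECG and GCG IBI (ms)",
                 ylab = "GCG - ECG IBI (ms)", ...)
  graphics::abline(h = report$bias_ms, col = "blue")
  graphics::abline(h = c(report$loa_low_ms, report$loa_high_ms),
                   col = "red", lty = 2)
  invisible(report)
}
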