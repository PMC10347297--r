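rp <- function(t) beat_series(t, "R_PEAK")
np <- function(t) beat_series(t, "NCC_PEAK")

test_that("cycle windows are half-open R-to-R partitions", {
  w <- cycle_windows(rp(c(1000, 2000, 3000)))
  expect_equal(w$start_ms, c(1000, 2000))
  expect_equal(w$end_ms, c(2000, 3000))

  # a peak exactly on the boundary belongs to the later cycle
  ann <- annotate_beats(np(c(2000, 2500)), rp(c(1000, 2000, 3000)),
                        expected_delay_ms = 0, delay_tol_ms = 1500)
  expect_equal(ann$annotation$n_peaks, c(0L, 2L))

  wd <- cycle_windows(rp(c(1000, 2000, 3000)), delta_ms = 100)
  expect_equal(wd$start_ms, c(1100, 2100))
  expect_equal(wd$end_ms, c(2100, 3100))
  expect_error(cycle_windows(rp(500)), "2 R peaks")
})

test_that("annotation labels TP, FP, FN and DE cycles per the counting rules", {
  r <- rp(seq(1000, 6000, by = 1000))          # 5 cycles
  # perfect: one peak per cycle at R + 100 ms
  perfect <- np(seq(1100, 5100, by = 1000))
  a <- annotate_beats(perfect, r, expected_delay_ms = 100)
  expect_equal(unclass(a$counts)[c("tp", "fp", "fn", "de")],
               list(tp = 5L, fp = 0L, fn = 0L, de = 0L))

  # an extra in-tolerance peak in cycle 2: TP with one FP
  extra <- np(sort(c(seq(1100, 5100, by = 1000), 2150)))
  a2 <- annotate_beats(extra, r, expected_delay_ms = 100)
  expect_equal(a2$counts$tp, 5L)
  expect_equal(a2$counts$fp, 1L)
  expect_equal(a2$annotation$label[2], "TP")
  expect_equal(a2$annotation$extra_fp[2], 1L)

  # cycle 3's only peak is 400 ms off the expected position: DE
  de <- np(c(1100, 2100, 3500, 4100, 5100))
  a3 <- annotate_beats(de, r, expected_delay_ms = 100, delay_tol_ms = 150)
  expect_equal(a3$annotation$label[3], "DE")
  expect_equal(a3$counts$de, 1L)
  expect_equal(a3$counts$fp, 0L)          # DE is tallied separately from FP
  expect_equal(a3$counts$tp + a3$counts$fn + a3$counts$de, 5L)
  # DE enters both metric denominators
  expect_equal(sensitivity(a3$counts), 100 * 4 / 5)
  expect_equal(ppv(a3$counts), 100 * 4 / 5)

  # empty cycle: FN
  fn <- np(c(1100, 2100, 4100, 5100))
  a4 <- annotate_beats(fn, r, expected_delay_ms = 100)
  expect_equal(a4$annotation$label[3], "FN")
  expect_equal(a4$counts$fn, 1L)
})

test_that("conservation and shift invariance hold on random scenarios", {
  set.seed(9)
  for (k in 1:20) {
    nr <- sample(3:12, 1)
    r_times <- cumsum(runif(nr, 600, 1200)) + 1000
    pk <- sort(runif(sample(0:15, 1), min(r_times), max(r_times)))
    pk <- pk[!duplicated(round(pk))]
    peaks <- if (length(pk)) np(pk) else np(numeric(0))
    a <- annotate_beats(peaks, rp(r_times), delay_tol_ms = 150)
    expect_equal(a$counts$tp + a$counts$fn + a$counts$de, nr - 1L)
    expect_equal(a$counts$fp, sum(a$annotation$extra_fp))

    # global time shift of both series leaves labels unchanged
    sh <- 5000
    a_sh <- annotate_beats(if (length(pk)) np(pk + sh) else np(numeric(0)),
                           rp(r_times + sh), delay_tol_ms = 150)
    expect_equal(a_sh$annotation$label, a$annotation$label)
    expect_equal(unclass(a_sh$counts), unclass(a$counts))
  }
})

test_that("inter-beat intervals are first differences", {
  expect_equal(inter_beat_intervals(np(c(0, 800, 1650))), c(800, 850))
  expect_equal(inter_beat_intervals(rp(seq(0, 7500, by = 750))),
               rep(750, 10))
  expect_error(inter_beat_intervals(np(100)), "2 beats")
})

test_that("IBI pairing keeps only intervals flanked by TP cycles", {
  r <- rp(seq(1000, 7000, by = 1000))          # 6 cycles
  peaks <- np(seq(1100, 6100, by = 1000))      # all TP
  a <- annotate_beats(peaks, r, expected_delay_ms = 100)
  p <- pair_valid_ibis(a)
  expect_equal(nrow(p), 5)
  expect_equal(p$ref_ibi_ms, rep(1000, 5))
  expect_equal(p$test_ibi_ms, rep(1000, 5))

  # drop cycle 3's peak: the two interval pairs touching it disappear
  peaks2 <- np(seq(1100, 6100, by = 1000)[-3])
  a2 <- annotate_beats(peaks2, r, expected_delay_ms = 100)
  expect_equal(nrow(pair_valid_ibis(a2)), 3)
  expect_lte(nrow(pair_valid_ibis(a2)), sum(a2$annotation$label == "TP") - 1)
})

test_that("paired IBI error reflects propagated R-to-AO jitter", {
  set.seed(13)
  sigma <- 3
  nr <- 200
  r_times <- 1000 + cumsum(rep(800, nr))
  ao <- r_times + 100 + rnorm(nr, 0, sigma)
  a <- annotate_beats(np(sort(ao)), rp(r_times), delay_tol_ms = 150)
  p <- pair_valid_ibis(a)
  expect_gte(nrow(p), nr - 2)
  # |d| has mean sigma*sqrt(2)*sqrt(2/pi) =~ 3.4 ms; 3*sigma*sqrt(2) bounds it
  expect_lte(mean(abs(p$test_ibi_ms - p$ref_ibi_ms)), 3 * sigma * sqrt(2))
})
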