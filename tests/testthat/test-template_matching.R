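make_rec <- function(x, fs = 1000) gcg_recording(list(gcgy = x), fs = fs)

test_that("template carving follows sample arithmetic and rejects bad input", {
  set.seed(1)
  rec <- make_rec(rnorm(10000))
  tm <- select_template(rec, "gcgy", 1000, 1800)
  expect_length(tm$samples, 801)
  expect_equal(tm$start_ms, 1000)
  expect_error(select_template(rec, "gcgy", 1800, 1000), "greater")
  expect_error(select_template(rec, "gcgy", 9000, 11000), "outside")
  flat <- make_rec(c(rnorm(5000), numeric(5000)))
  expect_error(select_template(flat, "gcgy", 6000, 6500), "variance")
})

test_that("NCC is exact on self-match and invariant to affine transforms", {
  set.seed(2)
  w <- rnorm(100)
  tm <- gcg_template(w, fs = 1000)
  self <- ncc(w, tm)
  expect_length(self$values, 1)
  expect_lt(abs(self$values - 1), 1e-12)
  aff <- ncc(3.7 * w - 12, tm)
  expect_lt(abs(aff$values - 1), 1e-9)
})

test_that("NCC equals the direct double-loop formula on random cases", {
  set.seed(3)
  for (k in 1:10) {
    n <- sample(200:1500, 1)
    m <- sample(10:80, 1)
    x <- rnorm(n) * runif(1, 0.1, 10) + runif(1, -5, 5)
    w <- rnorm(m)
    got <- ncc(x, gcg_template(w, fs = 500), fs = 500)$values
    expect_length(got, n - m + 1)
    expect_lt(max(abs(got - brute_ncc(x, w))), 1e-10)
    expect_true(all(got >= -1 & got <= 1))
  }
})

test_that("NCC affine invariance holds as a property of the whole series", {
  set.seed(4)
  x <- rnorm(800)
  w <- rnorm(60)
  tm <- gcg_template(w, fs = 250)
  base <- ncc(x, tm, fs = 250)$values
  shifted <- ncc(2.5 * x + 100, tm, fs = 250)$values
  expect_lt(max(abs(base - shifted)), 1e-9)
  # zero-variance windows are 0 by convention
  xz <- c(numeric(200), x)
  vz <- ncc(xz, tm, fs = 250)$values
  expect_true(all(vz[1:100] == 0))
})

test_that("peak picking obeys prominence, distance and tie rules", {
  flat <- ncc_series(rep(0.2, 3000), fs = 1000)
  expect_length(detect_ncc_peaks(flat, peak_params())$times_ms, 0)

  # two equal peaks 400 ms apart: only the earlier survives at 500 ms spacing
  v <- numeric(2000)
  v[c(600, 1000)] <- 1
  b <- detect_ncc_peaks(ncc_series(v, fs = 1000), peak_params(0.5, 500))
  expect_equal(b$times_ms, 599)  # sample 600 -> (600-1)/fs*1000

  # higher of two close peaks wins
  v2 <- numeric(2000)
  v2[600] <- 0.8; v2[1000] <- 0.9
  b2 <- detect_ncc_peaks(ncc_series(v2, fs = 1000), peak_params(0.5, 500))
  expect_equal(b2$times_ms, 999)
})

test_that("peak picking matches the brute-force oracle on random walks", {
  set.seed(5)
  for (k in 1:10) {
    v <- cumsum(rnorm(400, sd = 0.12))
    v <- (v - min(v)) / (max(v) - min(v)) * 2 - 1   # keep inside [-1, 1]
    s <- ncc_series(v, fs = 100)
    prom <- runif(1, 0.1, 0.6)
    dist_ms <- sample(50:400, 1)
    got <- detect_ncc_peaks(s, peak_params(prom, dist_ms))$times_ms
    want <- idx <- brute_pick_peaks(v, prom, dist_ms / 1000 * 100)
    expect_equal(got, (idx - 1) / 100 * 1000)
    if (length(got) >= 2) expect_true(all(diff(got) >= dist_ms))
  }
})

test_that("automatic template suggestion brackets the generator's beat", {
  cfg <- synth_config(n_beats = 60, snr_db = 20, seed = 21)
  dat <- synth_recording(cfg)
  gf <- preprocess_gcg(dat$recording$channels$gcgy, 1000)
  tm <- suggest_template(gf, 1000)
  tr <- dat$truth
  j <- which.min(abs(tr$ao_ms - (tm$start_ms + tm$end_ms) / 2))
  expect_gte(tm$start_ms, tr$sys_onset_ms[j] - 60)
  expect_lte(tm$start_ms, tr$sys_onset_ms[j] + 15)
  expect_lte(abs(tm$end_ms - tr$dia_offset_ms[j]), 80)
  # the template must contain the systolic peak
  expect_true(tm$start_ms < tr$ao_ms[j] && tm$end_ms > tr$ao_ms[j])
})

test_that("template suggestion refuses beat-free noise", {
  set.seed(22)
  noise <- preprocess_gcg(rnorm(10000), 1000)
  expect_error(suggest_template(noise, 1000), "manual")
})

test_that("end-to-end detection recovers clean and noisy beat trains", {
  # no noise: every beat within +/- 30 ms of the systolic anchor
  cfg0 <- synth_config(n_beats = 120, snr_db = Inf, morphology_jitter = 0,
                       resp_mod_depth = 0, seed = 31)
  d0 <- synth_recording(cfg0)
  gf0 <- preprocess_gcg(d0$recording$channels$gcgy, 1000)
  tm0 <- suggest_template(gf0, 1000)
  b0 <- detect_heartbeats(d0$recording$channels$gcgy, 1000, tm0)
  expect_equal(length(b0$times_ms), nrow(d0$truth))
  m0 <- match_beats(b0, d0$truth$ao_ms, tol_ms = 30)
  expect_equal(m0$matched, nrow(d0$truth))

  # 10 dB SNR: sensitivity and PPV >= 99% at +/- 150 ms, evaluated over
  # the reference span (the protocol is cycle-bounded, as in annotate_beats)
  cfg1 <- synth_config(n_beats = 120, snr_db = 10, seed = 32)
  d1 <- synth_recording(cfg1)
  gf1 <- preprocess_gcg(d1$recording$channels$gcgy, 1000)
  tm1 <- suggest_template(gf1, 1000)
  b1 <- detect_heartbeats(d1$recording$channels$gcgy, 1000, tm1)
  span <- b1$times_ms >= min(d1$truth$r_ms) &
    b1$times_ms <= max(d1$truth$ao_ms) + 400
  m1 <- match_beats(b1$times_ms[span], d1$truth$ao_ms, tol_ms = 150)
  expect_gte(m1$sensitivity_pct, 99)
  expect_gte(m1$ppv_pct, 99)

  # noise-only signal: any detections are sparse (500 ms spacing cap) and
  # far below the NCC similarity of genuine template matches (> 0.9)
  set.seed(33)
  noise <- rnorm(2000)
  b2 <- detect_heartbeats(noise, 1000, tm1)
  expect_lte(length(b2$times_ms), 3)
  nv <- ncc(preprocess_gcg(noise, 1000), tm1)$values
  expect_lt(max(nv), 0.75)
})

test_that("detection is deterministic", {
  cfg <- synth_config(n_beats = 40, seed = 41)
  d <- synth_recording(cfg)
  gf <- preprocess_gcg(d$recording$channels$gcgy, 1000)
  tm <- suggest_template(gf, 1000)
  b1 <- detect_heartbeats(d$recording$channels$gcgy, 1000, tm)
  b2 <- detect_heartbeats(d$recording$channels$gcgy, 1000, tm)
  expect_identical(b1$times_ms, b2$times_ms)
})
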