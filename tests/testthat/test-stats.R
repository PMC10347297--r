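test_that("sensitivity and PPV reproduce the headline worked example", {
  cnt <- detection_counts(tp = 35383, fn = 2486, de = 2656, fp = 526)
  expect_equal(round(sensitivity(cnt)), 87)
  expect_equal(round(ppv(cnt)), 92)
  expect_equal(cnt$tp + cnt$fp + cnt$de, 38565)

  expect_equal(sensitivity(detection_counts(tp = 10)), 100)
  expect_equal(sensitivity(detection_counts(fn = 5, de = 5)), 0)
  expect_equal(ppv(detection_counts(tp = 10)), 100)
  expect_equal(ppv(detection_counts(fp = 3, de = 1)), 0)
  expect_error(sensitivity(detection_counts()), "zero")
  expect_error(ppv(detection_counts()), "zero")
})

test_that("metrics are invariant to scaling all counts", {
  cnt <- detection_counts(tp = 40, fp = 3, fn = 5, de = 2)
  cnt7 <- detection_counts(tp = 280, fp = 21, fn = 35, de = 14)
  expect_equal(sensitivity(cnt), sensitivity(cnt7))
  expect_equal(ppv(cnt), ppv(cnt7))
})

test_that("regression matches exact relations and the normal equations", {
  ref <- c(700, 750, 800, 850, 900)
  ident <- regress_ibis(ref, ref)
  expect_equal(ident$slope, 1)
  expect_equal(ident$intercept_ms, 0)
  expect_equal(ident$r_squared, 1)

  lin <- regress_ibis(ref, 0.9 * ref + 50)
  expect_equal(lin$slope, 0.9)
  expect_equal(lin$intercept_ms, 50)
  expect_equal(lin$r_squared, 1)

  set.seed(14)
  x <- rnorm(200, 800, 50)
  y <- 0.97 * x + 20 + rnorm(200, 0, 5)
  got <- regress_ibis(x, y)
  want <- ols_oracle(x, y)
  expect_lt(abs(got$slope - want$slope), 1e-9)
  expect_lt(abs(got$intercept_ms - want$intercept), 1e-9)
  expect_lt(abs(got$r_squared - want$r2), 1e-9)

  # swapping a noiseless relation inverts the slope
  sw <- regress_ibis(0.9 * ref + 50, ref)
  expect_equal(sw$slope, 1 / 0.9)
  expect_error(regress_ibis(rep(800, 5), ref), "constant")
})

test_that("Pearson correlation matches the textbook formula", {
  ref <- c(700, 760, 810, 860, 920)
  expect_equal(pearson_ibis(ref, ref)$r, 1)
  expect_equal(pearson_ibis(ref, -ref)$r, -1)

  set.seed(15)
  n <- 200
  x <- rnorm(n)
  y <- 0.8 * x + sqrt(1 - 0.8^2) * rnorm(n)
  got <- pearson_ibis(x, y)
  want <- pearson_oracle(x, y)
  expect_lt(abs(got$r - want$r), 1e-9)
  expect_lt(abs(got$p - want$p), 1e-9)
  expect_gte(got$r, 0.72)
  expect_lte(got$r, 0.86)
  expect_error(pearson_ibis(rep(1, 5), ref), "constant")
})

test_that("Bland-Altman handles degenerate difference vectors", {
  ref <- c(800, 810, 790, 805)
  ba0 <- bland_altman(ref, ref)
  expect_equal(ba0$bias_ms, 0)
  expect_equal(c(ba0$loa_low_ms, ba0$loa_high_ms), c(0, 0))

  ba5 <- bland_altman(ref, ref + 5)
  expect_equal(ba5$bias_ms, 5)
  expect_equal(ba5$sd_ms, 0)
  expect_equal(c(ba5$loa_low_ms, ba5$loa_high_ms), c(5, 5))
  expect_error(bland_altman(ref[1:2], ref[1:2]), "3 pairs")
})

test_that("Bland-Altman reproduces the hand-computed closed form", {
  d <- c(-3.2, 0.4, 1.1, 2.5, -0.7, 0.9, 1.8, -1.4)
  ref <- seq(700, 840, by = 20)
  test <- ref + d
  n <- length(d)
  bias <- mean(d); s <- sd(d); tq <- qt(0.975, n - 1)
  ba <- bland_altman(ref, test)
  expect_lt(abs(ba$bias_ms - bias), 1e-9)
  expect_lt(abs(ba$loa_low_ms - (bias - 1.96 * s)), 1e-9)
  expect_lt(abs(ba$loa_high_ms - (bias + 1.96 * s)), 1e-9)
  expect_lt(max(abs(ba$ci_bias_ms - (bias + c(-1, 1) * tq * s / sqrt(n)))), 1e-9)
  se_loa <- s * sqrt(3 / n)
  expect_lt(max(abs(ba$ci_loa_low_ms -
                      (bias - 1.96 * s + c(-1, 1) * tq * se_loa))), 1e-9)
  expect_lt(max(abs(ba$ci_loa_high_ms -
                      (bias + 1.96 * s + c(-1, 1) * tq * se_loa))), 1e-9)
  expect_lt(abs(ba$bias_p - t.test(d)$p.value), 1e-12)
  # bias always equals mean(test) - mean(ref)
  expect_equal(ba$bias_ms, mean(test) - mean(ref))
})

test_that("Bland-Altman at headline scale recovers the simulated moments", {
  set.seed(16)
  n <- 31831
  d <- rnorm(n, 0.15, 6.63)
  ref <- rnorm(n, 800, 50)
  ba <- bland_altman(ref, ref + d)
  expect_lt(abs(ba$bias_ms - 0.15), 0.1)
  halfwidth <- (ba$loa_high_ms - ba$loa_low_ms) / 2
  expect_lt(abs(halfwidth - 1.96 * 6.63), 0.2)
})

test_that("the combined agreement report is a faithful bundle", {
  set.seed(17)
  x <- rnorm(100, 800, 50)
  y <- x + rnorm(100, 0, 5)
  ar <- agreement_report(x, y)
  expect_s3_class(ar, "agreement_report")
  expect_equal(ar$slope, regress_ibis(x, y)$slope)
  expect_equal(ar$pearson_r, pearson_ibis(x, y)$r)
  expect_equal(ar$bias_ms, bland_altman(x, y)$bias_ms)
  expect_true(ar$loa_low_ms < ar$loa_high_ms)
  expect_true(abs(ar$pearson_r) <= 1)
})
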