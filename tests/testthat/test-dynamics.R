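test_that("recovery fit recovers the generating half-life exactly", {
  s <- makeDynamicSeries(hvTruth, longTimeline, "na_amplitude", noiseSd = 0)
  fit <- fitRecovery(s, fromPeak = TRUE)
  expect_equal(halfLife(fit), 636, tolerance = 1e-6)
  expect_true(converged(fit))

  s300 <- makeDynamicSeries(subjectTruth("HV", dynHalfLife = 300),
                            longTimeline, "na_amplitude", noiseSd = 0)
  expect_equal(halfLife(fitRecovery(s300)), 300, tolerance = 1e-4)
})

test_that("t2 decline fit recovers its half-life and ignores amplitude scale", {
  s <- makeDynamicSeries(hvTruth, longTimeline, "water_t2", halfLife = 620,
                         noiseSd = 0)
  fit <- fitT2Decline(s)
  expect_equal(halfLife(fit), 620, tolerance = 1e-6)

  # halving the excursion above baseline leaves the half-life unchanged
  v <- values(s); b <- baselineValue(s)
  half <- DynamicSeries(timestamps(s), b + (v - b) / 2, "water_t2", b)
  expect_equal(halfLife(fitT2Decline(half)), 620, tolerance = 1e-6)
})

test_that("degenerate and shifted inputs are handled as documented", {
  t <- timePoints(longTimeline, "na_amplitude")
  flat <- DynamicSeries(t, rep(2, length(t)), "na_amplitude", 2)
  fit <- fitRecovery(flat, fromPeak = FALSE)
  expect_true("degenerate" %in% fit@flags)
  expect_true("degenerate" %in% fitT2Decline(flat)@flags)

  # time-shift invariance under from-peak re-zeroing
  s <- makeDynamicSeries(hvTruth, longTimeline, "na_amplitude", noiseSd = 0)
  shifted <- DynamicSeries(timestamps(s) + 57, values(s), "na_amplitude",
                           baselineValue(s))
  expect_equal(halfLife(fitRecovery(shifted, fromPeak = TRUE)),
               halfLife(fitRecovery(s, fromPeak = TRUE)), tolerance = 1e-8)
})

test_that("noisy recovery fits stay close to truth", {
  set.seed(21)
  hl <- replicate(60, {
    s <- makeDynamicSeries(hvTruth, longTimeline, "na_amplitude",
                           noiseSd = 0.005, seed = sample.int(2^31 - 1, 1))
    halfLife(fitRecovery(s, fromPeak = TRUE))
  })
  expect_lt(abs(median(hl) - 636), 49)
})

test_that("time-to-peak locates the smoothed maximum with early ties", {
  s <- makeDynamicSeries(hvTruth, longTimeline, "na_amplitude", noiseSd = 0)
  dtNa <- diff(timestamps(s))[1]
  expect_lt(abs(timeToPeak(s) - 480), dtNa + 1e-9)

  t <- c(0, 10, 20, 30)
  dec <- DynamicSeries(t, c(4, 3, 2, 1), "na_amplitude", 4)
  expect_equal(timeToPeak(dec), 0)
  tie <- DynamicSeries(t, c(1, 5, 5, 1), "na_amplitude", 1)
  expect_equal(timeToPeak(tie), 10)
})

test_that("baseline comparison uses the exact signed-rank null", {
  # printed toy differences versus exhaustive sign enumeration
  d <- c(1.5, -0.4, 2.2, 0.9, -1.1, 3.0)
  t <- c(60, 120, 180)
  series <- lapply(d, function(di)
    DynamicSeries(t, rep(10 + di, 3), "na_amplitude", 10))
  out <- compareToBaseline(series)
  expect_equal(out$p_value[1], enumSignedRankP(d), tolerance = 1e-12)

  # exact null matches 2^n enumeration for a range of n (tie-free
  # magnitudes: the exact distribution is only defined without ties)
  set.seed(33)
  for (n in c(5, 7, 10)) {
    d <- sample(seq(0.1, 2, length.out = n)) *
      sample(c(-1, 1), n, replace = TRUE)
    series <- lapply(d, function(di)
      DynamicSeries(t, rep(1 + di, 3), "na_amplitude", 1))
    out <- compareToBaseline(series)
    expect_equal(out$p_value[1], enumSignedRankP(d), tolerance = 1e-12)
  }

  # all-at-baseline cohorts produce no significant timepoints
  null <- lapply(1:6, function(i)
    DynamicSeries(t, rep(5, 3), "na_amplitude", 5))
  outNull <- compareToBaseline(null)
  expect_false(any(outNull$significant))
  expect_true(all(outNull$flag == "all_zero"))
  expect_true(all(outNull$p_value == 1))
})

test_that("baseline comparison is invariant to positive affine rescaling", {
  # the signed ranks depend only on the ordering of |value - baseline|,
  # which any positive affine change of units preserves
  set.seed(8)
  t <- c(60, 120, 180, 240)
  series <- lapply(1:8, function(i)
    DynamicSeries(t, 1 + abs(rnorm(4, 0.5, 0.2)), "na_amplitude", 1))
  p1 <- compareToBaseline(series)$p_value
  rescaled <- lapply(series, function(s)
    DynamicSeries(timestamps(s), 3.7 * values(s) + 2, "na_amplitude",
                  3.7 * baselineValue(s) + 2))
  p2 <- compareToBaseline(rescaled)$p_value
  expect_equal(p1, p2, tolerance = 1e-12)
})

test_that("early sodium timepoints separate from baseline in healthy cohorts", {
  set.seed(55)
  hits <- replicate(40, {
    series <- lapply(1:10, function(i)
      makeDynamicSeries(hvTruth, AcquisitionTimeline(), "na_amplitude",
                        noiseSd = 0.02, seed = sample.int(2^31 - 1, 1)))
    out <- compareToBaseline(series)
    early <- out$timepoint <= 600
    any(out$significant[early])
  })
  expect_gte(mean(hits), 0.9)
})

test_that("group mean curves interpolate subjects onto a common grid", {
  a <- DynamicSeries(c(0, 100, 200, 300), c(1, 2, 3, 4), "na_amplitude", 1)
  b <- DynamicSeries(c(0, 150, 300), c(3, 4.5, 6), "na_amplitude", 3)
  gm <- groupMeanSeries(list(a, b), grid = c(0, 150, 300))
  expect_equal(values(gm), c(2, (2.5 + 4.5) / 2, 5))
  expect_equal(baselineValue(gm), 2)
})
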