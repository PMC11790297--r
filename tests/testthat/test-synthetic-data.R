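test_that("noiseless FID magnitude follows the biexponential envelope", {
  # single-exponential limit: magnitude ratio over one slow T2* is e^-1
  mono <- subjectTruth("HV", mFastFraction = 1e-12, t2sSlow = 13.4)
  fid <- makeFid(mono, amplitude = 2, nSamples = 512, dwell = 0.1,
                 t0 = 0, noiseSd = 0)
  m <- Mod(samples(fid))
  k <- which.min(abs(timePoints(fid) - 13.4))
  expect_equal(m[k] / m[1], exp(-1), tolerance = 1e-6)

  # magnitude at the first sample equals amplitude times the t0 decay
  fid <- makeFid(hvTruth, amplitude = 3, noiseSd = 0)
  expected <- 3 * (0.46 * exp(-0.16 / 2.2) + 0.54 * exp(-0.16 / 13.4))
  expect_equal(Mod(samples(fid))[1], expected, tolerance = 1e-12)
})

test_that("generators are reproducible bit-for-bit under a seed", {
  a <- makeFid(hvTruth, noiseSd = 0.05, seed = 1)
  b <- makeFid(hvTruth, noiseSd = 0.05, seed = 1)
  expect_identical(samples(a), samples(b))
  expect_false(identical(samples(a),
                         samples(makeFid(hvTruth, noiseSd = 0.05, seed = 2))))

  e1 <- makeEchoSeries(29.3, noiseSd = 0.01, seed = 7)
  e2 <- makeEchoSeries(29.3, noiseSd = 0.01, seed = 7)
  expect_identical(amplitudes(e1), amplitudes(e2))

  d1 <- makeDixonVolume(matrix(30, 3, 3), noiseSd = 0.01, seed = 3)
  d2 <- makeDixonVolume(matrix(30, 3, 3), noiseSd = 0.01, seed = 3)
  expect_identical(d1@echoes, d2@echoes)
})

test_that("generator inputs are validated", {
  expect_error(makeFid(hvTruth, amplitude = -1), "amplitude")
  expect_error(makeFid(hvTruth, dwell = 0), "dwell")
  expect_error(makeEchoSeries(t2 = -5), "t2")
  expect_error(makeDixonVolume(matrix(120, 2, 2)), "fat fractions")
  expect_error(makeDynamicSeries(hvTruth, longTimeline, "unknown"))
})

test_that("echo series log-amplitudes are exactly linear in TE", {
  s <- makeEchoSeries(t2 = 47, s0 = 2.5, noiseSd = 0)
  fitLine <- lm(log(amplitudes(s)) ~ echoTimes(s))
  expect_equal(unname(coef(fitLine)[2]), -1 / 47, tolerance = 1e-10)
  expect_equal(amplitudes(makeEchoSeries(30, 1))[1], exp(-1),
               tolerance = 1e-12)
})

test_that("dynamic series honour the documented shapes", {
  na <- makeDynamicSeries(hvTruth, longTimeline, "na_amplitude", noiseSd = 0)
  t <- timestamps(na); v <- values(na)
  # exact half-life contract on the decay segment
  peak <- hvTruth@dynPeakTime
  vAt <- function(tt) approx(t, v, xout = tt)$y
  b <- baselineValue(na)
  # use post-peak model values directly: timestamps beyond peak + half-life
  i1 <- which(t >= peak)[1]
  expect_equal((vAt(t[i1] + 636) - b) / (v[i1] - b), 0.5, tolerance = 0.02)
  # unimodal with maximum strictly after the first timepoint
  expect_gt(which.max(v), 1)
  expect_equal(length(which(diff(sign(diff(v))) < 0)), 1)

  wt <- makeDynamicSeries(hvTruth, longTimeline, "water_t2", noiseSd = 0)
  expect_equal(which.max(values(wt)), 1L)

  dp <- makeDynamicSeries(dpTruth, longTimeline, "na_amplitude", noiseSd = 0)
  expect_lte(max(values(dp)) / min(values(dp)), 1.1)
})

test_that("cohort draws match the specified distributions", {
  spec <- cohortSpec(nPerGroup = 200, seed = 42)
  coh <- makeCohort(spec, render = FALSE)
  hv <- coh$truths[coh$truths$group == "HV", ]
  se <- 3.1 / sqrt(200)
  expect_lt(abs(mean(hv$naConcentration) - 19.6), 3 * se)
  expect_true(all(coh$truths$t2sFast < coh$truths$t2sSlow))
  expect_true(all(coh$truths$ff >= 0 & coh$truths$ff <= 100))

  # degenerate SDs collapse every subject onto the group mean
  hv0 <- groupParameterTable("HV"); hv0$sd <- 0
  dp0 <- groupParameterTable("DP"); dp0$sd <- 0
  coh0 <- makeCohort(cohortSpec(nPerGroup = 3, hv = hv0, dp = dp0, seed = 1),
                     render = FALSE)
  expect_equal(unique(coh0$truths$naConcentration[coh0$truths$group == "HV"]),
               19.6)

  # determinism
  cohA <- makeCohort(cohortSpec(nPerGroup = 5, seed = 9), render = FALSE)
  cohB <- makeCohort(cohortSpec(nPerGroup = 5, seed = 9), render = FALSE)
  expect_identical(cohA$truths, cohB$truths)
})

test_that("every generator inverts to truth under its fitting operation", {
  # FID -> biexponential fit
  for (truth in list(hvTruth, dpTruth)) {
    fit <- fitBiexpT2Star(makeFid(truth, noiseSd = 0))
    expect_equal(fit@t2sSlow, truth@t2sSlow, tolerance = 1e-6)
    expect_equal(fit@t2sFast, truth@t2sFast, tolerance = 1e-6)
    expect_equal(fastFraction(fit), truth@mFastFraction, tolerance = 1e-6)
  }
  # echo series -> mono T2 fit
  fit <- fitMonoT2(makeEchoSeries(29.3, s0 = 1.3, noiseSd = 0))
  expect_equal(fit@t2, 29.3, tolerance = 1e-6)
  expect_equal(fit@s0, 1.3, tolerance = 1e-6)
  # dynamics -> recovery fit
  s <- makeDynamicSeries(hvTruth, longTimeline, "na_amplitude", noiseSd = 0)
  expect_equal(halfLife(fitRecovery(s, fromPeak = TRUE)), 636,
               tolerance = 1e-6)
  # Dixon -> fat-water separation
  ff <- matrix(c(0, 30, 62.5, 100), 2, 2)
  res <- separateFatWater(makeDixonVolume(ff, waterT2star = 25, noiseSd = 0))
  expect_equal(as.vector(ffMap(res)), as.vector(ff), tolerance = 1e-4)
})
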