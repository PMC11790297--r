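test_that("biexponential fit recovers noiseless generating parameters", {
  fit <- fitBiexpT2Star(makeFid(hvTruth, noiseSd = 0))
  expect_equal(fit@t2sSlow, 13.4, tolerance = 1e-3)
  expect_equal(fit@t2sFast, 2.2, tolerance = 1e-3)
  expect_equal(fastFraction(fit), 0.46, tolerance = 1e-3)
  expect_true(converged(fit))
})

test_that("biexponential fit collapses cleanly on monoexponential data", {
  mono <- subjectTruth("HV", mFastFraction = 0, t2sFast = 2.2)
  fid <- makeFid(mono, noiseSd = 0)
  fit <- fitBiexpT2Star(fid)
  expect_lt(fastFraction(fit), 0.01)
  expect_equal(fit@t2sSlow, 13.4, tolerance = 1e-4)
  # nested-model consistency: biexponential RSS matches a one-component fit
  t <- timePoints(fid); y <- Mod(samples(fid))
  monoFit <- fitMonoT2(EchoAmplitudeSeries(t, y))
  expect_lt(abs(fit@rss - monoFit@rss), 1e-9)
})

test_that("biexponential fit is scale-equivariant and order-invariant", {
  fid <- makeFid(hvTruth, noiseSd = 0.02, seed = 11)
  t <- timePoints(fid); y <- Mod(samples(fid))
  f1 <- fitBiexpT2Star(data.frame(time = t, magnitude = y))
  f2 <- fitBiexpT2Star(data.frame(time = t, magnitude = 3 * y))
  expect_equal(f2@mFast, 3 * f1@mFast, tolerance = 1e-5)
  expect_equal(f2@mSlow, 3 * f1@mSlow, tolerance = 1e-5)
  expect_equal(f2@noiseOffset, 3 * f1@noiseOffset, tolerance = 1e-4)
  expect_equal(f2@t2sSlow, f1@t2sSlow, tolerance = 1e-6)
  expect_equal(f2@t2sFast, f1@t2sFast, tolerance = 1e-6)
  perm <- sample(length(t))
  f3 <- fitBiexpT2Star(data.frame(time = t[perm], magnitude = y[perm]))
  expect_equal(f3@t2sSlow, f1@t2sSlow, tolerance = 1e-8)
  expect_equal(f3@rss, f1@rss, tolerance = 1e-10)
})

test_that("noisy biexponential recovery is unbiased at moderate SNR", {
  # Monte-Carlo recovery against generating values, patient parameter set
  set.seed(101)
  seeds <- sample.int(2^31 - 1, 60)
  rec <- t(vapply(seeds, function(s) {
    fit <- fitBiexpT2Star(makeFid(dpTruth, noiseSd = 1 / 50, seed = s))
    c(fit@t2sFast, fit@t2sSlow)
  }, numeric(2)))
  expect_lt(abs(mean(rec[, 1]) - 1.0) / 1.0, 0.10)
  expect_lt(abs(median(rec[, 2]) - 14.0) / 14.0, 0.05)
})

test_that("spectra behave as Fourier-transform pairs", {
  mono <- subjectTruth("HV", mFastFraction = 1e-12, t2sSlow = 10)
  fid <- makeFid(mono, noiseSd = 0)
  sp <- fidToSpectrum(fid, zeroFill = 2)
  # single resonance centred at 0 Hz
  expect_lt(abs(frequencyAxis(sp)[which.max(Mod(values(sp)))]), 4)
  # linearity
  sp2 <- fidToSpectrum(makeFid(mono, amplitude = 2, noiseSd = 0),
                       zeroFill = 2)
  expect_equal(Mod(values(sp2)), 2 * Mod(values(sp)), tolerance = 1e-9)
  expect_error(fidToSpectrum(fid, zeroFill = 0.5), "zeroFill")
})

test_that("peak area tracks time-domain amplitude linearly", {
  areas <- vapply(seq(0.5, 5, length.out = 10), function(a) {
    fid <- makeFid(hvTruth, amplitude = a, noiseSd = 0)
    peakArea(fidToSpectrum(fid, zeroFill = 2), c(-250, 250))
  }, 0)
  fitLine <- lm(areas ~ seq(0.5, 5, length.out = 10))
  expect_gt(suppressWarnings(summary(fitLine)$r.squared), 0.999)
  # explicit 2x ratio and the zero-signal null case
  expect_equal(areas[10] / areas[5], seq(0.5, 5, length.out = 10)[10] /
                 seq(0.5, 5, length.out = 10)[5], tolerance = 0.01)
  z <- new("Spectrum", frequency = seq(-100, 100), values = complex(201),
           processing = list())
  expect_equal(peakArea(z, c(-50, 50)), 0)
})

test_that("widening the window adds the analytic Lorentzian tail", {
  # analytic lineshape of a decaying exponential with halved first point:
  # S(f) = 1/(lambda + 2 pi i f) - dt/2; the oracle integrates |S| on a
  # fine independent grid with the same edge-baseline rule as peakArea
  t2 <- 8 # ms
  lambda <- 1000 / t2 # 1/s
  gam <- lambda / (2 * pi) # Hz scale unit used as the "linewidth"
  dt <- 0.125e-3 # s
  mono <- subjectTruth("HV", mFastFraction = 1e-12, t2sSlow = t2)
  fid <- makeFid(mono, nSamples = 4096, dwell = 0.125, t0 = 0, noiseSd = 0)
  sp <- fidToSpectrum(fid, zeroFill = 2)
  shape <- function(f) Mod(1 / (lambda + 2i * pi * f) - dt / 2)
  df <- 1000 / (0.125 * 8192) # frequency resolution of the transform above
  analytic <- function(k) {
    f <- seq(-k * gam, k * gam, by = df)
    y <- shape(f)
    n <- length(f); kk <- min(10, max(1, n %/% 4))
    li <- seq_len(kk); ri <- seq.int(n - kk + 1, n)
    base <- mean(y[li]) + (f - mean(f[li])) *
      (mean(y[ri]) - mean(y[li])) / (mean(f[ri]) - mean(f[li]))
    yc <- y - base
    sum(diff(f) * (yc[-1] + yc[-n]) / 2)
  }
  # absolute areas and their ratio against the independent lineshape oracle
  expect_equal(peakArea(sp, c(-3 * gam, 3 * gam)), analytic(3),
               tolerance = 0.02)
  r35 <- peakArea(sp, c(-5 * gam, 5 * gam)) /
         peakArea(sp, c(-3 * gam, 3 * gam))
  expect_equal(r35, analytic(5) / analytic(3), tolerance = 0.02)
})

test_that("single-resonance water fit recovers amplitude and frequency", {
  t <- 0.25 + (0:511) * 0.5
  s <- 1.0 * exp(1i * 0.7) * exp((2i * pi * 50 / 1000 - 1 / 35) * t)
  fit <- fitWaterAmplitude(Fid(s, dwell = 0.5, t0 = 0.25, nucleus = "1H"))
  expect_equal(fit@amplitude, 1.0, tolerance = 1e-6)
  expect_equal(fit@frequency, 50, tolerance = 1e-6)
  expect_equal(fit@damping, 35, tolerance = 1e-5)

  # Monte-Carlo amplitude bias under noise stays small
  set.seed(5)
  amps <- replicate(40, {
    sn <- s + complex(real = rnorm(512, 0, 1 / 30),
                      imaginary = rnorm(512, 0, 1 / 30))
    fitWaterAmplitude(Fid(sn, 0.5, 0.25, "1H"))@amplitude
  })
  expect_lt(abs(mean(amps) - 1.0), 0.02)
})

test_that("mono T2 fit matches the log-linear oracle and flags bad input", {
  s <- makeEchoSeries(29.3, s0 = 0.8, noiseSd = 0)
  fit <- fitMonoT2(s)
  oracle <- coef(lm(log(amplitudes(s)) ~ echoTimes(s)))
  expect_equal(fit@t2, -1 / oracle[2], tolerance = 1e-6,
               ignore_attr = TRUE)
  expect_equal(fit@s0, exp(oracle[1]), tolerance = 1e-6, ignore_attr = TRUE)

  flat <- EchoAmplitudeSeries(c(30, 40, 60), rep(1, 3))
  expect_true("non_decaying" %in% fitMonoT2(flat)@flags)
  expect_error(fitMonoT2(EchoAmplitudeSeries(c(30, 40), c(1, 0.5))),
               "3 echoes")
})
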