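test_that("pure water and pure fat phantoms hit the limits", {
  water <- makeDixonVolume(matrix(0, 4, 4), waterT2star = 25, noiseSd = 0)
  resW <- separateFatWater(water)
  expect_equal(as.vector(ffMap(resW)), rep(0, 16), tolerance = 1e-4)
  # with no fat, |signal| varies across echoes only through the T2* factor
  m <- vapply(water@echoes, function(e) Mod(e[1, 1]), 0)
  expect_equal(m / exp(-echoTimes(water) / 25), rep(1, 3),
               tolerance = 1e-12)

  fat <- makeDixonVolume(matrix(100, 4, 4), waterT2star = 25, noiseSd = 0)
  resF <- separateFatWater(fat)
  expect_equal(as.vector(ffMap(resF)), rep(100, 16), tolerance = 1e-4)
  # pure-fat generator signal equals F * c(TE) * decay exactly
  cte <- naqms:::fatModulation(echoTimes(fat), fat@fatSpectrum, 3)
  expect_equal(fat@echoes[[2]][1, 1],
               cte[2] * exp(-echoTimes(fat)[2] / 25), tolerance = 1e-12)
})

test_that("fat fraction and R2* are recovered across the full range", {
  ffTrue <- array(seq(0, 100, by = 10), c(11, 1))
  vol <- makeDixonVolume(ffTrue, waterT2star = 25, noiseSd = 0)
  res <- separateFatWater(vol)
  expect_lt(max(abs(ffMap(res) - ffTrue)), 1)
  expect_lt(max(abs(res@r2star - 40)) / 40, 0.05)

  # mid-range voxel to sub-half-point accuracy
  res30 <- separateFatWater(makeDixonVolume(matrix(30, 2, 2),
                                            waterT2star = 25))
  expect_lt(max(abs(ffMap(res30) - 30)), 0.5)
})

test_that("separation is invariant to global complex scaling", {
  ff <- matrix(c(10, 35, 60, 85), 2, 2)
  vol <- makeDixonVolume(ff, waterT2star = 30, noiseSd = 0)
  scaled <- DixonSeries(lapply(vol@echoes, function(e) e * (2.5 * exp(1i))),
                        echoTimes(vol), 3, vol@fatSpectrum)
  expect_equal(ffMap(separateFatWater(scaled)),
               ffMap(separateFatWater(vol)), tolerance = 1e-6)
})

test_that("water/fat role swap mirrors the fat fraction", {
  ff <- matrix(c(20, 40, 70, 90), 2, 2)
  a <- separateFatWater(makeDixonVolume(ff, waterT2star = 25))
  b <- separateFatWater(makeDixonVolume(100 - ff, waterT2star = 25))
  expect_equal(ffMap(b), 100 - ffMap(a), tolerance = 0.1)
})

test_that("a smooth nonzero field offset is absorbed, not swapped", {
  ff <- matrix(25, 6, 6)
  psi <- matrix(seq(-40, 40, length.out = 36), 6, 6)
  vol <- makeDixonVolume(ff, waterT2star = 25, fieldMapHz = psi)
  res <- separateFatWater(vol)
  expect_lt(max(abs(ffMap(res) - 25)), 1)
  expect_lt(max(abs(res@fieldMap - psi)), 1)
  expect_equal(res@swapUnresolved, 0L)
})

test_that("noise-bias correction matches the Rician mean", {
  expect_equal(noiseBiasCorrect(c(0.5, 2, 7), 0), c(0.5, 2, 7))
  expect_lt(noiseBiasCorrect(sqrt(2) * 3, 3), 1e-6)  # floor case
  expect_error(noiseBiasCorrect(-1, 1), "non-negative")

  # the correction unbiases the squared signal (E[M^2] = A^2 + 2 sigma^2);
  # the corrected mean itself retains the second-order Jensen shortfall
  # sigma^2/(2A), about 2% at A = 5 sigma, so it sits just inside 3%
  set.seed(99)
  a <- 5; sigma <- 1
  m <- Mod(complex(real = a + rnorm(1e5, 0, sigma),
                   imaginary = rnorm(1e5, 0, sigma)))
  corr <- noiseBiasCorrect(m, sigma)
  expect_lt(abs(mean(corr^2) - a^2) / a^2, 0.01)
  expect_lt(abs(mean(corr) - a) / a, 0.03)
  # and it removes most of the raw magnitude bias direction
  expect_lt(mean(corr), mean(m))
})

test_that("background noise estimation divides out the Rayleigh factor", {
  set.seed(4)
  bg <- Mod(complex(real = rnorm(2e4, 0, 1.5), imaginary = rnorm(2e4, 0, 1.5)))
  expect_lt(abs(estimateNoiseSd(bg) - 1.5) / 1.5, 0.05)
})

test_that("fat-fraction summaries weight voxels, not slices", {
  ff <- array(25.7, c(3, 3, 2))
  mask <- array(1L, c(3, 3, 2))
  s <- summarizeFF(ff, mask)
  expect_equal(s$mean_ff, 25.7)
  expect_equal(nrow(s$per_slice), 2)

  # 10% over 100 voxels and 20% over 300 voxels -> 17.5%
  ff2 <- array(c(rep(10, 100), rep(20, 300)), c(10, 10, 4))
  mask2 <- array(1L, c(10, 10, 4))
  expect_equal(summarizeFF(ff2, mask2)$mean_ff, 17.5)

  one <- array(0L, c(3, 3, 2)); one[2, 2, 1] <- 1L
  expect_equal(summarizeFF(ff, one)$mean_ff, 25.7)
  expect_equal(summarizeFF(ff, one)$n_voxels, 1)
  expect_error(summarizeFF(ff, array(0L, c(3, 3, 2))), "empty mask")
  # zero-signal voxels are excluded and counted
  zs <- array(FALSE, c(3, 3, 2)); zs[1, 1, 1] <- TRUE
  s2 <- summarizeFF(ff, mask, zs)
  expect_equal(s2$n_excluded, 1)
  expect_equal(s2$n_voxels, 17)
})
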