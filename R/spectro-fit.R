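#' @importFrom minpack.lm nls.lm nls.lm.control
NULL

# core bounded Levenberg-Marquardt biexponential fit on (t, y) magnitude
# data; par = (mFast, mSlow, t2f, t2s, offset)
biexpFitCore <- function(t, y, init = NULL, nStarts = 5) {
  stopIfNot(length(t) == length(y), "times and magnitudes differ in length")
  stopIfNot(length(y) >= 5, "fewer samples than parameters")
  stopIfNot(all(y >= 0), "magnitude data must be non-negative")
  lower <- c(0, 0, 0.05, 0.05, 0)
  upper <- c(Inf, Inf, 500, 500, Inf)
  # the noise floor enters in quadrature: magnitude data are Rician, and
  # sqrt(signal^2 + floor^2) tracks the Rician mean far better through the
  # signal/noise crossover than an additive constant (which biases the slow
  # T2* low); as noise -> 0 the model reduces to the plain biexponential
  resid <- function(p)
    y - sqrt((p[1] * exp(-t / p[3]) + p[2] * exp(-t / p[4]))^2 + p[5]^2)
  starts <- if (!is.null(init)) list(init) else {
    # T2* pairs log-spaced over the physiological range, amplitude split 50/50
    centres <- exp(seq(log(0.3), log(50), length.out = nStarts))
    span <- max(y) - min(y)
    lapply(centres, function(ct)
      c(span / 2, span / 2, ct, min(ct * 8, 400), min(y)))
  }
  best <- NULL
  for (s in starts) {
    fit <- tryCatch(
      nls.lm(par = pmin(pmax(s, lower), c(1e12, 1e12, 500, 500, 1e12)),
             lower = lower, upper = upper, fn = resid,
             control = nls.lm.control(maxiter = 500, ftol = 1e-14,
                                      ptol = 1e-14)),
      error = function(e) NULL)
    if (is.null(fit)) next
    rss <- sum(fit$fvec^2)
    tf <- min(fit$par[3], fit$par[4])
    if (is.null(best) || rss < best$rss - 1e-15 ||
        (abs(rss - best$rss) <= 1e-15 && tf < min(best$par[3], best$par[4])))
      best <- list(par = fit$par, rss = rss,
                   ok = fit$info %in% c(1, 2, 3, 4))
  }
  if (is.null(best))
    return(new("BiexpT2StarFit", mFast = 0, mSlow = 0, t2sFast = 0.05,
               t2sSlow = 500, noiseOffset = 0, rss = Inf, converged = FALSE,
               flags = "non_convergence"))
  p <- best$par
  if (p[3] > p[4]) p <- p[c(2, 1, 4, 3, 5)]
  flags <- character()
  if (p[4] > 0 && (p[4] - p[3]) / p[4] < 0.05)
    flags <- c(flags, "effectively_monoexponential")
  if (!best$ok) flags <- c(flags, "convergence_uncertain")
  new("BiexpT2StarFit", mFast = p[1], mSlow = p[2], t2sFast = p[3],
      t2sSlow = p[4], noiseOffset = p[5], rss = best$rss,
      converged = best$ok, flags = flags)
}

#' Fit the biexponential sodium T2* model
#'
#' Bounded nonlinear least-squares fit of the biexponential magnitude model
#' `M(t) = sqrt((m_fast exp(-t/T2*_fast) + m_slow exp(-t/T2*_slow))^2 +
#' offset^2)` to the magnitude of a time-domain FID (or to a `data.frame`
#' with columns `time` and `magnitude`). The noise term enters as a
#' quadrature floor because magnitude data with circular complex Gaussian
#' noise are Rician: the root-sum-of-squares form follows the Rician mean
#' through the signal/noise crossover, where an additive constant offset
#' systematically shortens the fitted slow T2*; for noiseless data it
#' reduces to the plain biexponential decay plus noise level.
#' All parameters are constrained non-negative with T2* in
#' [0.05, 500] ms; when no starting point is supplied, five starts with
#' log-spaced T2* pairs are tried and the lowest residual sum of squares
#' wins (ties broken toward the smaller fast T2*). Components are ordered so
#' the fast one is the shorter. Non-convergence is flagged on the result,
#' never silent.
#'
#' @param x a [Fid-class] or a data.frame with columns `time` (ms) and
#'   `magnitude`
#' @param init optional numeric starting point
#'   `(m_fast, m_slow, t2s_fast, t2s_slow, offset)`
#' @param nStarts number of multi-start initialisations when `init` is absent
#' @return a [BiexpT2StarFit-class]
#' @examples
#' fit <- fitBiexpT2Star(makeFid(subjectTruth("HV"), noiseSd = 0))
#' fit
#' @export
setGeneric("fitBiexpT2Star",
  function(x, init = NULL, nStarts = 5) standardGeneric("fitBiexpT2Star"))

#' @rdname fitBiexpT2Star
#' @export
setMethod("fitBiexpT2Star", "Fid", function(x, init = NULL, nStarts = 5)
  biexpFitCore(timePoints(x), Mod(samples(x)), init, nStarts))

#' @rdname fitBiexpT2Star
#' @export
setMethod("fitBiexpT2Star", "data.frame", function(x, init = NULL,
                                                   nStarts = 5) {
  stopIfNot(all(c("time", "magnitude") %in% names(x)),
            "data.frame needs columns 'time' and 'magnitude'")
  biexpFitCore(x$time, x$magnitude, init, nStarts)
})

#' Fourier transform a FID to a spectrum
#'
#' Optional exponential apodization and zero-filling followed by a discrete
#' Fourier transform. The first point is halved before transforming so that
#' integrated (Parseval-style) area checks against time-domain amplitude
#' hold, and values are scaled by the dwell time so the spectrum
#' approximates the continuous-time transform (units signal x seconds). The
#' frequency axis is in Hz, ascending, centred on 0.
#'
#' @param fid a [Fid-class]
#' @param zeroFill zero-filling factor (>= 1; 1 = none)
#' @param apodizationHz exponential line broadening, Hz (0 = none)
#' @return a [Spectrum-class]
#' @export
fidToSpectrum <- function(fid, zeroFill = 1, apodizationHz = 0) {
  stopIfNot(is(fid, "Fid"), "fid must be a Fid")
  stopIfNot(zeroFill >= 1, "zeroFill must be >= 1")
  stopIfNot(apodizationHz >= 0, "apodizationHz must be non-negative")
  y <- samples(fid)
  n <- length(y)
  trel <- (seq_len(n) - 1) * dwellTime(fid) / 1000  # seconds from first sample
  if (apodizationHz > 0) y <- y * exp(-pi * apodizationHz * trel)
  y[1] <- y[1] / 2
  nfft <- as.integer(round(n * zeroFill))
  y <- c(y, complex(nfft - n))
  sp <- stats::fft(y) * (dwellTime(fid) / 1000)
  # reorder so frequencies run ascending through zero
  sw <- 1000 / dwellTime(fid)
  df <- sw / nfft
  freq <- (seq_len(nfft) - 1) * df
  freq[freq >= sw / 2] <- freq[freq >= sw / 2] - sw
  ord <- order(freq)
  new("Spectrum", frequency = freq[ord], values = sp[ord],
      processing = list(zero_fill = zeroFill, apodization_hz = apodizationHz))
}

#' Integrate a spectral peak
#'
#' Trapezoidal integral of the magnitude spectrum over a frequency window,
#' after subtracting a linear baseline through the means of the 10 points at
#' each window edge. Strictly increasing in the underlying signal amplitude
#' for a fixed lineshape.
#'
#' @param spec a [Spectrum-class]
#' @param window numeric length-2 frequency window, Hz
#' @return integrated area (signal units; magnitude x Hz x s)
#' @export
peakArea <- function(spec, window = c(-250, 250)) {
  stopIfNot(is(spec, "Spectrum"), "spec must be a Spectrum")
  stopIfNot(length(window) == 2 && window[1] < window[2],
            "window must be an increasing frequency pair")
  f <- frequencyAxis(spec)
  stopIfNot(window[1] >= min(f) && window[2] <= max(f),
            "window must lie inside the frequency axis")
  idx <- which(f >= window[1] & f <= window[2])
  stopIfNot(length(idx) >= 2, "window contains too few points")
  fx <- f[idx]
  m <- Mod(values(spec)[idx])
  k <- min(10L, max(1L, length(idx) %/% 4L))
  leftY <- mean(m[seq_len(k)]); rightY <- mean(m[seq.int(length(m) - k + 1, length(m))])
  leftX <- mean(fx[seq_len(k)]); rightX <- mean(fx[seq.int(length(m) - k + 1, length(m))])
  base <- if (rightX > leftX)
    leftY + (fx - leftX) * (rightY - leftY) / (rightX - leftX)
  else rep(leftY, length(fx))
  yc <- m - base
  sum(diff(fx) * (yc[-1] + yc[-length(yc)]) / 2)
}

#' Fit a single water resonance in the time domain
#'
#' Nonlinear least-squares fit of one exponentially damped complex sinusoid
#' `s(t) = A exp(i phi) exp(2 pi i f t) exp(-t/tau)` to a proton FID
#' (real and imaginary channels jointly). The amplitude is the extrapolate
#' at t = 0, the centre of the excitation pulse. Initialised from the
#' magnitude-spectrum peak (frequency), a log-magnitude regression
#' (damping), and the first sample (amplitude/phase).
#'
#' @param fid a [Fid-class] dominated by a single resonance
#' @return a [LorentzianFit-class]
#' @export
fitWaterAmplitude <- function(fid) {
  stopIfNot(is(fid, "Fid"), "fid must be a Fid")
  t <- timePoints(fid)              # ms, absolute since pulse centre
  s <- samples(fid)
  n <- length(s)
  # frequency init from the spectrum maximum
  sp <- fidToSpectrum(fid, zeroFill = 2)
  f0 <- frequencyAxis(sp)[which.max(Mod(values(sp)))]
  # damping init from log-magnitude slope over the stronger half
  m <- Mod(s)
  useidx <- which(m > max(m) * 0.05)
  useidx <- useidx[seq_len(max(2L, length(useidx) %/% 2L))]
  sl <- unname(stats::coef(stats::lm(log(m[useidx]) ~ t[useidx]))[2])
  tau0 <- if (is.finite(sl) && sl < 0) -1 / sl else max(t) / 3
  a0 <- m[1] * exp(t[1] / tau0)
  phi0 <- Arg(s[1] * exp(-2i * pi * f0 * t[1] / 1000))
  resid <- function(p) {
    mod <- p[1] * exp(1i * p[4]) * exp((2i * pi * p[2] / 1000 - 1 / p[3]) * t)
    c(Re(s - mod), Im(s - mod))
  }
  fit <- tryCatch(
    nls.lm(par = c(a0, f0, tau0, phi0),
           lower = c(0, -Inf, 1e-3, -2 * pi), upper = c(Inf, Inf, 1e5, 2 * pi),
           fn = resid,
           control = nls.lm.control(maxiter = 500, ftol = 1e-14,
                                    ptol = 1e-14)),
    error = function(e) NULL)
  if (is.null(fit))
    return(new("LorentzianFit", amplitude = NA_real_, frequency = NA_real_,
               damping = NA_real_, phase = NA_real_, rss = Inf,
               converged = FALSE))
  p <- unname(fit$par)
  new("LorentzianFit", amplitude = p[1], frequency = p[2],
      damping = p[3], phase = p[4], rss = sum(fit$fvec^2),
      converged = fit$info %in% c(1, 2, 3, 4))
}

#' Fit a monoexponential T2 decay across echo times
#'
#' Nonlinear least-squares fit of `S(TE) = s0 exp(-TE/t2)` to an echo
#' amplitude series, with `t2` bounded in (1, 1000) ms and initialised from
#' a log-linear regression. Non-decaying data (fitted `t2` at the upper
#' bound, or a non-negative log-amplitude slope with no curvature to rescue)
#' is flagged.
#'
#' @param series an [EchoAmplitudeSeries-class] with >= 3 echoes
#' @return a [MonoT2Fit-class]
#' @export
fitMonoT2 <- function(series) {
  stopIfNot(is(series, "EchoAmplitudeSeries"),
            "series must be an EchoAmplitudeSeries")
  te <- echoTimes(series)
  y <- amplitudes(series)
  stopIfNot(length(te) >= 3, "need at least 3 echoes")
  pos <- y > 0
  init <- if (sum(pos) >= 2) {
    cf <- unname(stats::coef(stats::lm(log(y[pos]) ~ te[pos])))
    t2i <- if (is.finite(cf[2]) && cf[2] < 0) -1 / cf[2] else 999
    c(exp(cf[1]), min(max(t2i, 1.001), 999))
  } else c(max(abs(y), 1e-12), 50)
  resid <- function(p) y - p[1] * exp(-te / p[2])
  fit <- nls.lm(par = init, lower = c(0, 1), upper = c(Inf, 1000),
                fn = resid,
                control = nls.lm.control(maxiter = 500, ftol = 1e-14,
                                         ptol = 1e-14))
  flags <- character()
  fit$par <- unname(fit$par)
  if (fit$par[2] >= 1000 * (1 - 1e-6)) flags <- c(flags, "non_decaying")
  new("MonoT2Fit", s0 = fit$par[1], t2 = fit$par[2],
      rss = sum(fit$fvec^2), converged = fit$info %in% c(1, 2, 3, 4),
      flags = flags)
}
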