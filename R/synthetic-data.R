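#' Group-level generating parameters
#'
#' Construct the ground truth for one synthetic subject. Defaults are the
#' published cohort means for healthy volunteers (`"HV"`) and dysferlinopathy
#' patients (`"DP"`): tissue sodium concentration 19.6 / 36.2 mM, muscle
#' water T2 29.3 / 33.8 ms, sodium T2* components 2.2 & 13.4 / 1.0 & 14.0 ms
#' with fast-signal fractions 0.46 / 0.38, and fat fraction 3.4 / 25.7%.
#' Post-exercise dynamics default to the healthy-control recovery half-life
#' of 636 s with a sodium peak at 480 s (~8 min).
#'
#' @param group `"HV"` or `"DP"`
#' @param naConcentration tissue sodium concentration, mM
#' @param waterT2 muscle water T2, ms
#' @param t2sFast,t2sSlow sodium T2* components, ms (`t2sFast < t2sSlow`)
#' @param mFastFraction fraction of sodium signal decaying fast, in [0, 1]
#' @param ff fat fraction, percent
#' @param dynHalfLife post-exercise recovery half-life, s
#' @param dynPeakTime time of the post-exercise sodium peak, s
#' @param dynPeakRatio peak/baseline amplitude ratio (>= 1)
#' @return a [SubjectTruth-class]
#' @examples
#' subjectTruth("HV")
#' subjectTruth("DP", naConcentration = 40)
#' @export
subjectTruth <- function(group = c("HV", "DP"),
                         naConcentration = NULL, waterT2 = NULL,
                         t2sFast = NULL, t2sSlow = NULL,
                         mFastFraction = NULL, ff = NULL,
                         dynHalfLife = 636, dynPeakTime = 480,
                         dynPeakRatio = NULL) {
  group <- match.arg(group)
  d <- groupDefaults(group)
  pick <- function(x, nm) if (is.null(x)) d[[nm]] else x
  new("SubjectTruth", group = group,
      naConcentration = as.numeric(pick(naConcentration, "naConcentration")),
      waterT2 = as.numeric(pick(waterT2, "waterT2")),
      t2sFast = as.numeric(pick(t2sFast, "t2sFast")),
      t2sSlow = as.numeric(pick(t2sSlow, "t2sSlow")),
      mFastFraction = as.numeric(pick(mFastFraction, "mFastFraction")),
      ff = as.numeric(pick(ff, "ff")),
      dynHalfLife = as.numeric(dynHalfLife),
      dynPeakTime = as.numeric(dynPeakTime),
      dynPeakRatio = as.numeric(pick(dynPeakRatio, "dynPeakRatio")))
}

# cohort means (and the post/pre amplitude ratios implied by them)
groupDefaults <- function(group) {
  if (group == "HV")
    list(naConcentration = 19.6, waterT2 = 29.3, t2sFast = 2.2,
         t2sSlow = 13.4, mFastFraction = 0.46, ff = 3.4,
         dynPeakRatio = 1.1e-4 / 8.7e-5)
  else
    list(naConcentration = 36.2, waterT2 = 33.8, t2sFast = 1.0,
         t2sSlow = 14.0, mFastFraction = 0.38, ff = 25.7,
         dynPeakRatio = 1.4e-4 / 1.29e-4)
}

#' Generate a synthetic sodium FID
#'
#' Renders a complex free induction decay whose noiseless magnitude follows
#' the biexponential envelope
#' `amplitude * (f exp(-t/T2*_fast) + (1 - f) exp(-t/T2*_slow))` at sample
#' times `t_k = t0 + k * dwell`, with independent circular complex Gaussian
#' noise per channel (so the magnitude of noisy data is Rician). Defaults
#' mirror the ISIS readout: 1024 samples over 128 ms starting 0.16 ms after
#' the pulse centre.
#'
#' @param truth a [SubjectTruth-class] supplying the relaxometry
#' @param amplitude total signal magnitude at t = 0 (arbitrary units, > 0)
#' @param nSamples number of complex samples (>= 8)
#' @param dwell dwell time, ms
#' @param t0 time of the first sample, ms
#' @param noiseSd per-channel Gaussian noise standard deviation
#' @param seed integer seed for reproducible noise; `NULL` uses the current
#'   RNG stream
#' @return a [Fid-class]
#' @examples
#' fid <- makeFid(subjectTruth("HV"), noiseSd = 0)
#' Mod(samples(fid))[1]
#' @export
makeFid <- function(truth, amplitude = 1, nSamples = 1024, dwell = 0.125,
                    t0 = 0.16, noiseSd = 0, seed = NULL) {
  stopIfNot(is(truth, "SubjectTruth"), "truth must be a SubjectTruth")
  stopIfNot(amplitude > 0, "amplitude must be positive")
  stopIfNot(dwell > 0, "dwell must be positive")
  stopIfNot(nSamples >= 8, "need at least 8 samples")
  stopIfNot(t0 >= 0, "t0 must be non-negative")
  stopIfNot(noiseSd >= 0, "noiseSd must be non-negative")
  t <- t0 + (seq_len(nSamples) - 1) * dwell
  env <- amplitude * biexpEnvelope(t, truth@mFastFraction,
                                   1 - truth@mFastFraction,
                                   truth@t2sFast, truth@t2sSlow)
  sig <- as.complex(env)
  if (noiseSd > 0)
    sig <- withSeed(seed, sig + complexNoise(nSamples, noiseSd))
  Fid(sig, dwell = dwell, t0 = t0, nucleus = "23Na")
}

#' Generate a synthetic multi-echo amplitude series
#'
#' Monoexponential echo-time decay `s0 * exp(-TE/t2)` plus Gaussian noise,
#' at the multi-echo water acquisition's echo times by default.
#'
#' @param t2 transverse relaxation time, ms (> 0)
#' @param s0 amplitude at TE = 0
#' @param echoTimes echo times, ms, strictly increasing
#' @param noiseSd Gaussian noise standard deviation
#' @param seed integer seed; `NULL` uses the current stream
#' @return an [EchoAmplitudeSeries-class]
#' @export
makeEchoSeries <- function(t2, s0 = 1,
                           echoTimes = c(30, 40, 60, 80, 100, 150),
                           noiseSd = 0, seed = NULL) {
  stopIfNot(t2 > 0, "t2 must be positive")
  amp <- s0 * exp(-echoTimes / t2)
  if (noiseSd > 0)
    amp <- withSeed(seed, amp + stats::rnorm(length(amp), 0, noiseSd))
  EchoAmplitudeSeries(echoTimes, amp, source = "synthetic")
}

#' Generate a post-exercise dynamic time course
#'
#' Renders one subject's post-exercise series at the interleaved acquisition
#' cadence. Healthy-volunteer sodium amplitude rises linearly from a start
#' value to its peak at `dynPeakTime`, then decays toward baseline as
#' `baseline + A * 2^(-(t - t_peak)/halfLife)`. Healthy-volunteer water T2 is
#' maximal at the first timepoint and declines monoexponentially to its
#' baseline. Patient series are near-flat at an elevated level with a small
#' configurable downward trend.
#'
#' @param truth a [SubjectTruth-class]
#' @param timeline an [AcquisitionTimeline-class]
#' @param modality `"na_amplitude"` or `"water_t2"`
#' @param noiseSd Gaussian noise standard deviation (units of the series)
#' @param seed integer seed; `NULL` uses the current stream
#' @param baseline pre-exercise baseline; defaults to 1 (arbitrary units)
#'   for sodium amplitude and to `truth@waterT2` (ms) for water T2
#' @param halfLife recovery half-life, s; defaults to `truth@dynHalfLife`
#' @param peakRatio peak/baseline ratio; defaults to `truth@dynPeakRatio`
#'   for sodium and to 36.4/29.3 (published post/pre water-T2 means) for
#'   water T2
#' @param startRatio sodium start value at t = 0 relative to baseline
#' @param dpTrend fractional decline of the patient series over the observed
#'   span (default 0.02)
#' @return a [DynamicSeries-class]
#' @export
makeDynamicSeries <- function(truth, timeline = AcquisitionTimeline(),
                              modality = c("na_amplitude", "water_t2"),
                              noiseSd = 0, seed = NULL, baseline = NULL,
                              halfLife = NULL, peakRatio = NULL,
                              startRatio = 1, dpTrend = 0.02) {
  stopIfNot(is(truth, "SubjectTruth"), "truth must be a SubjectTruth")
  stopIfNot(is(timeline, "AcquisitionTimeline"),
            "timeline must be an AcquisitionTimeline")
  modality <- match.arg(modality)
  t <- timePoints(timeline, modality)
  if (is.null(baseline))
    baseline <- if (modality == "na_amplitude") 1 else truth@waterT2
  if (is.null(halfLife)) halfLife <- truth@dynHalfLife
  if (is.null(peakRatio))
    peakRatio <- if (modality == "na_amplitude") truth@dynPeakRatio
                 else 36.4 / 29.3
  if (truth@group == "DP") {
    v <- baseline * peakRatio * (1 - dpTrend * t / max(t))
  } else if (modality == "na_amplitude") {
    peak <- baseline * peakRatio
    start <- baseline * startRatio
    tp <- truth@dynPeakTime
    v <- ifelse(t <= tp,
                start + (peak - start) * t / tp,
                baseline + (peak - baseline) * 2^(-(t - tp) / halfLife))
  } else {
    peak <- baseline * peakRatio
    v <- baseline + (peak - baseline) * 2^(-t / halfLife)
  }
  if (noiseSd > 0)
    v <- withSeed(seed, v + stats::rnorm(length(v), 0, noiseSd))
  DynamicSeries(t, v, modality = modality, baselineValue = baseline,
                subject = "synthetic", group = truth@group)
}

#' Default multi-peak fat spectral model
#'
#' Six-peak fat spectrum (chemical shifts in ppm with relative amplitudes
#' summing to 1) read from the plain-text table shipped with the package.
#' Users can supply their own table with the same columns.
#'
#' @return data.frame with columns `ppm` and `amplitude`
#' @export
defaultFatSpectrum <- function() {
  path <- system.file("extdata", "fat_spectrum_6peak.csv", package = "naqms")
  utils::read.csv(path, comment.char = "#")
}

# complex fat modulation c(TE) relative to water for TE in ms
fatModulation <- function(te, fatSpectrum, fieldStrength,
                          waterPpm = 4.7, gammaMHzPerT = 42.5774) {
  dfHz <- (fatSpectrum$ppm - waterPpm) * gammaMHzPerT * fieldStrength
  vapply(te, function(x)
    sum(fatSpectrum$amplitude * exp(2i * pi * dfHz * x / 1000)),
    complex(1))
}

#' Generate a synthetic three-echo Dixon acquisition
#'
#' Renders complex echo images
#' `S(TE) = (W + F c(TE)) exp(2 pi i psi TE) exp(-TE/T2*)` per voxel, where
#' `c(TE)` is the complex sum of the multi-peak fat spectrum at the given
#' field strength, `W/(W + F) = 1 - ff/100`, `psi` is the field offset (Hz)
#' and a single T2* is shared by water and fat. Circular complex Gaussian
#' noise is added per channel.
#'
#' @param ffMap array (2D or 3D) of fat fractions, percent in [0, 100]
#' @param waterT2star shared T2*, ms (scalar or array matching `ffMap`)
#' @param fieldStrength field strength, tesla
#' @param echoTimes three (or more) echo times, ms
#' @param noiseSd per-channel noise standard deviation
#' @param seed integer seed; `NULL` uses the current stream
#' @param s0 total proton-density magnitude `W + F` (scalar or array)
#' @param fieldMapHz field offset map, Hz (scalar or array)
#' @param fatSpectrum multi-peak fat model table
#' @return a [DixonSeries-class]
#' @export
makeDixonVolume <- function(ffMap, waterT2star = 25, fieldStrength = 3,
                            echoTimes = c(3.45, 4.60, 5.75), noiseSd = 0,
                            seed = NULL, s0 = 1, fieldMapHz = 0,
                            fatSpectrum = defaultFatSpectrum()) {
  ffMap <- as.array(ffMap)
  stopIfNot(all(ffMap >= 0 & ffMap <= 100),
            "fat fractions must lie in [0, 100] percent")
  stopIfNot(length(echoTimes) >= 3, "need at least three echo times")
  conform <- function(x, what) {
    if (length(x) == 1) array(x, dim(ffMap))
    else if (identical(dim(as.array(x)), dim(ffMap))) as.array(x)
    else stop(what, " must be scalar or match the shape of ffMap",
              call. = FALSE)
  }
  t2s <- conform(waterT2star, "waterT2star")
  s0 <- conform(s0, "s0")
  psi <- conform(fieldMapHz, "fieldMapHz")
  cte <- fatModulation(echoTimes, fatSpectrum, fieldStrength)
  w <- s0 * (1 - ffMap / 100)
  f <- s0 * ffMap / 100
  echoes <- withSeed(seed, lapply(seq_along(echoTimes), function(j) {
    te <- echoTimes[j]
    sig <- (w + f * cte[j]) * exp(2i * pi * psi * te / 1000) * exp(-te / t2s)
    if (noiseSd > 0) sig <- sig + complexNoise(length(sig), noiseSd)
    array(sig, dim(ffMap))
  }))
  DixonSeries(echoes, echoTimes = echoTimes, fieldStrength = fieldStrength,
              fatSpectrum = fatSpectrum)
}

#' Cohort specification
#'
#' Sampling specification for a two-group synthetic cohort: per-group means
#' and standard deviations for each [SubjectTruth-class] parameter, the
#' number of subjects per group, a seed, and the acquisition timeline.
#' Defaults are the published group means/SDs.
#'
#' @slot nPerGroup subjects per group
#' @slot hv,dp data.frames with columns `parameter`, `mean`, `sd`
#' @slot seed integer seed
#' @slot timeline an [AcquisitionTimeline-class]
#' @export
setClass("CohortSpec",
  representation(nPerGroup = "integer", hv = "data.frame", dp = "data.frame",
                 seed = "integer", timeline = "AcquisitionTimeline"))

setValidity("CohortSpec", function(object) {
  msg <- character()
  if (object@nPerGroup < 1L) msg <- c(msg, "nPerGroup must be >= 1")
  for (g in c("hv", "dp")) {
    tab <- slot(object, g)
    if (!all(c("parameter", "mean", "sd") %in% names(tab)))
      msg <- c(msg, paste(g, "table needs parameter/mean/sd columns"))
    else if (any(tab$sd < 0)) msg <- c(msg, "all SDs must be >= 0")
  }
  if (length(msg)) msg else TRUE
})

#' Default per-group sampling tables
#'
#' Published cohort means and SDs for each generating parameter.
#'
#' @param group `"HV"` or `"DP"`
#' @return data.frame with columns `parameter`, `mean`, `sd`
#' @export
groupParameterTable <- function(group = c("HV", "DP")) {
  group <- match.arg(group)
  if (group == "HV")
    data.frame(
      parameter = c("naConcentration", "waterT2", "t2sFast", "t2sSlow",
                    "mFastFraction", "ff"),
      mean = c(19.6, 29.3, 2.2, 13.4, 0.46, 3.4),
      sd = c(3.1, 1.1, 1.3, 2.3, 0.09, 1.2))
  else
    data.frame(
      parameter = c("naConcentration", "waterT2", "t2sFast", "t2sSlow",
                    "mFastFraction", "ff"),
      mean = c(36.2, 33.8, 1.0, 14.0, 0.38, 25.7),
      sd = c(11.4, 2.7, 0.5, 1.5, 0.13, 15.6))
}

#' Construct a [CohortSpec-class]
#'
#' @param nPerGroup subjects per group
#' @param hv,dp per-group parameter tables (see [groupParameterTable()])
#' @param seed integer seed
#' @param timeline an [AcquisitionTimeline-class]
#' @return a [CohortSpec-class]
#' @export
cohortSpec <- function(nPerGroup = 10, hv = groupParameterTable("HV"),
                       dp = groupParameterTable("DP"), seed = 1L,
                       timeline = AcquisitionTimeline()) {
  new("CohortSpec", nPerGroup = as.integer(nPerGroup), hv = hv, dp = dp,
      seed = as.integer(seed), timeline = timeline)
}

# truncation bounds keeping each drawn parameter physical
truthBounds <- list(
  naConcentration = c(1e-6, Inf), waterT2 = c(1e-6, Inf),
  t2sFast = c(0.05, Inf), t2sSlow = c(0.05, Inf),
  mFastFraction = c(0, 1), ff = c(0, 100))

drawTruth <- function(tab, group) {
  val <- list()
  for (i in seq_len(nrow(tab))) {
    p <- tab$parameter[i]
    b <- truthBounds[[p]]
    val[[p]] <- rtruncnorm1(tab$mean[i], tab$sd[i], b[1], b[2])
  }
  # keep the two components separated; redraw the fast one if needed
  for (k in 1:1000) {
    if (val$t2sFast < val$t2sSlow) break
    i <- which(tab$parameter == "t2sFast")
    val$t2sFast <- rtruncnorm1(tab$mean[i], tab$sd[i], 0.05,
                               val$t2sSlow * 0.999)
  }
  subjectTruth(group, naConcentration = val$naConcentration,
               waterT2 = val$waterT2, t2sFast = val$t2sFast,
               t2sSlow = val$t2sSlow, mFastFraction = val$mFastFraction,
               ff = val$ff,
               dynHalfLife = if (group == "HV") 636 else 636,
               dynPeakTime = 480)
}

#' Generate a two-group synthetic cohort
#'
#' Draws per-subject ground truth from truncated normal distributions with
#' the specified group means/SDs, and (optionally) renders each subject's
#' acquisitions: a baseline sodium FID, a multi-echo water series, and
#' post-exercise dynamic series for both modalities. Deterministic for a
#' given spec (including its seed).
#'
#' @param spec a [CohortSpec-class]
#' @param render logical; render acquisitions or return truths only
#' @param fidNoiseSd,echoNoiseSd,dynNoiseSd noise levels for the rendered
#'   acquisitions (defaults give roughly SNR 50 FIDs and low-noise series)
#' @return a list with `truths` (data.frame, one row per subject) and
#'   `subjects` (list of per-subject truth + acquisitions)
#' @export
makeCohort <- function(spec = cohortSpec(), render = TRUE,
                       fidNoiseSd = 0.02, echoNoiseSd = 0.005,
                       dynNoiseSd = 0.01) {
  stopIfNot(is(spec, "CohortSpec"), "spec must be a CohortSpec")
  withSeed(spec@seed, {
    subjects <- list()
    rows <- list()
    idx <- 0L
    for (group in c("HV", "DP")) {
      tab <- slot(spec, tolower(group))
      for (i in seq_len(spec@nPerGroup)) {
        idx <- idx + 1L
        truth <- drawTruth(tab, group)
        id <- sprintf("%s%02d", group, i)
        subj <- list(id = id, truth = truth)
        if (render) {
          subj$fid <- makeFid(truth, amplitude = truth@naConcentration,
                              noiseSd = fidNoiseSd * truth@naConcentration)
          subj$echoes <- makeEchoSeries(truth@waterT2, s0 = 1,
                                        noiseSd = echoNoiseSd)
          subj$dynNa <- makeDynamicSeries(truth, spec@timeline,
                                          "na_amplitude",
                                          noiseSd = dynNoiseSd)
          subj$dynT2 <- makeDynamicSeries(truth, spec@timeline, "water_t2",
                                          halfLife = 620,
                                          noiseSd = dynNoiseSd * truth@waterT2)
        }
        subjects[[id]] <- subj
        rows[[id]] <- data.frame(
          subject = id, group = group,
          naConcentration = truth@naConcentration, waterT2 = truth@waterT2,
          t2sFast = truth@t2sFast, t2sSlow = truth@t2sSlow,
          mFastFraction = truth@mFastFraction, ff = truth@ff)
      }
    }
    list(truths = do.call(rbind, c(rows, list(make.row.names = FALSE))),
         subjects = subjects)
  })
}
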