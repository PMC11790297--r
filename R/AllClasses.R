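#' Free induction decay
#'
#' Complex time-domain MR signal with its sampling metadata. Sample k
#' (0-based) is nominally acquired at `t0 + k * dwell` milliseconds after the
#' centre of the excitation pulse.
#'
#' @slot samples complex vector of time-domain samples (>= 8)
#' @slot dwell dwell time between samples, ms (> 0)
#' @slot t0 time of the first sample after the excitation-pulse centre, ms
#' @slot nucleus `"1H"` or `"23Na"`
#' @slot voxelDims nominal voxel dimensions in mm (length 3, may be `NA`)
#' @slot timestamp acquisition time in seconds relative to exercise end
#'   (`NA` when not part of a dynamic run)
#' @export
setClass("Fid",
  representation(samples = "complex", dwell = "numeric", t0 = "numeric",
                 nucleus = "character", voxelDims = "numeric",
                 timestamp = "numeric"),
  prototype(nucleus = "23Na", voxelDims = c(NA_real_, NA_real_, NA_real_),
            timestamp = NA_real_))

setValidity("Fid", function(object) {
  msg <- character()
  if (length(object@samples) < 8L) msg <- c(msg, "need at least 8 samples")
  if (length(object@dwell) != 1L || !is.finite(object@dwell) ||
      object@dwell <= 0) msg <- c(msg, "dwell must be a single positive number")
  if (length(object@t0) != 1L || !is.finite(object@t0) || object@t0 < 0)
    msg <- c(msg, "t0 must be a single non-negative number")
  if (!object@nucleus %in% c("1H", "23Na"))
    msg <- c(msg, "nucleus must be '1H' or '23Na'")
  if (length(msg)) msg else TRUE
})

#' Construct a [Fid-class] object
#'
#' @param samples complex (or numeric, promoted to complex) sample vector
#' @param dwell dwell time, ms
#' @param t0 time of the first sample, ms
#' @param nucleus `"1H"` or `"23Na"`
#' @param voxelDims voxel dimensions, mm
#' @param timestamp seconds relative to exercise end, or `NA`
#' @return a [Fid-class]
#' @export
Fid <- function(samples, dwell, t0 = 0, nucleus = "23Na",
                voxelDims = c(NA_real_, NA_real_, NA_real_),
                timestamp = NA_real_) {
  new("Fid", samples = as.complex(samples), dwell = as.numeric(dwell),
      t0 = as.numeric(t0), nucleus = nucleus,
      voxelDims = as.numeric(voxelDims), timestamp = as.numeric(timestamp))
}

#' @rdname accessors
#' @export
setMethod("samples", "Fid", function(x) x@samples)

#' @rdname accessors
#' @export
setMethod("dwellTime", "Fid", function(x) x@dwell)

#' @describeIn Fid-class sample times `t0 + k * dwell` in ms
#' @param x,object a `Fid`
#' @param ... unused
#' @export
setMethod("timePoints", "Fid", function(x, ...)
  x@t0 + (seq_along(x@samples) - 1) * x@dwell)

setMethod("show", "Fid", function(object) {
  cat(sprintf("Fid: %d %s samples, dwell %.4g ms, t0 %.4g ms\n",
              length(object@samples), object@nucleus, object@dwell,
              object@t0))
})

#' Frequency-domain spectrum
#'
#' Discrete Fourier transform of a [Fid-class], with the processing that
#' produced it recorded (zero-fill factor, exponential apodization).
#'
#' @slot frequency frequency axis, Hz (ascending)
#' @slot values complex spectral values, same length as `frequency`
#' @slot processing list with elements `zero_fill` and `apodization_hz`
#' @export
setClass("Spectrum",
  representation(frequency = "numeric", values = "complex",
                 processing = "list"))

setValidity("Spectrum", function(object) {
  if (length(object@frequency) != length(object@values))
    "frequency axis and values must have equal length" else TRUE
})

#' @rdname accessors
#' @export
setMethod("frequencyAxis", "Spectrum", function(x) x@frequency)

#' @rdname accessors
#' @export
setMethod("values", "Spectrum", function(x) x@values)

setMethod("show", "Spectrum", function(object) {
  cat(sprintf("Spectrum: %d points, %.4g to %.4g Hz\n",
              length(object@values), min(object@frequency),
              max(object@frequency)))
})

#' Signal amplitude per echo time
#'
#' Water signal amplitude as a function of echo time, either fitted from
#' per-echo spectroscopy or generated synthetically.
#'
#' @slot echoTimes echo times, ms, strictly increasing
#' @slot amplitudes signal amplitudes, arbitrary units
#' @slot source `"fitted"` or `"synthetic"`
#' @export
setClass("EchoAmplitudeSeries",
  representation(echoTimes = "numeric", amplitudes = "numeric",
                 source = "character"),
  prototype(source = "synthetic"))

setValidity("EchoAmplitudeSeries", function(object) {
  msg <- character()
  if (length(object@echoTimes) != length(object@amplitudes))
    msg <- c(msg, "echoTimes and amplitudes must have equal length")
  if (length(object@echoTimes) &&
      (any(object@echoTimes <= 0) || any(diff(object@echoTimes) <= 0)))
    msg <- c(msg, "echoTimes must be positive and strictly increasing")
  if (!object@source %in% c("fitted", "synthetic"))
    msg <- c(msg, "source must be 'fitted' or 'synthetic'")
  if (length(msg)) msg else TRUE
})

#' Construct an [EchoAmplitudeSeries-class]
#' @param echoTimes echo times, ms
#' @param amplitudes amplitudes, arbitrary units
#' @param source `"fitted"` or `"synthetic"`
#' @return an [EchoAmplitudeSeries-class]
#' @export
EchoAmplitudeSeries <- function(echoTimes, amplitudes, source = "synthetic") {
  new("EchoAmplitudeSeries", echoTimes = as.numeric(echoTimes),
      amplitudes = as.numeric(amplitudes), source = source)
}

#' @rdname accessors
#' @export
setMethod("echoTimes", "EchoAmplitudeSeries", function(x) x@echoTimes)

#' @rdname accessors
#' @export
setMethod("amplitudes", "EchoAmplitudeSeries", function(x) x@amplitudes)

setMethod("show", "EchoAmplitudeSeries", function(object) {
  cat(sprintf("EchoAmplitudeSeries (%s): %d echoes, TE %.4g-%.4g ms\n",
              object@source, length(object@echoTimes),
              min(object@echoTimes), max(object@echoTimes)))
})

#' Post-exercise dynamic time course
#'
#' Timestamped post-exercise measurements of one modality for one subject,
#' together with that subject's pre-exercise baseline value.
#'
#' @slot timestamps seconds since exercise end, strictly increasing
#' @slot values measurement values (arbitrary units for sodium amplitude,
#'   ms for water T2)
#' @slot modality `"na_amplitude"` or `"water_t2"`
#' @slot baselineValue pre-exercise baseline, same units as `values`
#' @slot subject subject identifier
#' @slot group `"HV"` (healthy volunteer) or `"DP"` (dysferlinopathy patient)
#' @export
setClass("DynamicSeries",
  representation(timestamps = "numeric", values = "numeric",
                 modality = "character", baselineValue = "numeric",
                 subject = "character", group = "character"),
  prototype(subject = "s1", group = "HV"))

setValidity("DynamicSeries", function(object) {
  msg <- character()
  if (length(object@timestamps) != length(object@values))
    msg <- c(msg, "timestamps and values must have equal length")
  if (length(object@timestamps) < 3L)
    msg <- c(msg, "need at least 3 timepoints")
  if (length(object@timestamps) > 1L && any(diff(object@timestamps) <= 0))
    msg <- c(msg, "timestamps must be strictly increasing")
  if (!object@modality %in% c("na_amplitude", "water_t2"))
    msg <- c(msg, "modality must be 'na_amplitude' or 'water_t2'")
  if (!object@group %in% c("HV", "DP"))
    msg <- c(msg, "group must be 'HV' or 'DP'")
  if (length(msg)) msg else TRUE
})

#' Construct a [DynamicSeries-class]
#' @param timestamps seconds since exercise end
#' @param values measurement values
#' @param modality `"na_amplitude"` or `"water_t2"`
#' @param baselineValue pre-exercise baseline
#' @param subject subject id
#' @param group `"HV"` or `"DP"`
#' @return a [DynamicSeries-class]
#' @export
DynamicSeries <- function(timestamps, values, modality, baselineValue,
                          subject = "s1", group = "HV") {
  new("DynamicSeries", timestamps = as.numeric(timestamps),
      values = as.numeric(values), modality = modality,
      baselineValue = as.numeric(baselineValue), subject = subject,
      group = group)
}

#' @rdname accessors
#' @export
setMethod("timestamps", "DynamicSeries", function(x) x@timestamps)

#' @rdname accessors
#' @export
setMethod("values", "DynamicSeries", function(x) x@values)

#' @rdname accessors
#' @export
setMethod("modality", "DynamicSeries", function(x) x@modality)

#' @rdname accessors
#' @export
setMethod("baselineValue", "DynamicSeries", function(x) x@baselineValue)

setMethod("show", "DynamicSeries", function(object) {
  cat(sprintf("DynamicSeries [%s, %s, %s]: %d timepoints over %.0f s\n",
              object@subject, object@group, object@modality,
              length(object@timestamps), max(object@timestamps)))
})

#' Interleaved post-exercise acquisition timeline
#'
#' Cadence of the alternating sodium-spectroscopy / proton-spectroscopy
#' acquisition after exercise. Timestamps are assigned at scan midpoints.
#'
#' @slot naScanDuration duration of one sodium spectroscopy scan, s
#' @slot hScanDuration duration of one proton spectroscopy scan, s
#' @slot nCycles number of interleaved cycles
#' @slot postExerciseSpan total observed span, s
#' @export
setClass("AcquisitionTimeline",
  representation(naScanDuration = "numeric", hScanDuration = "numeric",
                 nCycles = "integer", postExerciseSpan = "numeric"))

setValidity("AcquisitionTimeline", function(object) {
  msg <- character()
  if (object@naScanDuration <= 0 || object@hScanDuration <= 0)
    msg <- c(msg, "scan durations must be positive")
  if (object@nCycles < 1L) msg <- c(msg, "nCycles must be >= 1")
  if (object@postExerciseSpan <= 0)
    msg <- c(msg, "postExerciseSpan must be positive")
  if (length(msg)) msg else TRUE
})

#' Construct an [AcquisitionTimeline-class]
#'
#' Defaults follow the interleaved protocol: 129 s sodium scans alternating
#' with 45 s proton scans, at least 10 cycles.
#'
#' @param naScanDuration sodium scan duration, s
#' @param hScanDuration proton scan duration, s
#' @param nCycles number of cycles; by default as many full cycles as fit in
#'   `postExerciseSpan`
#' @param postExerciseSpan observed post-exercise span, s
#' @return an [AcquisitionTimeline-class]
#' @export
AcquisitionTimeline <- function(naScanDuration = 129, hScanDuration = 45,
                                nCycles = NULL, postExerciseSpan = 1800) {
  cycle <- naScanDuration + hScanDuration
  if (is.null(nCycles)) nCycles <- max(1L, as.integer(postExerciseSpan %/% cycle))
  new("AcquisitionTimeline", naScanDuration = as.numeric(naScanDuration),
      hScanDuration = as.numeric(hScanDuration),
      nCycles = as.integer(nCycles),
      postExerciseSpan = as.numeric(postExerciseSpan))
}

#' @describeIn AcquisitionTimeline-class scan-midpoint timestamps (s) for one
#'   modality (`"na_amplitude"` starts each cycle, `"water_t2"` follows)
#' @param x,object an `AcquisitionTimeline`
#' @param modality which interleaved modality to return midpoints for
#' @param ... unused
#' @export
setMethod("timePoints", "AcquisitionTimeline",
  function(x, modality = c("na_amplitude", "water_t2"), ...) {
    modality <- match.arg(modality)
    cycle <- x@naScanDuration + x@hScanDuration
    start <- (seq_len(x@nCycles) - 1) * cycle
    if (modality == "na_amplitude") start + x@naScanDuration / 2
    else start + x@naScanDuration + x@hScanDuration / 2
  })

setMethod("show", "AcquisitionTimeline", function(object) {
  cat(sprintf(
    "AcquisitionTimeline: %d cycles of %.0f s (23Na) + %.0f s (1H)\n",
    object@nCycles, object@naScanDuration, object@hScanDuration))
})

#' Three-echo Dixon acquisition
#'
#' Complex echo images with their echo times, field strength and the
#' multi-peak fat spectral model used to interpret them. Echo images are
#' arrays of identical dimensions (2D or 3D).
#'
#' @slot echoes list of complex arrays, one per echo
#' @slot echoTimes echo times, ms
#' @slot fieldStrength main field strength, tesla
#' @slot fatSpectrum data.frame with columns `ppm` (chemical shift) and
#'   `amplitude` (relative amplitude summing to 1)
#' @export
setClass("DixonSeries",
  representation(echoes = "list", echoTimes = "numeric",
                 fieldStrength = "numeric", fatSpectrum = "data.frame"))

setValidity("DixonSeries", function(object) {
  msg <- character()
  if (length(object@echoes) < 3L) msg <- c(msg, "need at least 3 echoes")
  if (length(object@echoes) != length(object@echoTimes))
    msg <- c(msg, "one echo time per echo image")
  dims <- lapply(object@echoes, dim)
  if (length(unique(vapply(dims, paste, "", collapse = "x"))) > 1L)
    msg <- c(msg, "echo images must share dimensions")
  if (!all(c("ppm", "amplitude") %in% names(object@fatSpectrum)))
    msg <- c(msg, "fatSpectrum needs columns ppm and amplitude")
  else if (abs(sum(object@fatSpectrum$amplitude) - 1) > 1e-9)
    msg <- c(msg, "fat spectrum amplitudes must sum to 1")
  if (length(msg)) msg else TRUE
})

#' Construct a [DixonSeries-class]
#' @param echoes list of complex arrays (equal dimensions), one per echo
#' @param echoTimes echo times, ms (default the out-in-out scheme
#'   3.45, 4.60, 5.75)
#' @param fieldStrength field strength in tesla
#' @param fatSpectrum multi-peak fat model (see [defaultFatSpectrum()])
#' @return a [DixonSeries-class]
#' @export
DixonSeries <- function(echoes, echoTimes = c(3.45, 4.60, 5.75),
                        fieldStrength = 3,
                        fatSpectrum = defaultFatSpectrum()) {
  echoes <- lapply(echoes, function(e) {
    storage.mode(e) <- "complex"
    if (is.null(dim(e))) dim(e) <- length(e)
    e
  })
  new("DixonSeries", echoes = echoes, echoTimes = as.numeric(echoTimes),
      fieldStrength = as.numeric(fieldStrength), fatSpectrum = fatSpectrum)
}

#' @rdname accessors
#' @export
setMethod("echoTimes", "DixonSeries", function(x) x@echoTimes)

setMethod("show", "DixonSeries", function(object) {
  cat(sprintf("DixonSeries: %d echoes (%s ms) at %.1f T, image %s\n",
              length(object@echoes),
              paste(object@echoTimes, collapse = ", "),
              object@fieldStrength,
              paste(dim(object@echoes[[1]]), collapse = "x")))
})

#' Subject-level generating truth
#'
#' Ground-truth parameters behind one synthetic subject: tissue sodium
#' concentration, relaxometry, fat fraction and post-exercise dynamics.
#'
#' @slot group `"HV"` or `"DP"`
#' @slot naConcentration true tissue sodium concentration, mM
#' @slot waterT2 true muscle water T2, ms
#' @slot t2sFast fast sodium T2* component, ms
#' @slot t2sSlow slow sodium T2* component, ms
#' @slot mFastFraction fraction of sodium signal in the fast component, [0,1]
#' @slot ff fat fraction, percent
#' @slot dynHalfLife post-exercise recovery half-life, s
#' @slot dynPeakTime time of the sodium peak after exercise, s
#' @slot dynPeakRatio peak/baseline amplitude ratio (>= 1)
#' @export
setClass("SubjectTruth",
  representation(group = "character", naConcentration = "numeric",
                 waterT2 = "numeric", t2sFast = "numeric",
                 t2sSlow = "numeric", mFastFraction = "numeric",
                 ff = "numeric", dynHalfLife = "numeric",
                 dynPeakTime = "numeric", dynPeakRatio = "numeric"))

setValidity("SubjectTruth", function(object) {
  msg <- character()
  if (!object@group %in% c("HV", "DP"))
    msg <- c(msg, "group must be 'HV' or 'DP'")
  if (object@naConcentration <= 0)
    msg <- c(msg, "naConcentration must be positive")
  if (object@t2sFast >= object@t2sSlow)
    msg <- c(msg, "t2sFast must be smaller than t2sSlow")
  if (object@mFastFraction < 0 || object@mFastFraction > 1)
    msg <- c(msg, "mFastFraction must lie in [0, 1]")
  if (object@ff < 0 || object@ff > 100)
    msg <- c(msg, "ff must lie in [0, 100] percent")
  if (object@dynPeakRatio < 1)
    msg <- c(msg, "dynPeakRatio must be >= 1")
  if (length(msg)) msg else TRUE
})

setMethod("show", "SubjectTruth", function(object) {
  cat(sprintf(
    "SubjectTruth [%s]: [Na] %.1f mM, water T2 %.1f ms, T2* %.2f/%.2f ms (f=%.2f), FF %.1f%%\n",
    object@group, object@naConcentration, object@waterT2, object@t2sFast,
    object@t2sSlow, object@mFastFraction, object@ff))
})

#' Region-of-interest statistics
#'
#' Mean, standard deviation and voxel count of a magnitude image over a
#' labelled region.
#'
#' @slot mean ROI mean signal
#' @slot sd ROI standard deviation
#' @slot nVoxels number of voxels
#' @slot label region label
#' @export
setClass("RoiStats",
  representation(mean = "numeric", sd = "numeric", nVoxels = "integer",
                 label = "character"),
  prototype(label = "roi"))

setValidity("RoiStats", function(object) {
  msg <- character()
  if (object@nVoxels < 1L) msg <- c(msg, "nVoxels must be >= 1")
  if (object@sd < 0) msg <- c(msg, "sd must be non-negative")
  if (length(msg)) msg else TRUE
})

#' Construct a [RoiStats-class]
#' @param mean ROI mean
#' @param sd ROI standard deviation
#' @param nVoxels voxel count
#' @param label region label
#' @return a [RoiStats-class]
#' @export
RoiStats <- function(mean, sd = 0, nVoxels = 1L, label = "roi") {
  new("RoiStats", mean = as.numeric(mean), sd = as.numeric(sd),
      nVoxels = as.integer(nVoxels), label = label)
}

#' Reference phantom standard
#'
#' A sodium concentration standard of known concentration with its
#' relaxation behaviour (relative slow/fast magnitudes summing to 1 and the
#' corresponding T2* values) and measured ROI statistics.
#'
#' @slot concentration known NaCl concentration, mM
#' @slot mSlow,mFast relative magnitudes of the slow/fast components (sum 1)
#' @slot t2sSlow,t2sFast slow/fast T2*, ms
#' @slot roi [RoiStats-class] of the phantom ROI
#' @export
setClass("PhantomStandard",
  representation(concentration = "numeric", mSlow = "numeric",
                 mFast = "numeric", t2sSlow = "numeric", t2sFast = "numeric",
                 roi = "RoiStats"))

setValidity("PhantomStandard", function(object) {
  msg <- character()
  if (object@concentration <= 0) msg <- c(msg, "concentration must be > 0")
  if (abs(object@mSlow + object@mFast - 1) > 1e-9)
    msg <- c(msg, "mSlow + mFast must equal 1")
  if (object@t2sSlow <= 0 || object@t2sFast <= 0)
    msg <- c(msg, "T2* values must be positive")
  if (length(msg)) msg else TRUE
})

#' Construct a [PhantomStandard-class]
#'
#' Defaults describe an aqueous agar standard whose sodium decay is
#' effectively monoexponential (`mSlow = 1`).
#'
#' @param concentration known concentration, mM
#' @param mSlow,mFast relative component magnitudes (must sum to 1)
#' @param t2sSlow,t2sFast component T2*, ms
#' @param roi a [RoiStats-class] (default a unit placeholder)
#' @return a [PhantomStandard-class]
#' @export
PhantomStandard <- function(concentration = 20, mSlow = 1, mFast = 0,
                            t2sSlow = 55, t2sFast = 30,
                            roi = RoiStats(1)) {
  new("PhantomStandard", concentration = as.numeric(concentration),
      mSlow = as.numeric(mSlow), mFast = as.numeric(mFast),
      t2sSlow = as.numeric(t2sSlow), t2sFast = as.numeric(t2sFast),
      roi = roi)
}

setMethod("show", "PhantomStandard", function(object) {
  cat(sprintf("PhantomStandard: %.0f mM, Ms %.2f / Mf %.2f, T2* %.1f/%.1f ms\n",
              object@concentration, object@mSlow, object@mFast,
              object@t2sSlow, object@t2sFast))
})

#' Tissue relaxometry for concentration correction
#'
#' Per-subject relative slow/fast sodium signal magnitudes and T2* values,
#' normally taken from the subject's baseline biexponential fit.
#'
#' @slot mSlow,mFast relative magnitudes (sum to 1)
#' @slot t2sSlow,t2sFast component T2*, ms
#' @export
setClass("TissueRelaxometry",
  representation(mSlow = "numeric", mFast = "numeric", t2sSlow = "numeric",
                 t2sFast = "numeric"))

setValidity("TissueRelaxometry", function(object) {
  msg <- character()
  if (abs(object@mSlow + object@mFast - 1) > 1e-9)
    msg <- c(msg, "mSlow + mFast must equal 1")
  if (object@t2sSlow <= 0 || object@t2sFast <= 0)
    msg <- c(msg, "T2* values must be positive")
  if (length(msg)) msg else TRUE
})

#' Construct a [TissueRelaxometry-class]
#' @param mSlow,mFast relative component magnitudes (sum 1)
#' @param t2sSlow,t2sFast component T2*, ms
#' @return a [TissueRelaxometry-class]
#' @export
TissueRelaxometry <- function(mSlow, mFast, t2sSlow, t2sFast) {
  new("TissueRelaxometry", mSlow = as.numeric(mSlow),
      mFast = as.numeric(mFast), t2sSlow = as.numeric(t2sSlow),
      t2sFast = as.numeric(t2sFast))
}

#' @describeIn TissueRelaxometry-class relaxometry from a biexponential fit
#' @param fit a [BiexpT2StarFit-class]
#' @export
relaxometryFromFit <- function(fit) {
  stopifnot(is(fit, "BiexpT2StarFit"))
  tot <- fit@mFast + fit@mSlow
  TissueRelaxometry(mSlow = fit@mSlow / tot, mFast = fit@mFast / tot,
                    t2sSlow = fit@t2sSlow, t2sFast = fit@t2sFast)
}
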