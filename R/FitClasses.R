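#' Biexponential sodium T2* fit result
#'
#' Parameters of the magnitude-domain model
#' `M(t) = sqrt((m_fast exp(-t/T2*_fast) + m_slow exp(-t/T2*_slow))^2 +
#' offset^2)`, with components ordered so that `t2sFast < t2sSlow`.
#'
#' @slot mFast,mSlow component magnitudes at t = 0 (>= 0)
#' @slot t2sFast,t2sSlow component T2* values, ms
#' @slot noiseOffset fitted magnitude noise floor (enters in quadrature)
#' @slot rss residual sum of squares
#' @slot converged logical convergence flag
#' @slot flags character vector of quality flags (e.g.
#'   `"effectively_monoexponential"`)
#' @export
setClass("BiexpT2StarFit",
  representation(mFast = "numeric", mSlow = "numeric", t2sFast = "numeric",
                 t2sSlow = "numeric", noiseOffset = "numeric",
                 rss = "numeric", converged = "logical",
                 flags = "character"),
  prototype(flags = character()))

setValidity("BiexpT2StarFit", function(object) {
  msg <- character()
  if (object@mFast < 0 || object@mSlow < 0)
    msg <- c(msg, "component magnitudes must be non-negative")
  if (object@t2sFast > object@t2sSlow)
    msg <- c(msg, "components must be ordered t2sFast <= t2sSlow")
  if (length(msg)) msg else TRUE
})

#' @rdname accessors
#' @export
setMethod("fastFraction", "BiexpT2StarFit", function(x) {
  tot <- x@mFast + x@mSlow
  if (tot == 0) NA_real_ else x@mFast / tot
})

#' @rdname accessors
#' @export
setMethod("totalAmplitude", "BiexpT2StarFit", function(x) x@mFast + x@mSlow)

#' @rdname accessors
#' @export
setMethod("converged", "BiexpT2StarFit", function(x) x@converged)

setMethod("show", "BiexpT2StarFit", function(object) {
  cat(sprintf(
    "BiexpT2StarFit: T2*fast %.3g ms, T2*slow %.3g ms, fast fraction %.3f\n",
    object@t2sFast, object@t2sSlow, fastFraction(object)))
  cat(sprintf("  m_fast %.4g, m_slow %.4g, offset %.4g, RSS %.4g%s\n",
              object@mFast, object@mSlow, object@noiseOffset, object@rss,
              if (length(object@flags))
                paste0(" [", paste(object@flags, collapse = ", "), "]")
              else ""))
})

#' Monoexponential T2 fit result
#'
#' Parameters of `S(TE) = s0 exp(-TE/T2)` fitted across echo times.
#'
#' @slot s0 extrapolated amplitude at TE = 0
#' @slot t2 transverse relaxation time, ms
#' @slot rss residual sum of squares
#' @slot converged logical convergence flag
#' @slot flags quality flags (e.g. `"non_decaying"`)
#' @export
setClass("MonoT2Fit",
  representation(s0 = "numeric", t2 = "numeric", rss = "numeric",
                 converged = "logical", flags = "character"),
  prototype(flags = character()))

#' @rdname accessors
#' @export
setMethod("converged", "MonoT2Fit", function(x) x@converged)

setMethod("show", "MonoT2Fit", function(object) {
  cat(sprintf("MonoT2Fit: T2 %.4g ms, s0 %.4g, RSS %.4g%s\n",
              object@t2, object@s0, object@rss,
              if (length(object@flags))
                paste0(" [", paste(object@flags, collapse = ", "), "]")
              else ""))
})

#' Single-resonance time-domain fit result
#'
#' Parameters of one exponentially damped complex sinusoid
#' `s(t) = A exp(i phi) exp(2 pi i f t) exp(-t/tau)` fitted to a proton FID;
#' `amplitude` is the extrapolate at t = 0 (pulse centre).
#'
#' @slot amplitude signal amplitude at t = 0
#' @slot frequency resonance offset, Hz
#' @slot damping decay time constant tau, ms
#' @slot phase phase at t = 0, radians
#' @slot rss residual sum of squares (real + imaginary channels)
#' @slot converged logical convergence flag
#' @export
setClass("LorentzianFit",
  representation(amplitude = "numeric", frequency = "numeric",
                 damping = "numeric", phase = "numeric", rss = "numeric",
                 converged = "logical"))

#' @rdname accessors
#' @export
setMethod("converged", "LorentzianFit", function(x) x@converged)

setMethod("show", "LorentzianFit", function(object) {
  cat(sprintf(
    "LorentzianFit: amplitude %.4g, freq %.4g Hz, tau %.4g ms, phase %.3f rad\n",
    object@amplitude, object@frequency, object@damping, object@phase))
})

#' Recovery kinetics fit result
#'
#' Parameters of the three-parameter exponential recovery
#' `v(t) = baseline + (s0Post - baseline) * 2^(-t / halfLife)`, with the
#' 95% confidence interval of the half-life from the asymptotic covariance.
#'
#' @slot s0Post theoretical value at the start of the fitted segment
#' @slot halfLife recovery half-life, s
#' @slot baseline asymptotic baseline value
#' @slot ci95HalfLife half-width of the 95% CI on `halfLife`, s
#' @slot rss residual sum of squares
#' @slot converged logical convergence flag
#' @slot flags quality flags (e.g. `"degenerate"`, `"at_bound"`)
#' @export
setClass("RecoveryFit",
  representation(s0Post = "numeric", halfLife = "numeric",
                 baseline = "numeric", ci95HalfLife = "numeric",
                 rss = "numeric", converged = "logical",
                 flags = "character"),
  prototype(flags = character()))

#' @rdname accessors
#' @export
setMethod("halfLife", "RecoveryFit", function(x) x@halfLife)

#' @rdname accessors
#' @export
setMethod("converged", "RecoveryFit", function(x) x@converged)

setMethod("show", "RecoveryFit", function(object) {
  cat(sprintf(
    "RecoveryFit: T1/2 %.4g s (95%% CI +/- %.3g), baseline %.4g, s0 %.4g%s\n",
    object@halfLife, object@ci95HalfLife, object@baseline, object@s0Post,
    if (length(object@flags))
      paste0(" [", paste(object@flags, collapse = ", "), "]") else ""))
})

#' Tissue sodium concentration result
#'
#' Phantom-calibrated, relaxation-corrected tissue sodium concentration.
#'
#' @slot concentration tissue sodium concentration, mM
#' @slot correctionFactor relaxation correction `D_P(TE) / D_TA(TE)`
#' @slot siTa,siP tissue and phantom signal intensities used
#' @slot te echo time at which the correction was evaluated, ms
#' @export
setClass("SodiumConcentrationResult",
  representation(concentration = "numeric", correctionFactor = "numeric",
                 siTa = "numeric", siP = "numeric", te = "numeric"))

setMethod("show", "SodiumConcentrationResult", function(object) {
  cat(sprintf(
    "SodiumConcentrationResult: %.3g mM (correction %.4f at TE %.3g ms)\n",
    object@concentration, object@correctionFactor, object@te))
})

#' Dixon fat-water separation result
#'
#' Per-voxel water and fat magnitude maps, shared R2* and field-offset maps,
#' and the derived fat-fraction map `ff = 100 F / (W + F)` (0/0 voxels are
#' set to 0 and flagged).
#'
#' @slot water,fat non-negative magnitude maps, arbitrary units
#' @slot r2star shared effective relaxation rate map, 1/s
#' @slot fieldMap field offset map, Hz
#' @slot ff fat-fraction map, percent in [0, 100]
#' @slot zeroSignal logical map of 0/0 voxels excluded from summaries
#' @slot swapUnresolved number of voxels whose field-offset candidate could
#'   not be anchored to a neighbour during region growing
#' @export
setClass("FatWaterResult",
  representation(water = "array", fat = "array", r2star = "array",
                 fieldMap = "array", ff = "array", zeroSignal = "array",
                 swapUnresolved = "integer"),
  prototype(swapUnresolved = 0L))

#' @rdname accessors
#' @export
setMethod("ffMap", "FatWaterResult", function(x) x@ff)

setMethod("show", "FatWaterResult", function(object) {
  cat(sprintf(
    "FatWaterResult: %s voxels, mean FF %.2f%%, %d zero-signal, %d unresolved\n",
    paste(dim(object@ff), collapse = "x"),
    mean(object@ff[!object@zeroSignal]), sum(object@zeroSignal),
    object@swapUnresolved))
})
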