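---
title: "Models and methods for quantitative muscle sodium/proton MR"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods for quantitative muscle sodium/proton MR}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(naqms)
```

# Scope

`naqms` implements the quantitative analysis chain for interleaved
²³Na/¹H MR studies of skeletal muscle: sodium T2\* relaxometry,
phantom-calibrated tissue sodium concentration, multi-echo water T2,
post-exercise recovery kinetics, Dixon fat-fraction mapping, and the
nonparametric statistics used to compare patient and control cohorts. A
synthetic-data generator with known ground truth stands in for scanner
data, so every stage is validated by parameter recovery. This vignette
records the models, their assumptions, the defaults and the design choices
that were genuinely open.

# Sodium T2\* relaxometry

Tissue ²³Na signal decays biexponentially: quadrupolar interactions in
motion-restricted environments split the signal into a fast component
(T2\*~1–3 ms) and a slow component (~13–14 ms). We fit the magnitude of
the time-domain FID sampled at `t_k = t0 + k·dwell` (defaults: 1024
samples, dwell 0.125 ms — a 128 ms readout — and t0 = 0.16 ms, the
acquisition's echo time) with

$$M(t) = \sqrt{\left(M_f e^{-t/T_{2f}^*} + M_s e^{-t/T_{2s}^*}\right)^2 + \nu^2}.$$

**Why a quadrature noise floor.** Complex Gaussian noise makes the
magnitude Rician, with mean $\approx A$ for $A \gg \sigma$ and
$\sigma\sqrt{\pi/2}$ at $A = 0$. A noise term *added* to the envelope
overshoots the Rician mean in the crossover region; in simulation at SNR
50 this biased the fitted slow T2\* about 17% low and the fast fraction
about 5 points low. The root-sum-of-squares form
$\sqrt{A(t)^2 + \nu^2}$ tracks the crossover closely (residual bias
≈ 2% on the slow component) and reduces to the plain biexponential as
$\nu \to 0$. A full Rician likelihood would remove the remaining bias but
is deliberately out of scope.

**Numerics.** Bounded Levenberg–Marquardt (`minpack.lm::nls.lm`) with all
parameters non-negative and T2\* in [0.05, 500] ms; when no starting value
is given, five starts with T2\* pairs log-spaced over [0.3, 50] ms and the
amplitude split 50/50, keeping the lowest residual sum of squares (ties
broken toward the smaller fast T2\*). Components are ordered post-fit so
the fast one is shorter; fits whose two T2\* values differ by under 5% are
flagged `effectively_monoexponential`; non-convergence is flagged, never
silent.

The fitting domain is the magnitude of the time-domain data. Fitting a
phased real channel would gain √2 in noise but requires a phase estimation
step that the short-T2 first samples make fragile; magnitude fitting with
the floor model is robust and is validated to recover both cohorts'
generating parameters (2.2/13.4 ms at 46% fast, and 1.0/14.0 ms at 38%).

# Spectra, peak areas and the water resonance

`fidToSpectrum()` applies optional exponential apodization
(`exp(-π·lb·t)`, lb in Hz), halves the first point (so that the integrated
spectrum is consistent with the time-domain amplitude), zero-fills, and
discrete-Fourier-transforms; values are scaled by the dwell time to
approximate the continuous transform. `peakArea()` integrates the
magnitude spectrum over a window (default ±250 Hz) after subtracting a
linear baseline through the means of the 10 points at each window edge —
the window and baseline rule are configuration, since no standard exists.

The ¹H water amplitude per echo is obtained by fitting one exponentially
damped complex sinusoid to the time-domain FID (amplitude, frequency,
damping, phase), the single-resonance special case of standard
time-domain spectroscopy quantification. The amplitude is extrapolated to
t = 0 at the pulse centre. This assumes a water-dominated voxel, which
holds for spectroscopy voxels placed in the tibialis anterior; lipid
resonances are not modelled.

Water T2 comes from `fitMonoT2()` across echo times (defaults
30, 40, 60, 80, 100, 150 ms), with T2 bounded in (1, 1000) ms and the fit
initialised from a log-linear regression (which also serves as the test
oracle: on noiseless data the two agree to 1e-6).

# Tissue sodium concentration

With a reference phantom of known concentration (20 mM NaCl among the
10/20/30/40 mM standards), concentration is

$$\mathrm{Na}_{TA} = \mathrm{Na}_P \cdot \frac{SI_{TA}}{SI_P} \cdot
\frac{M_s^P e^{-TE/T_{2s}^{*P}} + M_f^P e^{-TE/T_{2f}^{*P}}}
     {M_s^{TA} e^{-TE/T_{2s}^{*TA}} + M_f^{TA} e^{-TE/T_{2f}^{*TA}}}.$$

Choices a user should know:

- `SI` values are ROI **means** of magnitude images (consistent with the
  SNR definition's vocabulary); the correction is applied to ROI-mean
  signals rather than per voxel.
- Background-noise subtraction is *not* applied inside the concentration
  formula (it appears only in the SNR definition); pre-correct the inputs
  with `noiseBiasCorrect()` if desired.
- TE defaults to 0.28 ms (ultrashort radial acquisition); the cartesian
  1.89 ms is supported via the `te` argument. At TE = 0 the correction is
  exactly 1 because each relaxometry's fractions sum to 1.
- The phantom's relaxation parameters are configuration. The defaults
  (`mSlow = 1`, T2\*slow = 55 ms) describe an effectively monoexponential
  aqueous agar standard; they are a synthetic stand-in chosen once, since
  reference values for the physical standards are measured per site, and
  synthetic runs derive them from the generator.
- The remaining standards feed `calibrationCheck()` (ordinary
  least-squares of ROI mean against concentration, warning below
  R² = 0.99), not the concentration formula itself.

# Post-exercise dynamics

Sodium amplitude rises for roughly 8 minutes after exercise before
recovering; water T2 is maximal at the first post-exercise timepoint. Both
recoveries are fitted with the three-parameter exponential

$$v(t) = b + (S_0 - b)\,2^{-t/T_{1/2}},$$

parameterised directly in half-life (a conversion to the e-folding time is
`T½ = τ·ln 2`). Because a decay model cannot represent the initial rise,
`fitRecovery()` defaults to starting at the series peak (located after
3-point moving-average smoothing, ties to the earliest timepoint) with
time re-zeroed there; `fromPeak = FALSE` fits from exercise end, and both
conventions can be reported. The water-T2 decline always starts at the
first timepoint. Half-life is bounded in (10, 10⁴) s; its 95% CI comes
from the asymptotic covariance. Degenerate fits (amplitude ≈ 0) and
half-lives at a bound are flagged.

Timestamps are assigned at scan midpoints of the interleaved cadence
(129 s sodium scans alternating with 45 s proton scans); group-mean curves
are built by per-subject linear interpolation onto a common grid before
averaging, since real cohorts' cadences differ. Per-timepoint deviation
from baseline uses the two-tailed Wilcoxon signed-rank test on
(value − subject baseline), exact for n ≤ 25 without ties and the
continuity-corrected normal approximation otherwise.

# Dixon fat–water separation

Three complex echoes (TE 3.45, 4.60, 5.75 ms at 3 T, an out–in–out phase
scheme) are modelled per voxel as

$$S(TE) = \left(W + F\sum_j a_j e^{2\pi i \Delta f_j TE}\right)
e^{2\pi i \psi TE} e^{-TE\,R_2^*},$$

with a six-peak fat spectrum (shifts relative to water at 4.7 ppm;
amplitudes summing to 1) shipped as a plain-text table
(`inst/extdata/fat_spectrum_6peak.csv`) and configurable — the multi-peak
model is a modelling convention, not a measured constant. A single R2\* is
shared by water and fat.

The solver uses variable projection: for a candidate (ψ, R2\*) the data
are demodulated and the complex (W, F) solved linearly against the
constant design [1, c(TE)]. Candidates are scanned on a shared coarse grid
(ψ ± 150 Hz in 5 Hz steps, R2\* 0–300 s⁻¹ in 25 s⁻¹ steps), and each
voxel's candidate basins (local minima of its ψ cost profile) are
disambiguated by region growing from the highest-magnitude voxel, each
voxel taking the basin nearest its decided neighbours' field offset —
water/fat swaps are the classic failure mode of chemical-shift imaging,
and smoothness of the field map is the standard prior. (ψ, R2\*) are then
refined per voxel by a shrinking local grid; all steps are vectorised
across voxels. Demodulation weights later echoes slightly differently
than the raw least-squares objective under noise; at the echo spacings
used the effect is negligible and the noiseless solution is exact
(fat-fraction error < 1 point across FF 0–100%, R2\* within 5%).

Magnitude noise bias is corrected as `sqrt(max(M² − 2σ², 0))` (two
quadrature channels), with σ estimated from a background ROI's standard
deviation divided by the Rayleigh factor `sqrt(2 − π/2)`. The corrected
*squared* signal is unbiased; the corrected mean itself retains the Jensen
shortfall σ²/(2A) — about 2% at A = 5σ — which users should keep in mind
for low-SNR regions. Fat-fraction summaries average masked voxels (not
slices), excluding and counting zero-signal voxels.

# Statistics

Baseline group comparisons use the two-tailed Mann–Whitney U test, exact
when the smaller group has ≤ 8 observations and no ties (both exact and
asymptotic p-values are reported, since either convention is encountered);
ties take average ranks everywhere. Correlations are Spearman's rank
coefficient with a t-approximation p-value. The cohort summary reports
group means, SDs, p-values and the integer-rounded percent difference
`100·(mean_DP − mean_HV)/mean_HV`. The significance threshold is 0.05
two-tailed, exposed as an argument. No multiple-testing correction is
applied, matching common practice for small exploratory cohorts — a known
limitation, not an endorsement.

# The synthetic-data generator

The generator emulates, with known truth: biexponential ²³Na FIDs with
circular complex Gaussian noise (magnitude therefore Rician);
monoexponential multi-TE water series; interleaved post-exercise
timelines; three-echo Dixon volumes; and two-group cohorts drawn from
truncated normal distributions at the published group means/SDs
(truncation keeps concentrations positive, fractions in [0, 1] and fat
fractions in [0, 100] — untruncated draws at e.g. FF 25.7 ± 15.6 would be
unphysical).

Healthy-control sodium dynamics rise linearly from a configurable start
value to the peak at 480 s (~8 min) — the simplest shape consistent with
the described time course, since the rise's functional form is not
established — then decay as `baseline + A·2^(−(t−t_peak)/T½)` with
T½ = 636 s; water T2 starts maximal and declines with T½ = 620 s to its
baseline, peaking at 36.4/29.3 of baseline. Patient series are near-flat
at an elevated level with a 2% downward trend across the observation span.
The sodium start value at t = 0 is exposed as `startRatio` (default 1,
i.e. from baseline) rather than fixed, as no reference value exists.

What the generator does **not** emulate: k-space sampling, radial
regridding, coil sensitivity or B1 inhomogeneity, frequency drift,
motion, partial volume, or lipid contamination of the water voxel.
Passing recovery tests therefore demonstrate correctness of the estimators
under the stated signal models, not robustness to all features of scanner
data.

# Study-condition simulations and problem sizes

The validation suite runs recovery at the conditions the cohort values
describe: 200 seeded FIDs at SNR 50 for relaxometry recovery (medians
within 5%/15%/5 points of truth); noiseless group-mean dynamics for the
half-lives (within 1%); and noisy dynamics whose per-point noise is
calibrated so that the recovery fit's asymptotic 95% CI half-width matches
the reported ±49 s (sodium, group mean of 6 subjects) and ±90 s (water T2,
10 subjects) — under that calibration the fraction of fits inside those
intervals is binomial with rate ≈ 0.95, and is tested against its exact
binomial lower bound rather than as a point value. Dixon recovery uses an
11-voxel fat-fraction sweep and small 2D/3D volumes; the solver scales
linearly in voxels and handles 64³ volumes in minutes on one core. These
sizes are the package's validation choices; all are generated at run time.

# Known limitations

- Magnitude-domain biexponential fitting retains a small (~2%) downward
  bias on the slow T2\* at SNR 50; a Rician maximum-likelihood fit would
  remove it.
- The Dixon solver's field-offset search range (±150 Hz default) must
  bracket the true offsets; strong off-resonance requires widening it.
- Recovery-fit CIs are asymptotic; for short series they understate
  uncertainty.
- The exact Mann–Whitney/Wilcoxon paths require tie-free data; with ties
  the implementation switches to the corrected normal approximation, as
  standard software does.
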