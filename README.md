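# naqms — quantitative ²³Na/¹H MR analysis of skeletal muscle

`naqms` is an R package for quantitative analysis of interleaved sodium-23
and proton MR measurements of skeletal muscle, the kind of protocol used to
study ion homeostasis in neuromuscular disease (e.g. dysferlinopathy) and
in healthy muscle after exercise. It is aimed at MR physicists and imaging
scientists who need a tested, scriptable alternative to one-off analysis
scripts for:

- **Biexponential ²³Na T2\* relaxometry** on time-domain free induction
  decays (FIDs). Tissue sodium decays with two components; the magnitude
  model fitted by bounded nonlinear least squares is

  ```
  M(t) = sqrt( (M_fast e^(−t/T2*_fast) + M_slow e^(−t/T2*_slow))² + ν² )
  ```

  where `t` is time since the excitation-pulse centre and `ν` is the
  magnitude noise floor (entering in quadrature because magnitude data with
  circular complex Gaussian noise are Rician). The fast fraction
  `M_fast/(M_fast+M_slow)` indexes motion-restricted, macromolecule-dense
  environments.

- **Phantom-calibrated tissue sodium concentration** with relaxation
  correction,

  ```
  Na_TA = Na_P · (SI_TA / SI_P) · [Ms_P e^(−TE/T2s*_P) + Mf_P e^(−TE/T2f*_P)]
                                / [Ms_TA e^(−TE/T2s*_TA) + Mf_TA e^(−TE/T2f*_TA)]
  ```

  referenced to a 20 mM NaCl standard, with per-subject tissue relaxometry
  taken from the baseline biexponential fit.

- **Muscle water T2** from multi-echo spectroscopy
  (`S(TE) = S0 e^(−TE/T2)`), and image SNR as
  `(mean signal − mean background) / sd(background)`.

- **Post-exercise recovery kinetics**: the three-parameter exponential
  `v(t) = baseline + (S0 − baseline) · 2^(−t/T½)` fitted to sodium
  amplitude (from its ~8 min post-exercise peak) and to the water-T2
  decline (from the first timepoint), with 95% confidence intervals on the
  half-life T½.

- **Three-echo Dixon fat–water separation** with a six-peak fat spectral
  model, a single shared T2\* and Rician noise-bias correction, producing
  fat-fraction maps `FF% = 100·F/(W+F)` and masked muscle summaries.

- **Nonparametric group statistics**: exact Mann–Whitney U, Wilcoxon
  signed-rank deviation-from-baseline per timepoint, Spearman correlation,
  and a cohort summary table with percent group differences.

A first-class **synthetic-data generator** renders every input the pipeline
consumes (FIDs, echo series, dynamic timelines, Dixon volumes, two-group
cohorts) from known ground truth, so each stage is validated by parameter
recovery.

## Worked example

```r
library(naqms)

# healthy-volunteer ground truth at the cohort means
truth <- subjectTruth("HV")

# render a noiseless sodium FID (1024 samples, dwell 0.125 ms) and fit it
fit <- fitBiexpT2Star(makeFid(truth, noiseSd = 0))
fit
#> BiexpT2StarFit: T2*fast 2.2 ms, T2*slow 13.4 ms, fast fraction 0.460
#>   m_fast 0.46, m_slow 0.54, offset 1.848e-13, RSS 1.796e-23

# post-exercise sodium amplitude over one hour, fitted from its peak
tl <- AcquisitionTimeline(postExerciseSpan = 3600)
dyn <- makeDynamicSeries(truth, tl, "na_amplitude", noiseSd = 0)
fitRecovery(dyn, fromPeak = TRUE)
#> RecoveryFit: T1/2 636 s (95% CI +/- 1.15e-12), baseline 1, s0 1.235

# phantom-calibrated concentration at the radial echo time
ph  <- PhantomStandard()                      # 20 mM reference standard
tis <- TissueRelaxometry(0.54, 0.46, 13.4, 2.2)
sodiumConcentration(1.043, 0.9963, ph, tis, te = 0.28)
#> SodiumConcentrationResult: 22.3 mM (correction 1.0654 at TE 0.28 ms)
```

The recovered T2\* components (2.2 / 13.4 ms), fast fraction (46%) and
half-life (636 s) equal the generating truth; the concentration example
converts a tissue/phantom signal ratio of 1.047 into 22.3 mM after a 6.5%
relaxation correction (tissue sodium decays faster than the aqueous
standard during the 0.28 ms echo time, so the raw ratio underestimates
concentration).

A thin command-line wrapper for the common single-file operations ships in
`inst/scripts/naqms.R` (`fit-fid`, `quantify`, `dynamics`).

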