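---
title: "Monitoring recovery after knee arthroplasty with a classifier's probability output: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Monitoring recovery after knee arthroplasty with a classifier's probability output: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

After a total knee arthroplasty (TKA), clinicians track recovery mostly
through patient-reported outcome measures such as the KOOS-ADL (0 = worst,
100 = best daily-life functioning). Biomechanical recovery — whether a
person's gait pattern actually converges back to that of asymptomatic
peers — is a different construct, and lab-based 3D motion capture is too
heavy for routine follow-up. Wearable inertial measurement units (IMUs)
provide joint-angle time series during level walking and stair negotiation
in ordinary clinical settings.

`gaitrecover` implements a complete pipeline built on one idea: train a
binary classifier to separate TKA-class gait from control gait, and then use
its *probability* output, not its hard label, as a scalar recovery metric.
A person scoring `p_tka = 0.95` at six weeks and `p_tka = 0.55` at twelve
months has improved materially even though a 0.5-threshold classifier calls
them "TKA" at both visits.

## Pipeline overview

1. **Segmentation.** Walking steps are detected as dominant peaks of
   anterior-posterior pelvis acceleration; a medio-lateral acceleration
   window signs each step left or right; stair strides are tibia-acceleration
   local maxima that follow a local minimum. One *middle* stride per leg is
   extracted, its nine joint-angle channels (spine, hip, knee, ankle) are
   low-pass filtered at 6 Hz and resampled to 101 points spanning 0–100% of
   the gait cycle.
2. **Feature construction.** Each channel is a *view*; new views are fused
   from ordered pairs by ratio, difference, sum and product, kept only while
   their absolute Pearson correlation with every already-retained view stays
   below 0.99. A fixed 15-statistic bank (moments, extremes, RMS, Fourier
   magnitudes 1–5 of the mean-subtracted series, linear-trend slope /
   intercept / r) is extracted per view and averaged per subject per
   activity — both legs for controls, the affected side only for patients.
3. **Classifier.** Features are standard-scaled with training-set statistics
   (`(x - mean)/sd`, population sd), then an L1-regularised logistic
   regression is tuned over ten `C` values log-spaced on `[0.01, 1]` by
   stratified 5-fold cross-validation on AUC and refit on the full training
   set. Evaluation is leave-one-*subject*-out, refitting the fused-view
   list, scaler and tuning inside every fold. Two training variants exist
   per activity: pre-operative and 6-weeks-post-operative.
4. **Monitoring.** The trained model is deployed on later timepoints
   (3, 6, 12 months) to give per-subject probability trajectories, compared
   against KOOS-ADL via a group Spearman correlation of 6-week→12-month
   change scores and per-subject Spearman correlations over the four
   post-operative points, banded weak/fair/moderate/strong at |rho| =
   0.25/0.5/0.75.

## Parameters that matter

| parameter | default | unit | why |
|---|---|---|---|
| sampling rate | 60 | Hz | typical IMU-suit output rate |
| low-pass cutoff | 6 | Hz | conventional filtering for joint kinematics; gait harmonics live below ~5 Hz |
| filter | Butterworth order 4, forward–backward | — | de-facto standard; zero phase so event timing is preserved |
| stride normalisation | 101 points | % cycle | gait-analysis convention (0..100% inclusive) |
| min step interval | 0.4 | s | cadence above 2.5 steps/s is implausible for this population |
| peak threshold | mean + 0.5·sd | — | adaptive; robust to amplitude differences across subjects |
| fusion correlation threshold | 0.99 | — | redundancy pruning; 1.0 disables the filter |
| fused-view cap | 32 | views | keeps the feature space at desk scale (615 columns) |
| C grid | 10 values, `0.01–1` log-spaced | — | ratio `10^(2/9)`; ties go to the smaller C (stronger sparsity) |
| optimiser cap | 100 | outer iterations | part of the method contract; hitting it warns, never aborts |
| decision boundary | 0.5 | probability | exact ties classify as control |

## The synthetic cohort

No public dataset of longitudinal post-TKA IMU gait exists (clinical motion
data is personal data under GDPR), so the package ships a generator that
states the world the analysis assumes and makes every stage testable:

- **Cohort**: 20 controls (one visit) and 19 patients with unilateral knee
  osteoarthritis evaluated pre-operatively and at 6 weeks, 3, 6, 12 months;
  one patient drops out after the pre-operative visit and one before 12
  months; a third of patients cannot negotiate stairs at 6 weeks.
- **Signals**: per-leg joint-angle channels are smooth periodic templates
  (≤ 4 harmonics per channel with published-plausible ranges, activity
  modifiers for stairs) plus stable per-subject individuality (amplitude,
  phase and offset jitter) plus Gaussian noise low-passed below 6 Hz — so
  the kinematic filter cannot trivially remove it. Acceleration channels
  carry one planted peak per step (anterior-posterior), signed deflections
  per side (medio-lateral), and a minimum-then-maximum pattern per stride
  (tibia), with ground-truth indices stored for oracle tests.
- **Severity**: a latent per-timepoint score in [0, 1] scales range
  reduction, offset shift, peak-timing shift and cadence slowdown, fully on
  the affected leg and at 40% on the contralateral leg. Recovering profiles
  decay severity monotonically from 6 weeks to 12 months; constant-severity
  (non-recovering) profiles are supported.
- **PROMs**: `koos = coupling · 100·(1 − severity) + (1 − coupling) ·
  (65 + 15·z)`, clipped to [0, 100]. `coupling = 1` is a deterministic
  gait–PROM link; `coupling = 0` makes the PROM independent of gait. The
  blend (rather than additive noise only) is what makes the zero-coupling
  null hold: with pure additive noise the deterministic term would dominate
  and individual correlations would not be centred at zero.

Two generator choices deserve emphasis because earlier drafts got them wrong
in instructive ways. First, angle channels are generated *per leg*: with a
single shared 9-channel series, a stride extracted at a right-foot event
slices the signal half a cycle out of phase, so controls (which average both
legs) systematically mix a canonical and a rotated curve while patients
contribute only the canonical one — a feature-mean shift that made even
zero-effect cohorts perfectly classifiable. Real IMU suits report both legs'
angles; modelling that restores the no-leakage null. Second, the cadence
slowdown is scaled by the effect size: an unconditional slowdown interacts
with the fixed 6 Hz filter (higher template harmonics sit at slightly
different frequencies) and leaks group identity even at zero effect.

**What a green test establishes — and what it does not.** The synthetic
world has exactly the structure the method assumes: clean periodic strides,
a monotone severity trend, a monotone severity→PROM link. Green acceptance
tests demonstrate that the pipeline recovers planted structure without
leaking information, not that real post-TKA gait is this well-behaved. Real
data adds turning strides, sensor-to-segment calibration error, soft-tissue
artefact, missing visits beyond the two modelled dropouts, and PROM ceiling
effects, none of which are emulated.

## Numerical choices

- **Scaling** uses the population standard deviation (divide by *n*),
  matching common standard-scaler behaviour; zero-variance columns are
  masked and dropped rather than producing division by zero.
- **The L1 fit** is a proximal-Newton coordinate descent (the
  LIBLINEAR/newGLMNET structure) written for this package, with the working
  -weight floor at 1e-6 and an active-set inner loop. The iteration cap
  (default 100 outer iterations) is enforced faithfully; non-convergence is
  a warning. Tests pin the solver against an independent reference
  implementation at matched penalty (`lambda = 1/(n·C)`) to ~1e-4.
- **AUC** is the rank-based Mann–Whitney statistic with average ranks for
  ties; folds whose validation split is single-class contribute `NA` and are
  dropped from the mean.
- **Ratio views** skip candidates whose training denominator passes within
  `1e-6 · RMS` of zero; at evaluation time a retained ratio clamps the
  denominator to ±eps instead, so a feature matrix never contains
  non-finite values and no imputation is ever needed.
- **Middle stride** for an even stride count takes the later of the two
  central strides (0-based index `floor(n/2)`); ties at the decision
  boundary (`p = 0.5` exactly) classify as control; AUC ties across the C
  grid resolve to the smallest C.
- **Spearman with four points** has support `{0, ±0.2, ±0.4, ±0.6, ±0.8,
  ±1}`; the individual-correlation report deliberately omits p-values at
  n = 4 and instead reports the band and the point count. Band boundaries
  are half-open on the left: weak [0, 0.25), fair [0.25, 0.5), moderate
  [0.5, 0.75), strong [0.75, 1].

## Open design decisions, resolved

- *Leave-one-out unit*: subjects, not rows — features are per
  subject-activity and the evaluation claim is about unseen people.
- *Which rows form the TKA class*: the pre-operative variant trains on
  controls + patients pre-op; the 6-week variant on controls + patients at
  6 weeks. One model per activity per variant (six models).
- *Individual correlations* use the four post-operative points only; the
  6-week score of the 6-week-trained model is in-sample and flagged as such
  in the trajectories.
- *Fusion scope*: pruning correlations are computed on the concatenation of
  all training strides, making the retained view list a property of the
  training data; the list is persisted in the model artifact and reused
  verbatim at evaluation time.
- *Group-correlation strength*: under a perfect (coupling = 1) link the
  group change-score correlation is *not* near −1: the probability is a
  sigmoid of the feature score, and differences of a nonlinear map are not
  rank-aligned with differences of the latent severity. Simulation across
  seeds gives rho ≈ −0.45 to −0.75 — an instructive echo of the fair group
  correlation clinical studies report even when individual trajectories
  track well.

## Limitations

- The generator is a statistical stand-in, not a musculoskeletal
  simulation; which biomechanical features drive class separation in real
  cohorts is an open question the synthetic world cannot answer.
- Feature construction implements the fusion-plus-pruning mechanism with a
  fixed 15-statistic bank; an industrial feature-construction system with a
  full operator inventory would produce orders of magnitude more features.
  Conclusions about L1 behaviour at that scale do not follow from this
  package's defaults.
- Accuracy is plain correct/total at 0.5; no calibration, class weighting
  or alternative classifiers are provided.
- Probability changes have no clinically validated minimal important
  difference; the monitoring output is a screening signal, not a treatment
  criterion.
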