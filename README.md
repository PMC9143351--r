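# gaitrecover

Monitoring functional recovery after total knee arthroplasty (TKA) from
wearable-sensor gait kinematics, using a classifier's probability output as
the recovery metric.

## The problem

People with end-stage knee osteoarthritis receive a TKA and are followed up
with patient-reported outcomes such as the KOOS-ADL score (0–100, higher =
better daily-life functioning). Whether their *gait* actually renormalises
is a separate question that usually requires a motion-capture lab. Inertial
measurement units (IMUs) capture nine joint-angle channels (spine, hip,
knee, ankle) during level walking and stair negotiation in any clinic.

`gaitrecover` implements the full analysis path from raw 60 Hz IMU signals
to a longitudinal recovery metric:

1. **Segmentation** — walking steps from anterior-posterior pelvis
   acceleration peaks, left/right from the medio-lateral signal, stair
   strides from tibia-acceleration maxima that follow a minimum; one middle
   stride per leg, 6 Hz zero-phase Butterworth filtering, time-normalised to
   101 points (0–100% of the gait cycle).
2. **Feature construction** — time-series fusion (ratio, difference, sum,
   product of channel pairs) with redundancy pruning at |Pearson r| ≥ 0.99,
   a fixed 15-statistic bank per view (moments, extremes, RMS, Fourier
   magnitudes 1–5, linear-trend statistics), averaged per subject per
   activity (controls: both legs; patients: affected side only).
3. **Classification** — standard scaling `(x − mean)/sd` with training
   statistics, L1-regularised logistic regression

   `p_tka = 1 / (1 + exp(−(wᵀx + b)))`,  `min ‖w‖₁ + C Σᵢ log(1 + e^{−yᵢ(wᵀxᵢ+b)})`

   with C tuned over ten log-spaced values on [0.01, 1] by stratified 5-fold
   CV on AUC, evaluated leave-one-subject-out with everything (fused views,
   scaler, tuning) refit inside each fold.
4. **Monitoring** — deploy the 6-week model on 3/6/12-month data, report
   per-subject `p_tka` trajectories (heatmap tables), 6-week→12-month change
   scores, a group Spearman correlation against ΔKOOS-ADL, and individual
   Spearman correlations banded weak/fair/moderate/strong at |ρ| =
   0.25/0.5/0.75.

Because longitudinal post-TKA IMU data is GDPR-restricted, the package
includes a first-class synthetic-cohort generator (20 controls + 19
patients, dropouts, stairs incapacity at 6 weeks, severity-coupled PROMs,
planted gait events) so that every stage is testable offline. See the
methods vignette (`vignettes/gaitrecover-methods.Rmd`) for the generative
model and design decisions.

## Worked example

```r
library(gaitrecover)
manifest <- run_pipeline(pipeline_config(seed = 42L), "out")
```

or equivalently from the shell:

```sh
Rscript inst/scripts/gaitrecover.R run-all --seed 42 --out-dir out
```

which prints (about 50 s on one CPU):

```
walk_pre_trained         C=0.07743 views=41 accuracy=0.949
walk_w6_trained          C=0.07743 views=41 accuracy=0.974
stairs_up_pre_trained    C=0.07743 views=41 accuracy=-
stairs_up_w6_trained     C=0.2154 views=41 accuracy=-
stairs_down_pre_trained  C=0.07743 views=41 accuracy=-
stairs_down_w6_trained   C=0.1292 views=41 accuracy=-
```

Six models are trained (three activities × two training variants); walking
models are additionally evaluated leave-one-subject-out — here 94.9%
(pre-operative variant) and 97.4% (6-week variant) of held-out subjects are
classified correctly at the 0.5 boundary. `out/` then contains, per model,
the feature matrix with its reconstruction sidecar, the persisted model
JSON, the probability heatmap table (subjects × timepoints, empty cells =
missing visits), and for the 6-week walking model the correlation report:

```r
rep <- jsonlite::read_json("out/correlation_report.json")
rep$group
#> $rho  -0.6151961      $p  0.008575573      $n  17
```

a moderate negative group correlation between the change in `p_tka` and the
change in KOOS-ADL from 6 weeks to 12 months (probability falls as reported
functioning rises), with 94% of patients in the strong individual-correlation
band for this deterministic-coupling seed, and

```r
manifest$results$walk_w6_trained$asymptomatic_m12
#> 0.882
```

the share of patients whose 12-month gait is classified asymptomatic
(`p_tka < 0.5`). A typical heatmap row shows the declining probability over
recovery:

```
subject_id      w6     m3     m6    m12
pat01        0.513  0.442  0.444  0.423
```

All numbers above are what the pipeline prints for this synthetic cohort;
they characterise the generator's stated world, not any clinical population.

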