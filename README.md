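# kinescore

Automated, motion-capture-based scoring of upper-extremity movement
impairment after stroke.

Clinical assessment of post-stroke arm impairment (Fugl-Meyer and related
item scales) relies on a trained specialist subjectively rating a handful of
movements on a coarse ordinal scale. `kinescore` implements an automated
alternative: from 3D trajectories of a few tracked skeletal landmarks —
captured by a laboratory-grade system at high rate or by a low-cost
markerless sensor at 30 Hz — it computes a continuous, quantitative
impairment score per movement, together with the reliability machinery
needed to interpret that score. It is intended for movement scientists and
rehabilitation researchers working on objective outcome measures.

## The score

For each movement type, joint-angle kinematics are reduced to four
physiological angles (shoulder flexion/extension, shoulder
abduction/adduction, elbow flexion/extension, wrist flexion/extension).
Repetitions performed by the **non-paretic** arm are averaged, and the 4×4
covariance of the demeaned mean trace is eigendecomposed; the smallest
number *k* of principal components explaining ≥ 95 % of variance (almost
always *k* = 2) defines a reference basis of the arm's normal inter-joint
coordination. Each single trial **x** (paretic or non-paretic) is then
demeaned with its own channel means, projected on the retained loadings
**V**, and reconstructed:

    x̂ = V Vᵀ (x − x̄),     score = R² = 1 − ‖x − x̄ − x̂‖² / ‖x − x̄‖²

The pooled coefficient of determination is the quantitative impairment
score: 1 when the trial lies in the span of the normal coordination basis,
lower as coordination departs from it. Per-trial demeaning makes the score
immune to the constant angular biases that dominate low-cost capture error,
and the dimensionality reduction suppresses sensitivity to capture noise.

Around the score, the package provides:

- **Kinematics** — zero-phase 2nd-order Butterworth low-pass (6 Hz) of
  marker trajectories, trunk-frame joint-angle computation, resampling to a
  common 100-point trial base.
- **Segmentation** — repetition detection by the peaks of a sliding
  correlation profile between the joint angles and a mean-trace template.
- **Reliability statistics** — bootstrap estimate of the minimal number of
  movement repetitions; bootstrap estimate of how many human raters match
  the automated score; per-rater ICC(2,1) against the panel mean; regression
  of qualitative on quantitative scores with analytic (Fisher-z) power;
  leave-one-subject-out decoding of clinical scores.
- **Inter-system accuracy** — per-joint RMS and maximal-excursion errors of
  a low-cost system against the standard system.
- **Synthetic data** — latent-drive movement models, impairment operators
  (reduced excursion, abnormal coupling, 3–6 Hz tremor, slowing), capture
  models for both systems, and noisy ordinal rater panels, so the whole
  pipeline runs and is testable without hardware or human data.

## Worked example

Score a simulated impaired arm against its own unimpaired side, all the way
from noisy 30 Hz landmark capture:

```r
library(kinescore)

cap <- capture_model("lowcost")                       # 30 Hz, bias-dominated
np  <- simulate_session(4, n_reps = 8, severity = 0,   cap = cap, seed = 21)
par <- simulate_session(4, n_reps = 8, severity = 0.6, cap = cap,
                        limb_side = "right", seed = 22)

angles_np  <- compute_joint_angles(lowpass_filter(np$recording))
angles_par <- compute_joint_angles(lowpass_filter(par$recording))

tmpl <- build_template(list(angles_np),
                       list(cbind(np$onsets_capture,
                                  np$onsets_capture + np$rep_samples_capture - 1)))
trials_np  <- detect_repetitions(angles_np, tmpl, min_corr = 0.5)
trials_np
#> <segmented_trials> 8 trial(s), movement NA
#>   trial length 100 samples; onsets: 25, 95, 164, 232, 302, 372, 440, 510

basis <- derive_basis(align_and_average(trials_np))
basis
#> <pc_basis> k = 2 of 4 components (threshold 0.95)
#>   explained variance: 81.7%, 18.0%, 0.2%, 0.1%
```

Two components capture the unimpaired coordination (99.7 % of variance).
Scoring the paretic trials against this basis, next to the non-paretic
baseline:

```r
tmpl_par <- build_template(list(angles_par),
                           list(cbind(par$onsets_capture,
                                      par$onsets_capture + par$rep_samples_capture - 1)))
trials_par <- detect_repetitions(angles_par, tmpl_par, min_corr = 0.5)

round(score_trials(trials_par, basis)$value, 3)
#> [1] 0.974 0.972 0.980 0.974 0.977 0.981 0.977 0.979
round(mean(score_baseline(trials_np, basis)$value), 3)
#> [1] 0.984
```

Every paretic trial scores below the unimpaired baseline: the non-paretic
components represent the impaired arm's coordination less well. At the
study level, `simulate_study()` runs participants × movements × limbs ×
capture systems through this pipeline and `fit_score_regression()`,
`loso_decode()`, `min_repetitions()`, `raters_to_match()` and
`icc_per_rater()` relate the scores to a simulated clinical rater panel.

A command-line interface wrapping these functions is installed at
`inst/cli/kinescore.R` (subcommands `angles`, `segment`, `score`,
`compare`, `simulate`, `bootstrap-reps`, `raters-match`, `decode`).

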