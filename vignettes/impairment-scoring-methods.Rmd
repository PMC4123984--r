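---
title: "Methods: PCA cross-reconstruction scoring of upper-limb impairment"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: PCA cross-reconstruction scoring of upper-limb impairment}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(kinescore)
```

# The measurement model

`kinescore` treats a movement trial as a short multivariate time series of
four physiological joint angles — shoulder flexion/extension, shoulder
abduction/adduction, elbow flexion/extension, wrist flexion/extension — in
degrees, on a common 100-point time base. The package's central claim is
that the *inter-joint coordination* of the unimpaired arm occupies a
low-dimensional subspace of this 4-channel space, and that impairment is
measurable as the failure of that subspace to represent the paretic arm's
movement.

Concretely, for one movement type and one participant:

1. Repetitions of the non-paretic arm are averaged pointwise into a mean
   trace.
2. The four channels of the mean trace are demeaned and their 4×4
   covariance over time is eigendecomposed. The smallest number $k$ of
   components explaining at least the variance threshold (default 0.95) is
   retained; unimpaired multi-joint movements typically need $k = 2$.
3. A single trial $X$ (time × 4) is demeaned *with its own channel means*
   $\bar{x}$, projected on the retained loadings $V$ and back-projected.
   The score is the pooled coefficient of determination
   $R^2 = 1 - \lVert X_c - X_c V V^\top \rVert_F^2 / \lVert X_c
   \rVert_F^2$, with $X_c = X - \mathbf{1}\bar{x}^\top$.

Two properties follow directly from this construction and are enforced by
tests rather than assumed:

* **Bias immunity.** Adding any constant offset per channel leaves the
  score bit-identical, because each trial is centered on itself. This is
  what makes the score usable with low-cost capture, whose dominant error
  mode is a constant per-session angular bias from misidentified landmarks.
* **Sensitivity only through dimensionality reduction.** With the complete
  basis ($k=4$, obtained at `variance_threshold = 1`) every score is
  exactly 1. The score discriminates only because $k < 4$.

Because the trial is centered on its own means and the projection is
orthogonal, the *pooled* score always lies in $[0, 1]$. The per-channel
pooling variant (`pooling = "per_channel"`) divides each channel's residual
by that channel's own variance and can legitimately go negative — a channel
can receive more residual than it has variance; negative values are
reported unclipped.

## Assumptions

* The four angles capture the clinically relevant degrees of freedom; hand
  and finger kinematics, pronation/supination and trunk compensation are
  out of scope.
* Within one participant and movement, repetitions are exchangeable after
  length normalization; alignment is by time shift and uniform resampling
  only (no dynamic time warping).
* The non-paretic arm is an adequate within-participant reference —
  the decomposition is never transferred across participants.

# From landmarks to angles

**Landmark set.** Six labeled landmarks are required: both shoulders,
elbow, wrist, hand, and a pelvis/trunk reference.

**Filtering.** Each coordinate channel is low-pass filtered with a
second-order Butterworth at 6 Hz, applied forward and backward. Zero-phase
application matters because segmentation happens downstream — phase lag
would shift every detected onset. The effective magnitude response is the
squared single-pass response. Numerically, the filter is applied with
odd-reflection end padding (pad length $6 f_s / f_c$ samples) so that
start-up transients from the filter's zero initial conditions decay inside
the discarded pad; on constant input the output is constant to numerical
precision.

**Trunk frame.** Angles are defined in a per-sample trunk frame built
entirely from tracked landmarks: mediolateral axis along the
contralateral→ipsilateral shoulder line, vertical axis along
pelvis→mid-shoulder orthogonalized against it, anteroposterior axis their
cross product. Defining the vertical from the trunk rather than the
laboratory makes all four angles exactly invariant under rigid rotation
and translation of the whole landmark set — the property a markerless
sensor with an arbitrary viewing direction needs. In an upright canonical
pose the trunk vertical coincides with gravity. Shoulder
flexion/extension and abduction/adduction are the upper-arm vector
projected on the sagittal and frontal planes, measured from straight-down;
elbow and wrist are 3D included angles, so they live in $[0°, 180°]$ by
construction.

**Degenerate poses.** A sample where a required vector has (numerically)
zero length, or where the upper arm lies exactly in the shoulder line, has
an undefined angle; such samples are flagged, carry the last valid value,
and a trial with more than 10 % flagged samples is rejected as invalid.
This is deterministic and auditable; no interpolation across degeneracies
is attempted.

**Resampling.** All cross-trial arithmetic happens on a common base of 100
equally spaced points per trial (linear interpolation). Pooling trials of
unequal duration requires *some* normalization; a fixed-length time base is
the minimal assumption and 100 points oversamples a 6 Hz-limited signal of
1–4 s duration.

# Segmentation

Repetitions inside a continuous recording are found by a matched-template
procedure: a mean trace ("template") is built from marked start/end pairs
(or seeded automatically from the first high-energy segment when a
recording holds a single movement type), and the Pearson correlation
between the template and every same-length window of the series is
computed per channel and averaged. Local maxima of the averaged profile
above `min_corr` (default 0.7), separated by at least 50 % of the template
length, become onsets.

Numerical choices:

* Channels on which the template is constant (a joint that does not
  participate in the movement) have undefined correlation and are excluded
  from the channel average rather than contributing an arbitrary value.
* Windows of zero variance (rest) correlate as 0.
* Peak suppression is greedy by descending correlation, which makes
  noise-free recovery exact for any threshold in $(0, 0.9]$.
* The correlation profile is computed by FFT cross-correlation with
  running-sum window statistics, and clamped to $[-1, 1]$ against rounding.

`min_corr` trades recall against false positives: 0.7 is conservative for
clean data; the study pipeline uses 0.5 because slowing and coupling
deform the paretic repetitions relative to the template. Both are exposed
in the configuration.

# Reliability statistics

**Minimal repetitions.** The per-trial error is the absolute difference
between a single trial's maximal angular excursion and the excursion of
the across-trial average. For each $k$, $k$ errors are drawn with
replacement (default 1000 draws) and the bootstrap error at $k$ is the
mean squared deviation of the $k$-draw mean from the overall mean error —
which converges to $\widehat{\sigma}^2_{\text{pop}}/k$. The stopping rule
"falls below the 95 % confidence interval of the mean error" is ambiguous
as stated; the default interpretation is the squared CI half-width
$(t_{0.975,n-1}\,\mathrm{SE})^2$ (switchable to the literal CI lower
bound via `criterion = "lower-bound"`). Under the half-width criterion the
crossing point is essentially $(n-1)/t^2$, weakly dependent on the data —
about 2 repetitions for realistic trial counts — which matches the scale
of the published estimates and explains why all four joints give nearly
the same answer.

**Raters to match.** Identical bootstrap machinery on a rating panel: the
rater error at $m$ is the mean squared deviation of an $m$-rater mean from
the full-panel mean, per participant × movement; $k^\*$ is the first $m$
beating that key's model error (the automated score's squared error on the
qualitative scale, via the fitted score regression). Keys never beaten by
the panel's maximal rater count are flagged "not reached" and excluded
from the aggregate, with the count reported.

**ICC.** Inter-rater reliability is ICC(2,1) — two-way random effects,
absolute agreement, single measurement — between each rater's scores and
the across-rater mean over all items, computed from the two-way ANOVA mean
squares directly. The classical reference this family of studies cites
does not pin the form; ICC(2,1) is the standard choice when raters are a
random sample and absolute agreement matters.

**Power.** The power of the Pearson correlation is computed analytically
from the Fisher-z approximation instead of a printed statistical table;
tables of correlation power are discretizations of the same formula.

**Decoding.** Leave-one-subject-out: the qualitative~quantitative
regression is fitted on all other participants (movement-level points by
default; participant means as an option, since both granularities are
plausible readings) and predicts the held-out participant's mean
qualitative score; the fold error is reported as % of the maximal ordinal
score.

# What the synthetic generator emulates — and what it does not

The generator exists because no human recordings ship with the package;
its job is to produce data with the statistical structure the scoring
method assumes, under controlled ground truth.

* **Movements** are driven by at most two latent drives: an out-and-back
  minimum-jerk profile and its normalized time-derivative (a biphasic
  transient, exactly orthogonal in time to the symmetric first drive). A
  4×2 synergy matrix maps drives to joints, so noise-free joint-space
  covariance has rank ≤ 2 and a 2-component basis explains 100 % of an
  unimpaired movement. Nine of the ten presets genuinely need two
  components at the 95 % threshold; one single-joint movement needs one —
  mirroring the reported regime. The presets mirror which joints move in
  common clinical test items, with no claim of biomechanical fidelity.
* **Impairment** at severity $s \in [0,1]$ applies, in order: time
  dilation by $1+s$; inter-joint coupling leakage (fraction $0.4s$ of each
  joint's demeaned trace replaced by its neighbour's); channel-wise
  rescaling so each excursion is exactly $1-0.5s$ times the input's; and
  band-limited 3–6 Hz tremor of s.d. $2.5s$ degrees. $s=0$ is bit-exact
  identity. The magnitudes were fixed once as mild-to-moderate clinical
  signatures; they are configuration, not fitted quantities.
* **Capture** adds, per trial (per session for continuous recordings), a
  per-channel angular bias drawn once (s.d. 25° for the low-cost model,
  1° for the standard), white angular noise per sample (3° / 0.5°),
  forward kinematics to landmark positions, and positional noise
  (4 mm / 1 mm), at 30 Hz and 480 Hz respectively. The bias-dominated
  low-cost defaults put per-channel RMS angular errors against truth in
  the same 16–26° band as published low-cost-sensor comparisons.
* **Raters** score each item as `round(2·quality + N(0, 0.35))` clipped to
  {0, 1, 2} — an imperfect clinician on the 3-point impairment scale.

Not emulated: musculoskeletal dynamics, sensor-specific skeleton-fitting
artifacts beyond bias+noise, trunk compensation strategies, marker
occlusion patterns, and rater idiosyncrasies beyond additive noise.
Passing the end-to-end tests therefore shows the pipeline's statistical
machinery is correct and coherent under its assumptions — it does not
certify accuracy on human recordings.

Two honest consequences of these choices are worth stating. First, the
coupling operator perturbs the joint-space loading directions but leaves
trajectories inside the two-drive subspace of time courses, so the score
degrades *quadratically* in the coupling gain: the simulated
quantitative–qualitative association is positive and significant but
substantially weaker than what the published human data show. Second,
because the projection convention for shoulder angles is not uniquely
invertible beyond ±90°, the presets keep shoulder angles within ±80° and
capture simulation clamps biased angles to ±85° (elbow/wrist to
[5°, 175°]) before forward kinematics.

# Numerical and design decisions

* **Covariance, not correlation.** Channels are not variance-normalized
  before the eigendecomposition, so large-excursion joints dominate the
  basis. This follows the stated method; the consequence is documented
  rather than hidden.
* **Threshold tie-break.** $k$ is the smallest integer whose cumulative
  variance fraction reaches the threshold (within $10^{-12}$); at exact
  equality that $k$ is used. `variance_threshold = 1` always yields the
  complete basis $k=4$, even for rank-deficient input.
* **Loading signs** are fixed by making each loading's largest-magnitude
  element positive, for reproducibility across eigensolvers.
* **Baseline mode.** Non-paretic trials are by default scored against the
  basis built from the average including themselves (`include_all`); a
  `leave_one_out` mode rebuilds the basis per trial. Include-all is the
  default because the published procedure gives no hint of exclusion and
  the mean of ≥ 5 trials is barely influenced by any single one.
* **"% of max" denominator** in the inter-system error report is the
  per-channel maximal range of motion observed in the standard system's
  recordings of that movement (the standard system being the gold
  standard). For joints that barely move in a given movement this
  denominator is small and the percentage correspondingly large; the
  degree-valued errors are the primary quantities.
* **Units** are meters, degrees, seconds throughout.

# Problem sizes

The test suite and the acceptance script run the benchmark at 8
participants × 10 movements × 8 repetitions per limb and system, ground
truth at 120 Hz, capture at 30 Hz (low-cost) and 480 Hz (standard),
bootstraps at 1000 draws (10⁵ where a curve is checked against its
analytic limit), and 100-seed Monte-Carlo loops for the recovery
properties. These sizes give stable statistics for every property tested
while keeping a full run in the minutes range on a single CPU.

# Known limitations

* The pooled score cannot go negative, so it compresses near 1 for mild
  impairment; resolution at the healthy end is limited by the inherent
  trial-to-trial variability of the baseline.
* The trunk frame needs a visible pelvis landmark; seated configurations
  with an occluded pelvis are not supported.
* C3D files are not read in this build; the tab-separated dialect is the
  canonical interchange format.
* The severity scale of the generator is ordinal by construction
  (operators are monotone in $s$), but no claim is made that equal steps
  in $s$ are clinically equal steps in impairment.
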