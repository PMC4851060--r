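---
title: "Recognizing bed and chair exits from batteryless RFID sensor streams"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Recognizing bed and chair exits from batteryless RFID sensor streams}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

A passive (batteryless) RFID tag with an onboard 3-axis accelerometer,
worn over clothing at the sternum, reports reads only when a ceiling- or
stand-mounted reader antenna energizes it. The resulting stream is
irregular and bursty: read rates vary with posture and antenna geometry,
and the wearer's own body occludes the tag, so reads can vanish for
seconds — often exactly during the posture transitions one wants to
detect. The clinical task is to alert a caregiver, in real time, when an
older patient leaves the bed or the chair unsupervised, while keeping the
false-alarm rate low enough to avoid alarm fatigue.

`rfidexit` implements the three-stage pipeline for this task — feature
extraction, probabilistic activity prediction, exit recognition — plus the
alarm-level evaluation protocol and a synthetic-trial simulator that stands
in for the (unavailable) human-trial data.

## Model

### Activity classes and features

Activities are `Sitting-on-bed` (1), `Sitting-on-chair` (2), `Lying` (3),
`Ambulating` (4). Each read is mapped to a feature vector with three
families (all causal):

* **Instantaneous**: the three accelerations (g); trunk tilt
  `sin θ = sin(atan2(a_f, a_v))`; yaw `atan2(a_l, a_f)`; roll
  `atan2(a_l, a_v)`; a one-hot antenna indicator; RSSI (dBm); the gap to
  the previous read (s); a gender covariate. The two-argument arctangent
  resolves the degenerate 0/0 ratios the plain quotient would leave
  undefined, mapping (0, 0) to 0.
* **Contextual**, over the window `(t − 4 s, t]` anchored at the current
  read (the window is half-open on the old side so it always contains the
  current read and stays causal): per-antenna read fractions; a bed/chair
  cross-transition score `(1/n) Σ_k 1{areas of adjacent reads differ}`;
  one-hot ids of the antennas with max and min RSSI; the double
  time-integral of `a_v` over the window (twice-repeated trapezoidal
  integration on the irregular timestamps, after subtracting the window
  mean — the mean removes gravity, which would otherwise dominate the
  integral; whether to remove it is a genuinely open choice and the
  subtraction is the conservative one); Pearson correlations between axis
  pairs (zero-variance inputs give 0). The four-antenna room additionally
  enables mean/SD of each axis, per-antenna RSSI mean/SD, the SD of the
  variable-frequency phase rate and the summed modulus of the
  constant-frequency phase rate. Phase rates are per-read phase
  differences (wrapped to `(−π, π]`) divided by time differences, split by
  whether the two reads share a frequency channel; the precise upstream
  definition of these quantities is not fully specified in the literature
  this design follows, so they sit behind one small function that can be
  swapped.
* **Inter-segment**: differences of median/max/min of each axis and of
  per-antenna RSSI between the current and the previous read's windows.
  Antennas absent from a window contribute read fraction 0 and RSSI
  statistics at a floor of −90 dBm (below any plausible read; the
  difference features then spike, which is informative — an antenna
  falling silent is itself a signal).

Features are z-scored with training-fold statistics before the classifier;
the schema mixes g, dBm, radians and seconds, and without standardization
the regularizer would act on incommensurate scales.

### Dynamically weighted CRF

The classifier is a linear-chain conditional random field with unary
weights (K × P) and a homogeneous K × K transition matrix (transitions
carry no observation-dependent features). Deployment-time inference is the
**filtered marginal** `p(y_t | x_{1..t})`, computed by the forward
sum-product recursion in log space — O(K²) per read, no lookahead, exactly
what a real-time alerting system can use.

Training maximizes the class-weighted per-position objective

    L(λ, w) = Σ_t w_{y_t} · log p(y_t | x_{1..t}, λ) − ϑ‖λ‖²

where `p` is the same filtered marginal (training and deployment share one
factorization; the gradient is exact reverse-mode differentiation through
the recursion, implemented in C++). At `w ≡ 1` this is an ordinary
(per-position) CRF likelihood. The class weights counter imbalance:
Ambulating is a few percent of labels, yet every exit alert hinges on
recognizing it. For `τ` rounds, weights are re-proposed as
`w_c ∝ 1 + α(1 − F_c)` (α = 1, mean-normalized) from per-class validation
F-scores, a proposal is kept only if validation macro-F does not drop, and
the best-validation model over rounds is returned. `τ = 0` reduces exactly
to the unweighted CRF. The exact functional form of the weight update is
not published in the source literature; this rule matches its stated
objective (maximize F-score) while being reproducible and monotone.

The fixed-w subproblem is solved by L-BFGS from a zero start (gradient
tolerance 1e-5 on the per-position mean objective — dividing by the number
of positions makes the tolerance dataset-size-free without changing the
maximizer — max 500 iterations). Everything is deterministic given the
data order, so refits are bit-reproducible.

### Score function and exit state machine

Raw per-read argmax predictions chatter; a single confidently wrong
marginal would wake a caregiver. The score function instead sums each
class's marginals over the last 1 s of reads, `(t′ − 1, t′]`, and assigns
the argmax, with ties broken to the previously assigned activity (and then
the lowest class index). One second is long enough to outvote isolated
errors but shorter than the 1.75-s minimum duration of a sit-stand
transition, so genuine transitions are not averaged away.

A finite-state machine then emits alerts: **bed exit** when
{Lying, Sitting-on-bed} is followed by {Ambulating, Sitting-on-chair};
**chair exit** when Sitting-on-chair is followed by anything else. Direct
bed→chair and chair→bed transfers alert (ambulation between them may
simply be unobserved). After an alert, same-kind alerts within 1.75 s
(inclusive) are discarded — two genuine same-kind exits cannot occur
faster than one posture transition. Suppression is tracked per kind and
against the last *emitted* alert, and the first assignment of a stream
never alerts.

### Alarm-level evaluation

Ground-truth exits are the annotation boundaries satisfying the same
transition rules. An alert is a true positive if

1. it occurs while the person is performing the post-exit activity
   (alert time inside the annotation interval that starts at the boundary), or
2. the annotated exit occurs at most `T = 5 s` *after* the alert.

Matching is greedy earliest-first, one-to-one within each kind; unmatched
alerts are false positives, unmatched truths false negatives. Delays are
signed (`alert − boundary`; negative = early alert). Criterion (1) follows
the study's wording — published mean recognition delays of ~2–3 s are only
possible if alerts raised during the ongoing post-exit activity count as
hits — rather than a fixed ±1.75-s band around the boundary.

Cross-validation partitions *trials* (not observations) into 10 seeded
subsets; rotation `r` tests on subsets `{r, r+1}`, selects `(τ, ϑ)` by
validation exit F-score on `{r+2, r+3}` and trains on the remaining six,
so each subset is a test subset exactly twice. Subsets may mix one
participant's trials — results are deliberately not
participant-independent, mirroring the reference protocol. Default grids
`τ ∈ {0, 1, 2, 4, 8}`, `ϑ ∈ {1e-4, 3e-4, 1e-3, 1e-2, 1e-1}` bracket the
operating points reported for the two rooms; the test suite uses reduced
grids purely for runtime.

## The simulator: what it emulates, and what it does not

No generative model of the sensor is published, so the simulator is built
to reproduce the documented failure modes rather than the physics in
detail:

* **Irregular, bursty reads** — per-antenna Poisson processes whose rates
  are thinned by posture- and antenna-dependent dropout (the body occludes
  the tag: bed antennas lose the wearer at the chair, everything degrades
  while ambulating). Multi-second gaps occur, as in the real traces.
* **RSSI** — the monostatic backscatter link
  `10·log10(K_b P_t G_t λ⁴ |H|⁴ / (4π d_o)⁴)` with a piecewise-linear
  sensor trajectory through room geometry (bed, chair, door; ambulation
  interpolates between them) and log-normal multipath `|H|` with unit
  median. Defaults (`P_t` = 1 W, `G_t` = 4, `K_b` = 0.01, λ = 0.325 m)
  put reads in a realistic −45…−75 dBm range with a −40 dB/decade
  distance law.
* **Acceleration** — posture mean orientations (upright ≈ (1, 0, 0) g on
  (a_v, a_l, a_f), supine ≈ (0, 0, 1) g, sitting slightly reclined) plus
  i.i.d. Gaussian sensor noise and a sinusoidal gait component (0.15 g,
  1.8 Hz) while ambulating. Sitting and standing are deliberately
  near-identical in orientation — disambiguating them is the recognizer's
  hard case, and only RF-side features can do it.
* **Phase / channel** — phase from round-trip distance on a per-read
  random channel, plus noise; enough to exercise the phase-rate features,
  not a model of reader phase reporting.

`make_benchmark()` wraps this into labeled multi-trial datasets whose
pooled observation-label fractions track a requested imbalance profile
(default: Lying 0.55, Sitting-on-bed 0.30, Sitting-on-chair 0.11,
Ambulating 0.04 — the published imbalance regime). Step durations are
sized as `profile / effective read rate` so observation shares, not time
shares, match the profile. Script templates include chair exits with and
without ambulation and direct bed↔chair transfers, so every state-machine
branch occurs in every dataset. Two regimes are provided: `snr = "high"`
(2.5 Hz per antenna, light dropout, low noise) and `snr = "low"` (1.2 Hz,
heavy occlusion dropout, strong noise — the regime where dynamic class
weighting matters). Trials default to 90 s — scaled down from the
90–120-minute clinical sessions so that a 30-trial, 10-fold
cross-validation runs on one desk CPU in minutes; per-trial event counts
(one or two exits of each kind) are preserved.

What the simulator does **not** emulate — and hence what a green test does
not establish: real multipath structure (fading is i.i.d. log-normal, not
spatially correlated), reader anti-collision behavior, temporally
correlated body sway (accelerometer noise is white), annotation latency of
a human observer, and inter-participant variability beyond the gender
covariate and trial seeds. Performance numbers on this benchmark
characterize the pipeline, not the clinical system.

## Numerical choices and degenerate inputs

* Log-space recursions throughout; marginals remain finite for unary
  scores up to ±800 where direct-space exponentiation overflows.
* Intervals are half-open `[start, end)`; adjacent activities partition
  time, and `label_at` on a boundary belongs to the later interval.
* Ties in the score-function argmax: previous activity, then lowest index
  (hysteresis against chatter at decision boundaries).
* Suppression compares `t − last_emitted ≤ 1.75 s` (closed boundary).
* SD of fewer than two values is 0; Pearson correlation with a
  zero-variance argument is 0; `atan2(0, 0) = 0`; a single delay has
  SD 0; metrics with zero denominators are `NA` and excluded from fold
  averages (with the exclusion visible in the fold table).
* Features of the first observation: `dt = 0`, inter-segment differences 0
  (previous window defined as the current one).
* The weighted objective divides by the number of positions inside the
  optimizer only; reported objective values and the exported
  `weighted_loglik_grad()` keep the sum scale of the definition.

## Known limitations

* On nearly separable (high-SNR) synthetic data the per-position filtered
  likelihood drives unary weights large, so marginals saturate; a burst of
  2–5 correlated wrong reads can then outvote the 1-s score window and
  produce an occasional false alert at cold start or during posture
  transitions. The reference study's own precision (57–79%) shows the
  same failure mode on real data. L2 regularization at the published ϑ
  scale is too weak to prevent saturation.
* Dynamic class weighting improves what it directly targets — the
  minority-class (Ambulating) label F-score — but can *reduce* alarm-level
  chair-exit F on noisy data: upweighting Ambulating yields more spurious
  Ambulating assignments while the wearer sits on the chair, and every
  Sitting-on-chair→anything flip is a chair alert. The reference study
  shows the same ambivalence between its two rooms. Treat `τ` as a
  validation-selected hyperparameter, not a guaranteed win.
* The per-position reading of the weighted likelihood makes the transition
  matrix only weakly identified (an additive column shift is absorbable
  by class intercepts); parameter-recovery experiments therefore compare
  column-centered transition weights.
* `crossval` featurizes every trial once up front; memory is O(total
  reads × features), fine for benchmarks but not for day-long streams.
* The CLI covers the documented subcommands but is a thin wrapper; it is
  exercised by a smoke test only.
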