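# rfidexit

Real-time recognition of **bed and chair exits** from streams of reads of a
batteryless, body-worn RFID sensor (a passive tag with an onboard 3-axis
accelerometer, worn at the sternum). Unsupervised bed and chair exits are
the moments hospitalized older people fall most often; a wearable,
batteryless alternative to pressure mats must work with what backscatter
gives it — irregular, bursty, occlusion-riddled reads that carry
acceleration, received signal strength (RSSI), RF phase and
frequency-channel side information.

The package implements the full pipeline:

1. **Feature extraction** (`featurize_trial()`): per-read instantaneous
   features (accelerations, trunk tilt `sin θ = sin(atan2(a_f, a_v))`, yaw,
   roll, antenna id, RSSI, inter-read gap), contextual features over a 4-s
   sliding window (per-antenna read fractions, bed/chair area
   cross-transition score, max/min-RSSI antenna ids, vertical-displacement
   double integral, axis correlations, and an extended statistics block for
   the four-antenna room), and inter-segment difference features.
2. **Activity prediction** (`crf_fit()`, `online_marginals()`): a
   linear-chain conditional random field over the four activities
   {Sitting-on-bed, Sitting-on-chair, Lying, Ambulating}, trained by a
   **dynamically weighted** log-likelihood
   `L(λ, w) = Σ_t w_{y_t} · log p(y_t | x_{1..t}, λ) − ϑ‖λ‖²`
   whose class weights `w` are re-estimated from validation per-class
   F-scores for `τ` rounds to counter severe class imbalance (Ambulating is
   a few percent of the labels). Deployment-time inference is the exact
   online (filtered) marginal `p(y_t | x_{1..t})` via the forward
   sum-product recursion in log space, O(K²) per read.
3. **Exit recognition** (`recognize_stream()`): a score function sums each
   activity's marginals over the last 1 s of reads and assigns the argmax;
   a finite-state machine raises a *bed exit* when {Lying, Sitting-on-bed}
   is followed by {Ambulating, Sitting-on-chair} and a *chair exit* when
   Sitting-on-chair is followed by anything else, with a 1.75-s per-kind
   refractory period (the minimum duration of a posture transition).
4. **Evaluation** (`match_alerts()`, `crossval()`): event-level alarm
   scoring — an alert is a true positive if it occurs during the post-exit
   activity or at most `T = 5 s` before the annotated exit; greedy
   one-to-one matching per kind; recall / precision / F-score and signed
   recognition-delay statistics under a rotating 6/2/2 10-fold
   cross-validation with hyperparameter selection on the validation folds.
5. **Simulation** (`simulate_trial()`, `make_benchmark()`): a seeded
   generator of synthetic trials with exact ground truth — per-antenna
   Poisson reads thinned by posture/antenna-dependent occlusion dropout,
   RSSI from the monostatic backscatter link
   `RSSI = 10·log10( K_b P_t G_t λ⁴ |H|⁴ / (4π d_o)⁴ )`
   with log-normal multipath `|H|`, and posture-driven chest acceleration
   with a sinusoidal gait component — so the whole pipeline is testable
   without human-trial data.

## Worked example

```r
library(rfidexit)

room <- room_config("room2")
bench <- make_benchmark(n_trials = 10, seed = 1)

# featurize and fit a dWCRF on the first 6 trials
seqs <- lapply(bench$trials, function(tr)
  list(X = featurize_trial(tr$stream, room),
       y = label_at(tr$annotations, tr$stream$t)))
fit <- crf_fit(seqs[1:6], seqs[7:8], tau = 2, theta = 1e-3)

# stream a held-out trial through the recognizer
rec <- recognize_stream(fit, bench$trials[[9]]$stream, room)
rec$alerts
#>          t  kind participant_id
#> 1 10.86128 chair            p04
#> 2 12.48695   bed            p04
#> 3 13.49911 chair            p04
#> 4 85.53697   bed            p04

truths <- extract_ground_truth_exits(bench$trials[[9]]$annotations)
truths
#>    kind        t      end
#> 2 chair 12.94878 14.04858
#> 1   bed 85.04021 86.62929
match_alerts(rec$alerts, truths)$bed
#> $tp [1] 1   $fp [1] 1   $fn [1] 0   $delays [1] 0.4967665
```

Both annotated exits were caught: the bed exit 0.50 s after the boundary
and the chair exit 2.09 s early (the alert preceded the annotated
boundary, within the 5-s tolerance). The trial also shows the
characteristic failure mode: the direct chair-to-bed transfer around
t = 11–13 s produced one spurious alert of each kind from a brief
misassignment — exactly the kind of error the score function suppresses
but cannot eliminate on saturated marginals.

The full cross-validated evaluation (10 rotations, 6/2/2 trial split,
hyperparameters picked per rotation on the validation folds):

```r
bench30 <- make_benchmark(n_trials = 30, seed = 0)
cv <- crossval(bench30, tau_grid = c(0L, 2L), theta_grid = 1e-3, seed = 0)
print(cv)   # per-kind recall / precision / F (mean +/- SD) and delays
```

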