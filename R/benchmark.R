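## Multi-trial benchmark generation with a controlled label-imbalance
## profile.  Step durations are chosen so that the *expected observation*
## share of each activity matches the requested profile given the
## configured effective read rates (rate * (1 - dropout) summed over
## antennas); actual shares then track the profile within sampling error.

default_imbalance_profile <- function() {
  c(`Lying` = 0.55, `Sitting-on-bed` = 0.30,
    `Sitting-on-chair` = 0.11, `Ambulating` = 0.04)
}

# script templates over activity names; every other trial carries a direct
# bed->chair or chair->bed transfer so both FSM special cases occur
benchmark_templates <- function() {
  list(
    c("Ambulating", "Sitting-on-chair", "Ambulating", "Sitting-on-bed",
      "Lying", "Sitting-on-bed", "Ambulating"),
    c("Ambulating", "Sitting-on-bed", "Lying", "Sitting-on-bed",
      "Sitting-on-chair", "Ambulating"),                      # bed -> chair
    c("Ambulating", "Sitting-on-chair", "Sitting-on-bed", "Lying",
      "Sitting-on-bed", "Ambulating"),                        # chair -> bed
    c("Ambulating", "Sitting-on-bed", "Lying", "Sitting-on-bed",
      "Ambulating", "Sitting-on-chair", "Ambulating"))
}

#' Simulation profile used by the benchmark generator
#'
#' The two noise regimes of [make_benchmark()], exposed so that probe
#' trials can be simulated from exactly the same generative settings as a
#' benchmark.  `"high"` SNR: dense reads (2.5 Hz per antenna), light
#' occlusion dropout, low acceleration noise and mild multipath.  `"low"`
#' SNR: sparse reads (1.2 Hz), heavy posture-dependent dropout and strong
#' noise.
#'
#' @param room a [room_config()].
#' @param snr `"high"` or `"low"`.
#' @return list with `read_rate_hz`, `dropout_prob` (activity x antenna
#'   matrices), `accel_noise_sd` and `rssi` ([rssi_model_params()]).
#' @export
benchmark_sim_profile <- function(room, snr = c("high", "low")) {
  snr <- match.arg(snr)
  acts <- names(activity_labels())
  ants <- room_antenna_ids(room)
  areas <- antenna_area(room, ants)
  mk_mat <- function(x) matrix(x, 4, length(ants), dimnames = list(acts, ants))
  if (snr == "high") {
    rates <- mk_mat(2.5)
    drop <- mk_mat(0.05)
    drop["Sitting-on-chair", areas == "bed"] <- 0.2
    drop["Ambulating", ] <- 0.15
    accel_sd <- 0.03; H_sigma <- 0.08
  } else {
    rates <- mk_mat(1.2)
    drop <- mk_mat(0.25)
    drop["Sitting-on-chair", areas == "bed"] <- 0.65
    drop["Ambulating", ] <- 0.55
    drop["Lying", areas == "chair"] <- 0.6
    accel_sd <- 0.12; H_sigma <- 0.3
  }
  list(read_rate_hz = rates, dropout_prob = drop, accel_noise_sd = accel_sd,
       rssi = rssi_model_params(H_sigma = H_sigma))
}

#' Generate a labeled synthetic benchmark
#'
#' Emits `n_trials` simulated trials whose pooled activity-label fractions
#' track `imbalance_profile` (fractions over observations, which is what
#' class imbalance means to the classifier).  Scripts cycle through
#' templates that include chair exits with and without ambulation and
#' direct bed-to-chair transfers.  `snr = "high"` gives dense reads, low
#' dropout and low noise; `snr = "low"` gives sparse bursty reads, heavy
#' occlusion dropout and noisy acceleration/multipath, the regime in which
#' class weighting matters.
#'
#' @param n_trials number of trials (>= 1).
#' @param imbalance_profile named numeric vector over the four label names,
#'   summing to 1.
#' @param seed integer master seed; trial seeds are derived from it.
#' @param room a [room_config()] (default Room 2).
#' @param snr `"high"` or `"low"`.
#' @param trial_duration approximate trial length in seconds.
#' @param participants number of participant ids to cycle over.
#' @return list of class `exit_benchmark`: `trials` (list of `sim_trial`),
#'   `manifest` (seed, profile, per-trial seeds/participants).
#' @export
make_benchmark <- function(n_trials,
                           imbalance_profile = default_imbalance_profile(),
                           seed = 1L,
                           room = room_config("room2"),
                           snr = c("high", "low"),
                           trial_duration = 90,
                           participants = 5L) {
  snr <- match.arg(snr)
  if (n_trials < 1) stop("n_trials must be >= 1")
  acts <- names(activity_labels())
  prof <- imbalance_profile[acts]
  if (anyNA(prof) || any(prof < 0) || abs(sum(prof) - 1) > 1e-6) {
    stop("imbalance_profile must be a nonnegative vector over the four ",
         "activity names summing to 1")
  }

  prof_cfg <- benchmark_sim_profile(room, snr)
  rates <- prof_cfg$read_rate_hz
  drop <- prof_cfg$dropout_prob
  accel_sd <- prof_cfg$accel_noise_sd
  rssi <- prof_cfg$rssi

  eff_rate <- rowSums(rates * (1 - drop))          # per-activity reads/s
  share_time <- (prof / eff_rate) / sum(prof / eff_rate)

  templates <- benchmark_templates()
  set.seed(as.integer(seed))
  trial_seeds <- sample.int(2^31 - 2, n_trials)
  trials <- vector("list", n_trials)
  for (i in seq_len(n_trials)) {
    tpl <- templates[[(i - 1) %% length(templates) + 1]]
    tpl <- tpl[prof[tpl] > 0]            # drop zero-share activities ...
    tpl <- tpl[c(TRUE, tpl[-1] != tpl[-length(tpl)])]  # ... collapse runs
    if (!length(tpl)) stop("imbalance profile leaves no activities")
    counts <- table(factor(tpl, levels = acts))
    dur <- share_time[tpl] * trial_duration / as.numeric(counts[tpl])
    jit <- exp(rnorm(length(dur), 0, 0.15))
    dur <- dur * jit
    script <- activity_script(tpl, dur, room)
    sim <- sim_config(room, seed = trial_seeds[i],
                      read_rate_hz = rates, dropout_prob = drop,
                      accel_noise_sd = accel_sd)
    pid <- sprintf("p%02d", (i - 1) %% participants + 1)
    gender <- (match(pid, sprintf("p%02d", 1:participants)) %% 2L)
    trials[[i]] <- simulate_trial(script, sim, rssi,
                                  participant_id = pid, gender = gender)
  }
  structure(
    list(trials = trials,
         room = room,
         manifest = list(seed = as.integer(seed), snr = snr,
                         profile = as.list(prof),
                         trial_seeds = trial_seeds,
                         n_trials = n_trials)),
    class = "exit_benchmark")
}

#' Pooled label fractions of a benchmark
#'
#' Fraction of observations per activity, pooled over all trials.
#' @param benchmark an `exit_benchmark`.
#' @return named numeric vector over the four label names, summing to 1.
#' @export
label_fractions <- function(benchmark) {
  counts <- setNames(numeric(4), names(activity_labels()))
  for (tr in benchmark$trials) {
    y <- label_at(tr$annotations, tr$stream$t)
    tab <- table(factor(activity_name(y), levels = names(counts)))
    counts <- counts + as.numeric(tab)
  }
  counts / sum(counts)
}
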