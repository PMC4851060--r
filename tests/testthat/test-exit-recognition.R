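test_that("score_assign pools 1 s of marginals and breaks ties sensibly", {
  # dominant class wins
  h <- list(t = c(0.2, 0.5, 0.9), m = matrix(rep(c(0.7, 0.1, 0.1, 0.1), 3),
                                             3, 4, byrow = TRUE))
  expect_equal(score_assign(h, 0.9), 1L)

  # hand summation: sums (1, 0, 1.6, 0.4) -> Lying (class 3)
  h <- list(t = c(0.1, 0.5, 0.9),
            m = rbind(c(1, 0, 0, 0), c(0, 0, 1, 0), c(0, 0, 0.6, 0.4)))
  expect_equal(score_assign(h, 0.9), 3L)

  # only marginals in (t' - 1, t'] participate
  h <- list(t = c(0.0, 1.5), m = rbind(c(1, 0, 0, 0), c(0, 1, 0, 0)))
  expect_equal(score_assign(h, 1.5), 2L)     # t = 0.0 < 0.5 excluded

  # all-uniform window: previous activity retained (hysteresis)
  h <- list(t = c(0.5, 1), m = matrix(0.25, 2, 4))
  expect_equal(score_assign(h, 1, prev = 3L), 3L)
  expect_equal(score_assign(h, 1, prev = NULL), 1L)  # lowest index fallback

  # invariance to positive rescaling of the window
  set.seed(4)
  m <- matrix(runif(20), 5, 4)
  h1 <- list(t = seq(0.1, 0.9, length.out = 5), m = m)
  h2 <- list(t = h1$t, m = m * 3.7)
  expect_equal(score_assign(h1, 0.9), score_assign(h2, 0.9))

  expect_error(score_assign(list(t = numeric(0), m = matrix(0, 0, 4)), 1),
               "window")
})

test_that("FSM truth table: 4 bed-exit pairs, 3 chair-exit pairs, 9 silent", {
  SB <- lab[["Sitting-on-bed"]]; SC <- lab[["Sitting-on-chair"]]
  LY <- lab[["Lying"]]; AM <- lab[["Ambulating"]]
  bed_pairs <- list(c(LY, AM), c(LY, SC), c(SB, AM), c(SB, SC))
  chair_pairs <- list(c(SC, SB), c(SC, LY), c(SC, AM))

  for (prev in 1:4) for (new in 1:4) {
    st <- recognizer_state()
    st <- fsm_step(st, prev, t = 0)$state
    out <- fsm_step(st, new, t = 10)
    expected <- if (any(vapply(bed_pairs, identical, logical(1),
                               c(prev, new)))) "bed"
      else if (any(vapply(chair_pairs, identical, logical(1),
                          c(prev, new)))) "chair"
      else NA_character_
    if (is.na(expected)) {
      expect_equal(nrow(out$alerts), 0)
    } else {
      expect_equal(out$alerts$kind, expected)
      expect_equal(out$alerts$t, 10)
    }
    expect_equal(out$state$activity, new)
  }

  # first assignment never alerts
  out <- fsm_step(recognizer_state(), lab[["Ambulating"]], t = 1)
  expect_equal(nrow(out$alerts), 0)
})

test_that("1.75-s suppression: boundary inclusive, per kind, last emitted", {
  LY <- lab[["Lying"]]; AM <- lab[["Ambulating"]]; SB <- lab[["Sitting-on-bed"]]
  st <- recognizer_state()
  st <- fsm_step(st, LY, 0)$state
  o1 <- fsm_step(st, AM, 10); st <- o1$state
  expect_equal(o1$alerts$kind, "bed")
  st <- fsm_step(st, SB, 10.5)$state
  o2 <- fsm_step(st, AM, 11.0); st <- o2$state       # within 1.75 s
  expect_equal(nrow(o2$alerts), 0)
  st <- fsm_step(st, SB, 11.5)$state
  o2b <- fsm_step(st, AM, 11.75); st <- o2b$state    # exactly 1.75 s: still
  expect_equal(nrow(o2b$alerts), 0)
  st <- fsm_step(st, SB, 11.9)$state
  o3 <- fsm_step(st, AM, 12.0)                        # > 1.75 s after t = 10
  expect_equal(o3$alerts$kind, "bed")

  # chair suppression is tracked independently of bed
  SC <- lab[["Sitting-on-chair"]]
  st <- recognizer_state()
  st <- fsm_step(st, SB, 0)$state
  o <- fsm_step(st, SC, 1); st <- o$state            # bed exit at t = 1
  expect_equal(o$alerts$kind, "bed")
  o <- fsm_step(st, AM, 2)                            # chair exit at t = 2
  expect_equal(o$alerts$kind, "chair")                # not suppressed by bed
})

test_that("recognize_stream is streaming and alert-consistent", {
  room <- room_config("room2")
  # degenerate model pinned to Lying -> zero alerts
  pin <- crf_model(matrix(0, 4, length(feature_schema(room))),
                   matrix(0, 4, 4), feature_schema = feature_schema(room))
  # huge class-3 score via the read fractions (they always sum to 1)
  pin$unary[3, grep("^frac_", feature_schema(room))] <- 50
  sim <- sim_config(room, seed = 77)
  tr <- simulate_trial(activity_script("Lying", 20, room), sim)
  rec <- recognize_stream(pin, tr$stream, room)
  expect_equal(nrow(rec$alerts), 0)
  expect_true(all(rec$labels$label == 3))

  # trained model on a noiseless scripted trial -> exactly one bed exit
  clean_sim <- function(seed) {
    sim_config(room, seed = seed, read_rate_hz = 5, dropout_prob = 0,
               accel_noise_sd = 0.01, phase_noise_sd = 0.01)
  }
  clean_rssi <- rssi_model_params(H_sigma = 0.02)
  scripts <- list(
    activity_script(c("Ambulating", "Sitting-on-chair", "Ambulating",
                      "Sitting-on-bed", "Lying", "Sitting-on-bed",
                      "Ambulating"), c(8, 15, 8, 15, 20, 10, 8), room),
    activity_script(c("Lying", "Sitting-on-bed", "Sitting-on-chair",
                      "Ambulating", "Sitting-on-bed", "Lying"),
                    c(20, 12, 15, 8, 12, 15), room))
  train <- lapply(1:4, function(i) {
    trr <- simulate_trial(scripts[[(i - 1) %% 2 + 1]], clean_sim(500 + i),
                          clean_rssi)
    list(X = featurize_trial(trr$stream, room),
         y = label_at(trr$annotations, trr$stream$t))
  })
  fit <- crf_fit(train[1:3], train[4], tau = 0, theta = 1e-3)
  script <- activity_script(c("Lying", "Sitting-on-bed", "Ambulating"),
                            c(30, 20, 10), room)
  tr2 <- simulate_trial(script, clean_sim(99), clean_rssi)
  rec2 <- recognize_stream(fit, tr2$stream, room)
  expect_equal(sum(rec2$alerts$kind == "bed"), 1)

  # suppression invariant on any run's alert log
  for (kind in unique(rec2$alerts$kind)) {
    tt <- sort(rec2$alerts$t[rec2$alerts$kind == kind])
    if (length(tt) > 1) expect_true(all(diff(tt) > 1.75))
  }

  # alert timestamps are observation timestamps
  expect_true(all(rec2$alerts$t %in% tr2$stream$t))
})
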