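room2 <- room_config("room2")
room1 <- room_config("room1")

test_that("instantaneous features: tilt, yaw, roll, dt", {
  obs <- fix_stream(1)[1, ]
  obs$a_v <- 0.5; obs$a_f <- 0.5; obs$a_l <- 0.3
  f <- instantaneous_features(obs, prev_t = NULL, room2)
  expect_equal(f[["sin_theta"]], sin(pi / 4))
  expect_equal(f[["roll"]], atan2(0.3, 0.5))
  expect_equal(f[["dt"]], 0)

  obs$a_f <- 0; obs$a_v <- 1; obs$a_l <- 0
  f <- instantaneous_features(obs, prev_t = 0.6, room2)
  expect_equal(f[["sin_theta"]], 0)          # upright
  expect_equal(f[["yaw"]], 0)
  expect_equal(f[["dt"]], 0.4)

  obs$a_l <- 0.3; obs$a_f <- 0.3; obs$a_v <- 0.3
  f <- instantaneous_features(obs, 0, room2)
  expect_equal(f[["yaw"]], pi / 4)
  expect_equal(f[["roll"]], pi / 4)

  # degenerate (0,0) ratios resolve to 0, not NaN
  obs$a_v <- 0; obs$a_l <- 0; obs$a_f <- 0
  f <- instantaneous_features(obs, 0, room2)
  expect_equal(unname(f[c("sin_theta", "yaw", "roll")]), c(0, 0, 0))

  # one-hot antenna indicator
  expect_equal(unname(f[paste0("ant_", c("antenna1", "antenna2", "antenna3"))]),
               c(1, 0, 0))
})

test_that("make_segment applies the (t-4, t] window, current first", {
  s <- fix_stream(c(0, 1, 3, 5))
  idx <- make_segment(s, 4)
  expect_equal(s$t[idx], c(5, 3))            # t = 1 is on the open boundary
  expect_equal(make_segment(fix_stream(0), 1), 1)
  s2 <- fix_stream(c(0, 0.1, 0.2, 0.3))
  expect_equal(sort(make_segment(s2, 4)), 1:4)
})

test_that("contextual features: fractions, mutual information, correlation", {
  s <- fix_stream(c(0, 0.5, 1),
                  antenna_id = c("antenna2", "antenna1", "antenna2"))
  seg <- s[make_segment(s, 3), ]
  f <- contextual_features(seg, room2)
  # areas bed, chair, bed -> both adjacent pairs cross -> 2/3
  expect_equal(f[["mi_bedchair"]], 2 / 3)
  expect_equal(unname(f[paste0("frac_", c("antenna1", "antenna2", "antenna3"))]),
               c(1 / 3, 2 / 3, 0))

  # single-antenna segment: fraction 1, max/min RSSI antenna coincide
  s <- fix_stream(c(0, 1, 2), antenna_id = "antenna3", rssi = c(-60, -50, -70))
  f <- contextual_features(s[make_segment(s, 3), ], room2)
  expect_equal(f[["frac_antenna3"]], 1)
  expect_equal(f[["mi_bedchair"]], 0)        # single area
  expect_equal(f[["rssimax_antenna3"]], 1)
  expect_equal(f[["rssimin_antenna3"]], 1)

  # exact affine dependence -> correlation +/- 1
  s <- fix_stream(c(0, 1, 2))
  s$a_f <- c(0.1, 0.2, 0.4); s$a_l <- 2 * s$a_f + 0.05
  f <- contextual_features(s[make_segment(s, 3), ], room2)
  expect_equal(f[["corr_lf"]], 1)
  s$a_l <- -s$a_f
  f <- contextual_features(s[make_segment(s, 3), ], room2)
  expect_equal(f[["corr_lf"]], -1)
})

test_that("per-antenna read fractions sum to 1; MI bounded by (n-1)/n", {
  set.seed(3)
  for (i in 1:20) {
    n <- sample(1:12, 1)
    s <- fix_stream(sort(runif(n, 0, 3.5)),
                    antenna_id = sample(paste0("antenna", 1:3), n, TRUE),
                    rssi = runif(n, -80, -40))
    f <- contextual_features(s[make_segment(s, n), ], room2)
    expect_equal(sum(f[paste0("frac_", paste0("antenna", 1:3))]), 1)
    expect_gte(f[["mi_bedchair"]], 0)
    expect_lte(f[["mi_bedchair"]], (n - 1) / n)
  }
})

test_that("intersegment features difference order statistics", {
  cur <- fix_stream(c(4, 5, 6)); cur$a_v <- c(0.2, 0.4, 0.9)
  prev <- fix_stream(c(1, 2, 3)); prev$a_v <- c(0.1, 0.1, 0.3)
  f <- intersegment_features(cur, prev, room2)
  expect_equal(f[["d_median_av"]], 0.3)
  expect_equal(f[["d_max_av"]], 0.6)
  expect_equal(f[["d_min_av"]], 0.1)

  # identical segments -> all zero
  f0 <- intersegment_features(cur, cur, room2)
  expect_true(all(f0 == 0))

  # antenna absent from previous segment -> floor sentinel differences
  cur2 <- fix_stream(c(4, 5), antenna_id = "antenna2", rssi = -55)
  prev2 <- fix_stream(c(1, 2), antenna_id = "antenna1", rssi = -60)
  f <- intersegment_features(cur2, prev2, room2)
  expect_equal(f[["d_median_rssi_antenna2"]], -55 - (-90))
  expect_equal(f[["d_median_rssi_antenna3"]], 0)   # absent from both
})

test_that("featurize_trial is causal with a stable per-room schema", {
  set.seed(8)
  sim <- sim_config(room1, seed = 41)
  tr <- simulate_trial(
    activity_script(c("Sitting-on-bed", "Lying"), c(10, 10), room1), sim)
  s <- tr$stream
  X <- featurize_trial(s, room1)
  expect_equal(nrow(X), nrow(s))
  expect_false(any(!is.finite(X)))
  expect_identical(colnames(X), feature_schema(room1))

  # causality: truncating the stream reproduces the leading rows
  i <- min(25, nrow(s) - 1)
  Xi <- featurize_trial(s[seq_len(i), ], room1)
  expect_equal(Xi, X[seq_len(i), , drop = FALSE])

  # single observation: one vector, inter-segment block all zero
  X1 <- featurize_trial(s[1, ], room1)
  expect_equal(nrow(X1), 1)
  expect_true(all(X1[1, grep("^d_", colnames(X1))] == 0))

  # schema: dagger features appear only for Room 1; count fixed at 16
  r1_nodagger <- room_config("room1")
  r1_nodagger$use_dagger_features <- FALSE
  expect_equal(length(feature_schema(room1)),
               length(feature_schema(r1_nodagger)) + 16)
  dagger_names <- c("mean_av", "sd_av", "mean_al", "sd_al", "mean_af",
                    "sd_af", "vfpr_sd", "cfpr_abssum")
  expect_true(all(dagger_names %in% feature_schema(room1)))
  expect_false(any(dagger_names %in% feature_schema(room2)))
})

test_that("phase-rate features wrap phase and split by channel", {
  # two reads on the same channel: CFPR = wrapped dphi / dt
  s <- fix_stream(c(0, 0.5), phase = c(6.2, 0.1), channel = c(4L, 4L))
  f <- contextual_features(s[make_segment(s, 2), ], room1)
  dphi <- (0.1 - 6.2 + pi) %% (2 * pi) - pi      # small positive wrap
  expect_equal(f[["cfpr_abssum"]], abs(dphi) / 0.5)
  expect_equal(f[["vfpr_sd"]], 0)

  # channel change routes the rate to VFPR instead
  s$channel <- c(4L, 5L)
  f <- contextual_features(s[make_segment(s, 2), ], room1)
  expect_equal(f[["cfpr_abssum"]], 0)
  expect_equal(f[["vfpr_sd"]], 0)                # single value -> SD 0
})
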