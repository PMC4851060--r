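## Per-observation feature extraction for irregular RFID sensor streams.
##
## Three families:
##  * instantaneous  — from the current read alone,
##  * contextual     — over a 4-s sliding window (t - 4, t] whose first
##                     element is the current read,
##  * inter-segment  — differences of order statistics between the current
##                     window and the previous observation's window.
## The extended ("dagger") statistics are emitted only when the room's
## `use_dagger_features` flag is set (Room 1).
##
## Degenerate-case conventions (applied throughout so vectors never carry
## undefined entries): single-argument arctangents become atan2 with
## atan2(0, 0) = 0; SD of fewer than two values is 0; Pearson correlation
## with a zero-variance argument is 0; antennas absent from a window get
## read-fraction 0 and RSSI statistics at a floor (default -90 dBm).

SEGMENT_SPAN <- 4          # seconds, contextual window length
RSSI_FLOOR <- -90          # dBm sentinel for antennas absent from a window

#' Instantaneous features of one observation
#'
#' Features computable from a single read: raw accelerations; trunk tilt
#' `sin(theta) = sin(atan2(a_f, a_v))` (forward/backward lean); rotational
#' angles `yaw = atan2(a_l, a_f)` and `roll = atan2(a_l, a_v)`; a one-hot
#' antenna indicator; RSSI; time since the previous observation (0 for the
#' first read); and the gender covariate.
#'
#' @param obs one-row data.frame (or list) with the stream fields.
#' @param prev_t timestamp of the previous observation, or `NULL`.
#' @param room a [room_config()].
#' @return named numeric vector.
#' @export
instantaneous_features <- function(obs, prev_t = NULL, room) {
  ants <- room_antenna_ids(room)
  onehot <- as.numeric(ants == obs$antenna_id)
  names(onehot) <- paste0("ant_", ants)
  c(a_v = obs$a_v, a_l = obs$a_l, a_f = obs$a_f,
    sin_theta = sin(atan2(obs$a_f, obs$a_v)),
    yaw = atan2(obs$a_l, obs$a_f),
    roll = atan2(obs$a_l, obs$a_v),
    onehot,
    rssi = obs$rssi,
    dt = if (is.null(prev_t)) 0 else obs$t - prev_t,
    gender = as.numeric(obs$gender))
}

#' Contextual window (segment) of a stream
#'
#' Returns the indices of the observations in the 4-s window anchored at
#' observation `i`: all reads with `t` in `(t_i - 4, t_i]`, current
#' observation first, then decreasing in time.
#'
#' @param stream a `sensor_stream` data.frame.
#' @param i index of the current observation.
#' @return integer vector of row indices (current first).
#' @export
make_segment <- function(stream, i) {
  stopifnot(i >= 1, i <= nrow(stream))
  t_cur <- stream$t[i]
  idx <- which(stream$t > t_cur - SEGMENT_SPAN & stream$t <= t_cur)
  idx <- idx[idx <= i]                     # causal: never read the future
  c(i, rev(setdiff(idx, i)))
}

# wrap phase differences into (-pi, pi]
wrap_phase <- function(dphi) {
  w <- (dphi + pi) %% (2 * pi) - pi
  w[w == -pi] <- pi
  w
}

sd0 <- function(x) if (length(x) < 2) 0 else sd(x)

cor0 <- function(x, y) {
  if (length(x) < 2 || sd(x) == 0 || sd(y) == 0) return(0)
  cor(x, y)
}

# twice-repeated trapezoidal integration of (a_v - mean(a_v)) over the
# window's irregular timestamps: vertical displacement proxy (g * s^2)
displacement_av <- function(t, a_v) {
  n <- length(t)
  if (n < 2) return(0)
  ord <- order(t)
  t <- t[ord]; a <- a_v[ord] - mean(a_v)
  dt <- diff(t)
  v <- c(0, cumsum(dt * (a[-n] + a[-1]) / 2))
  sum(dt * (v[-n] + v[-1]) / 2)
}

# constant/variable-frequency phase rates between consecutive reads
phase_rates <- function(t, phase, channel) {
  n <- length(t)
  if (n < 2) return(list(cfpr = numeric(0), vfpr = numeric(0)))
  ord <- order(t)
  t <- t[ord]; phase <- phase[ord]; channel <- channel[ord]
  dt <- diff(t)
  keep <- dt > 0
  rate <- wrap_phase(diff(phase))[keep] / dt[keep]
  same <- (diff(channel) == 0)[keep]
  list(cfpr = rate[same], vfpr = rate[!same])
}

#' Contextual (4-s window) features
#'
#' Statistics over the current segment: per-antenna read fractions; the
#' bed/chair area mutual-information score
#' `(1/n) * sum_k 1{(area_k, area_k+1) in {(bed,chair),(chair,bed)}}`
#' over time-adjacent reads; one-hot ids of the antennas attaining max and
#' min RSSI; the double time-integral displacement along `a_v` (gravity
#' removed by subtracting the window mean); Pearson correlations between
#' acceleration axis pairs; and, when the room enables dagger features,
#' mean/SD of each axis, per-antenna RSSI mean/SD, the SD of the
#' variable-frequency phase rate and the summed modulus of the
#' constant-frequency phase rate.
#'
#' @param seg data.frame of the segment's observations (current first, as
#'   produced by indexing the stream with [make_segment()]).
#' @param room a [room_config()].
#' @return named numeric vector (schema fixed per room).
#' @export
contextual_features <- function(seg, room) {
  stopifnot(nrow(seg) >= 1)
  ants <- room_antenna_ids(room)
  n <- nrow(seg)
  ord <- order(seg$t)                      # chronological for pairwise terms
  aid <- seg$antenna_id[ord]

  frac <- as.numeric(table(factor(seg$antenna_id, levels = ants))) / n
  names(frac) <- paste0("frac_", ants)

  if (n >= 2) {
    area <- antenna_area(room, aid)
    pair_cross <- (area[-n] == "bed" & area[-1] == "chair") |
      (area[-n] == "chair" & area[-1] == "bed")
    mi <- sum(pair_cross) / n
  } else {
    mi <- 0
  }

  i_max <- which.max(seg$rssi); i_min <- which.min(seg$rssi)
  max_hot <- as.numeric(ants == seg$antenna_id[i_max])
  min_hot <- as.numeric(ants == seg$antenna_id[i_min])
  names(max_hot) <- paste0("rssimax_", ants)
  names(min_hot) <- paste0("rssimin_", ants)

  out <- c(frac, mi_bedchair = mi, max_hot, min_hot,
           disp_av = displacement_av(seg$t, seg$a_v),
           corr_vl = cor0(seg$a_v, seg$a_l),
           corr_vf = cor0(seg$a_v, seg$a_f),
           corr_lf = cor0(seg$a_l, seg$a_f))

  if (room$use_dagger_features) {
    by_ant <- split(seg$rssi, factor(seg$antenna_id, levels = ants))
    rssi_mean <- vapply(by_ant,
                        function(x) if (length(x)) mean(x) else RSSI_FLOOR,
                        numeric(1))
    rssi_sd <- vapply(by_ant, sd0, numeric(1))
    names(rssi_mean) <- paste0("rssimean_", ants)
    names(rssi_sd) <- paste0("rssisd_", ants)
    pr <- phase_rates(seg$t, seg$phase, seg$channel)
    out <- c(out,
             mean_av = mean(seg$a_v), sd_av = sd0(seg$a_v),
             mean_al = mean(seg$a_l), sd_al = sd0(seg$a_l),
             mean_af = mean(seg$a_f), sd_af = sd0(seg$a_f),
             rssi_mean, rssi_sd,
             vfpr_sd = sd0(pr$vfpr),
             cfpr_abssum = sum(abs(pr$cfpr)))
  }
  out
}

seg_axis_stats <- function(seg) {
  vapply(c("a_v", "a_l", "a_f"), function(ax) {
    x <- seg[[ax]]
    c(median = median(x), max = max(x), min = min(x))
  }, numeric(3))
}

seg_rssi_stats <- function(seg, ants) {
  by_ant <- split(seg$rssi, factor(seg$antenna_id, levels = ants))
  vapply(by_ant, function(x) {
    if (!length(x)) return(c(median = RSSI_FLOOR, max = RSSI_FLOOR,
                             min = RSSI_FLOOR))
    c(median = median(x), max = max(x), min = min(x))
  }, numeric(3))
}

#' Inter-segment features
#'
#' Differences of median/max/min of each acceleration axis and of RSSI per
#' antenna between the current and the previous observation's segments.
#' Antennas absent from a segment contribute statistics at the -90 dBm
#' floor.  For the first observation of a trial pass `seg_prev = seg_cur`
#' (all differences 0).
#'
#' @param seg_cur,seg_prev segment data.frames (nonempty).
#' @param room a [room_config()].
#' @return named numeric vector.
#' @export
intersegment_features <- function(seg_cur, seg_prev, room) {
  stopifnot(nrow(seg_cur) >= 1, nrow(seg_prev) >= 1)
  ants <- room_antenna_ids(room)
  da <- seg_axis_stats(seg_cur) - seg_axis_stats(seg_prev)
  dr <- seg_rssi_stats(seg_cur, ants) - seg_rssi_stats(seg_prev, ants)
  out <- c(da[, "a_v"], da[, "a_l"], da[, "a_f"], as.numeric(dr))
  names(out) <- c(
    paste0("d_", c("median", "max", "min"), "_av"),
    paste0("d_", c("median", "max", "min"), "_al"),
    paste0("d_", c("median", "max", "min"), "_af"),
    as.vector(outer(c("d_median_rssi_", "d_max_rssi_", "d_min_rssi_"),
                    ants, paste0)))
  out
}

#' Feature schema for a room
#'
#' Ordered feature names produced by [featurize_trial()] for a room
#' configuration.  Identical for every observation of a dataset from that
#' room; Room 1 appends the dagger features.
#'
#' @param room a [room_config()].
#' @return character vector of feature names.
#' @export
feature_schema <- function(room) {
  stream <- data.frame(t = 0, a_v = 1, a_l = 0, a_f = 0, rssi = -60,
                       antenna_id = room_antenna_ids(room)[1], phase = 0,
                       channel = 1L, participant_id = "p", gender = 0L,
                       stringsAsFactors = FALSE)
  colnames(featurize_trial(stream, room))
}

#' Feature vectors for a whole trial
#'
#' One feature vector per observation, concatenating the instantaneous,
#' contextual and inter-segment families.  Strictly causal: the vector at
#' observation `i` depends only on reads at `t <= t_i`.
#'
#' @param stream a time-sorted `sensor_stream`.
#' @param room a [room_config()].
#' @return numeric matrix, `nrow(stream)` rows, columns named per
#'   [feature_schema()].
#' @export
featurize_trial <- function(stream, room) {
  n <- nrow(stream)
  if (n == 0) stop("cannot featurize an empty stream")
  rows <- vector("list", n)
  seg_prev <- NULL
  for (i in seq_len(n)) {
    idx <- make_segment(stream, i)
    seg <- stream[idx, , drop = FALSE]
    if (is.null(seg_prev)) seg_prev <- seg
    rows[[i]] <- c(
      instantaneous_features(stream[i, ], if (i > 1) stream$t[i - 1], room),
      contextual_features(seg, room),
      intersegment_features(seg, seg_prev, room))
    seg_prev <- seg
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
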