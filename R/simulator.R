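## Synthetic trial generator for body-worn passive RFID sensor streams.
##
## The generative model is deliberately simple but reproduces the phenomena
## a recognizer must survive with backscatter-powered tags:
##   * irregular, bursty read arrivals: per-antenna Poisson processes whose
##     rates are thinned by posture/antenna-dependent dropout (occlusion of
##     the tag by the body),
##   * RSSI following the inverse-fourth-power monostatic backscatter link
##     with log-normal multipath gain,
##   * posture-dependent chest acceleration (upright ~ (1,0,0) g on the
##     (a_v,a_l,a_f) axes, supine ~ (0,0,1) g) plus Gaussian sensor noise
##     and a sinusoidal gait component while ambulating.

#' Backscatter link-budget parameters
#'
#' Parameters of the monostatic backscatter power link used to generate
#' RSSI: received power is
#' `K_b * P_t * G_t * wl^4 * |H|^4 / (4 * pi * d_o)^4`,
#' where `d_o` is the direct tag-antenna distance and `H` the multipath
#' channel response.
#'
#' @param K_b tag backscatter gain (dimensionless, > 0).
#' @param P_t reader output power in linear units (mW here, so that
#'   `rssi_db()` is read as dBm).
#' @param G_t monostatic reader antenna gain (dimensionless).
#' @param wl carrier wavelength in meters (0.325 m ~ 923 MHz ISM band).
#' @param H_sigma scale (sdlog) of the log-normal multipath magnitude
#'   `|H|`, unit median.
#' @return object of class `rssi_model_params`.
#' @export
rssi_model_params <- function(K_b = 0.01, P_t = 1000, G_t = 4,
                              wl = 0.325, H_sigma = 0.12) {
  p <- list(K_b = K_b, P_t = P_t, G_t = G_t, wl = wl, H_sigma = H_sigma)
  if (any(unlist(p) <= 0)) stop("all rssi_model_params must be positive")
  structure(p, class = "rssi_model_params")
}

#' Backscatter RSSI in dB
#'
#' Received signal strength (dB relative to the power unit of `P_t`) of a
#' passive tag at direct distance `d_o` with multipath magnitude `H_mag`:
#' `10*log10(K_b*P_t*G_t*wl^4*H_mag^4 / (4*pi*d_o)^4)`.  Strictly
#' decreasing in `d_o` with a -40 dB/decade slope.
#'
#' @param params an [rssi_model_params()].
#' @param d_o direct distance in meters (> 0); vectorized.
#' @param H_mag multipath channel magnitude (> 0); vectorized.
#' @return RSSI in dBm (when `P_t` is in mW).
#' @examples
#' rssi_db(rssi_model_params(), d_o = 1) - rssi_db(rssi_model_params(), d_o = 2)
#' # == 10*log10(16): the fourth-power law
#' @export
rssi_db <- function(params, d_o, H_mag = 1) {
  stopifnot(inherits(params, "rssi_model_params"))
  if (any(d_o <= 0)) stop("d_o must be positive")
  if (any(H_mag <= 0)) stop("H_mag must be positive")
  lin <- params$K_b * params$P_t * params$G_t * params$wl^4 * H_mag^4 /
    (4 * pi * d_o)^4
  10 * log10(lin)
}

#' Activity script for a simulated trial
#'
#' An ordered list of (activity, duration) steps.  Transitions must be
#' physically plausible: `Lying` may only border `Sitting-on-bed`
#' (one sits up before leaving the bed); direct `Sitting-on-bed` <->
#' `Sitting-on-chair` transfers (no ambulation observed) are allowed, as
#' are transitions between `Ambulating` and either sitting posture.
#'
#' @param activities vector of label names or codes.
#' @param durations positive durations in seconds, same length.
#' @param room a [room_config()].
#' @return object of class `activity_script`.
#' @export
activity_script <- function(activities, durations, room) {
  act <- if (is.character(activities)) activity_code(activities)
         else as.integer(activities)
  if (length(act) == 0) stop("script must be nonempty")
  if (length(act) != length(durations) || any(durations <= 0)) {
    stop("durations must be positive and match activities in length")
  }
  lab <- activity_labels()
  LY <- lab[["Lying"]]; SB <- lab[["Sitting-on-bed"]]
  if (length(act) > 1) {
    prev <- act[-length(act)]; nxt <- act[-1]
    if (any(prev == nxt)) stop("consecutive script steps must differ")
    bad <- (prev == LY & nxt != SB) | (nxt == LY & prev != SB)
    if (any(bad)) {
      stop("implausible transition: Lying must border Sitting-on-bed")
    }
  }
  structure(list(activities = act, durations = as.numeric(durations),
                 room = room),
            class = "activity_script")
}

#' Simulation configuration
#'
#' Rates, dropout, noise scales and room geometry for [simulate_trial()].
#' `read_rate_hz` and `dropout_prob` are activity-by-antenna matrices
#' (rownames = label names, colnames = antenna ids); scalars are recycled.
#'
#' @param room a [room_config()].
#' @param seed integer RNG seed recorded in the trial manifest.
#' @param read_rate_hz scalar or activity x antenna matrix of Poisson read
#'   rates (Hz) per antenna.
#' @param dropout_prob scalar or activity x antenna matrix of read-loss
#'   probabilities in `[0, 1]` (thinning of the Poisson process).
#' @param accel_noise_sd accelerometer noise SD in g.
#' @param posture_orientation 4 x 3 matrix of mean `(a_v, a_l, a_f)` per
#'   activity code (rows 1..4); static postures should have magnitude ~1 g.
#' @param antenna_positions matrix (n_antennas x 3) of antenna coordinates
#'   in meters; rownames are antenna ids.
#' @param furniture_positions named list with 3-vectors `bed`, `chair`,
#'   `door` (sensor positions in meters when at that furniture).
#' @param gait_amp,gait_freq amplitude (g) and frequency (Hz) of the
#'   sinusoidal gait component added to `a_v` while Ambulating.
#' @param phase_noise_sd RF phase noise SD in radians.
#' @param n_channels number of frequency channels (hopping is uniform).
#' @return object of class `sim_config`.
#' @export
sim_config <- function(room,
                       seed = 1L,
                       read_rate_hz = 1.5,
                       dropout_prob = NULL,
                       accel_noise_sd = 0.05,
                       posture_orientation = NULL,
                       antenna_positions = NULL,
                       furniture_positions = NULL,
                       gait_amp = 0.15,
                       gait_freq = 1.8,
                       phase_noise_sd = 0.1,
                       n_channels = 16L) {
  acts <- names(activity_labels())
  ants <- room_antenna_ids(room)
  expand <- function(x, default) {
    if (is.null(x)) x <- default
    if (is.matrix(x)) {
      stopifnot(identical(rownames(x), acts), identical(colnames(x), ants))
      return(x)
    }
    matrix(x, nrow = length(acts), ncol = length(ants),
           dimnames = list(acts, ants))
  }
  rates <- expand(read_rate_hz, 1.5)
  if (is.null(dropout_prob)) {
    # default: ceiling/bed antennas lose reads while the wearer is at the
    # chair or walking (body occlusion); chair antenna loses reads in bed
    areas <- antenna_area(room, ants)
    dropout_prob <- matrix(0.15, nrow = length(acts), ncol = length(ants),
                           dimnames = list(acts, ants))
    dropout_prob["Sitting-on-chair", areas == "bed"] <- 0.55
    dropout_prob["Ambulating", ] <- 0.45
    dropout_prob["Lying", areas == "chair"] <- 0.5
    dropout_prob["Sitting-on-bed", areas == "chair"] <- 0.4
  }
  drop <- expand(dropout_prob, 0.15)
  if (any(rates <= 0)) stop("read rates must be positive")
  if (any(drop < 0 | drop > 1)) stop("dropout probabilities must be in [0,1]")

  if (is.null(posture_orientation)) {
    posture_orientation <- rbind(
      `Sitting-on-bed`   = c(0.98, 0.02, 0.18),
      `Sitting-on-chair` = c(0.97, -0.03, 0.22),
      `Lying`            = c(0.05, 0.02, 0.99),
      `Ambulating`       = c(0.99, 0.00, 0.10))
    colnames(posture_orientation) <- c("a_v", "a_l", "a_f")
  }
  if (is.null(furniture_positions)) {
    furniture_positions <- list(bed = c(1.0, 3.5, 0.9),
                                chair = c(3.5, 1.0, 1.0),
                                door = c(4.5, 4.5, 1.3))
  }
  if (is.null(antenna_positions)) {
    antenna_positions <- if (room$room_id == "room1") {
      rbind(antenna1 = c(2.2, 4.2, 1.3),   # vertical stand, bed area
            antenna2 = c(3.2, 0.6, 1.3),   # vertical stand, chair
            antenna3 = c(1.0, 3.5, 2.5),   # ceiling over bed
            antenna4 = c(0.3, 2.8, 1.3))   # vertical stand, bed area
    } else {
      rbind(antenna1 = c(3.6, 0.5, 1.3),   # vertical stand, chair
            antenna2 = c(0.8, 3.1, 2.5),   # ceiling, bed
            antenna3 = c(1.6, 4.0, 2.5))   # ceiling, bed
    }
  }
  stopifnot(identical(rownames(antenna_positions), ants))
  structure(list(room = room, seed = as.integer(seed),
                 read_rate_hz = rates, dropout_prob = drop,
                 accel_noise_sd = accel_noise_sd,
                 posture_orientation = posture_orientation,
                 antenna_positions = antenna_positions,
                 furniture_positions = furniture_positions,
                 gait_amp = gait_amp, gait_freq = gait_freq,
                 phase_noise_sd = phase_noise_sd,
                 n_channels = as.integer(n_channels)),
            class = "sim_config")
}

# sensor position while performing activity `code` at furniture-level
# granularity (lying lowers the chest a little relative to sitting in bed)
activity_position <- function(sim, code) {
  fp <- sim$furniture_positions
  switch(code,
         fp$bed + c(0, 0, 0.25),   # sitting on bed
         fp$chair,                 # sitting on chair
         fp$bed,                   # lying
         NULL)                     # ambulating: interpolated by caller
}

#' Simulate one trial
#'
#' Generates a sensor observation stream plus exact ground-truth
#' annotations for an [activity_script()].  Reads arrive as per-antenna
#' Poisson processes thinned by dropout; acceleration is the posture mean
#' plus Gaussian noise (plus a sinusoidal gait component while
#' Ambulating); RSSI comes from [rssi_db()] with the sensor-to-antenna
#' distance along a piecewise trajectory and log-normal multipath; during
#' Ambulating the sensor moves linearly from the previous posture's
#' location to the next one's (or to the door).  Identical seeds give
#' identical output.
#'
#' @param script an [activity_script()].
#' @param sim a [sim_config()].
#' @param rssi an [rssi_model_params()].
#' @param participant_id opaque participant identifier.
#' @param gender 0/1 covariate.
#' @return list of class `sim_trial` with elements `stream`
#'   (a `sensor_stream`), `annotations`, `script`, `room`, and `manifest`
#'   (seed and config summary).
#' @export
simulate_trial <- function(script, sim, rssi = rssi_model_params(),
                           participant_id = "p01", gender = 0L) {
  stopifnot(inherits(script, "activity_script"), inherits(sim, "sim_config"))
  room <- sim$room
  ants <- room_antenna_ids(room)
  acts <- names(activity_labels())
  starts <- cumsum(c(0, script$durations[-length(script$durations)]))
  ends <- starts + script$durations
  ann <- make_annotations(starts, ends, script$activities)

  set.seed(sim$seed)
  n_steps <- length(script$activities)
  AMB <- activity_labels()[["Ambulating"]]

  # piecewise-linear sensor trajectory anchors per script step
  pos_from <- pos_to <- matrix(NA_real_, n_steps, 3)
  for (i in seq_len(n_steps)) {
    code <- script$activities[i]
    if (code != AMB) {
      pos_from[i, ] <- pos_to[i, ] <- activity_position(sim, code)
    }
  }
  for (i in seq_len(n_steps)) {
    if (script$activities[i] == AMB) {
      from <- if (i > 1) pos_to[i - 1, ] else sim$furniture_positions$door
      to <- if (i < n_steps) pos_from[i + 1, ] else sim$furniture_positions$door
      pos_from[i, ] <- from + c(0, 0, 0.3)  # standing raises the chest
      pos_to[i, ] <- to + c(0, 0, 0.3)
    }
  }

  rows <- vector("list", n_steps)
  for (i in seq_len(n_steps)) {
    code <- script$activities[i]
    act <- acts[code]
    dur <- script$durations[i]
    tt <- aid <- NULL
    for (a in ants) {
      lambda <- sim$read_rate_hz[act, a] * (1 - sim$dropout_prob[act, a])
      n <- rpois(1, lambda * dur)
      if (n > 0) {
        tt <- c(tt, starts[i] + sort(runif(n, 0, dur)))
        aid <- c(aid, rep(a, n))
      }
    }
    if (is.null(tt)) next
    ord <- order(tt)
    tt <- tt[ord]; aid <- aid[ord]
    frac <- (tt - starts[i]) / dur
    pos <- pos_from[rep(i, length(tt)), , drop = FALSE] +
      outer(frac, pos_to[i, ] - pos_from[i, ])
    d <- sqrt(rowSums((pos - sim$antenna_positions[aid, , drop = FALSE])^2))
    H <- rlnorm(length(tt), 0, rssi$H_sigma)
    rs <- rssi_db(rssi, d, H)
    mu <- sim$posture_orientation[code, ]
    acc <- matrix(rnorm(3 * length(tt), sd = sim$accel_noise_sd),
                  ncol = 3, byrow = FALSE) +
      matrix(mu, nrow = length(tt), ncol = 3, byrow = TRUE)
    if (code == AMB) {
      acc[, 1] <- acc[, 1] + sim$gait_amp * sin(2 * pi * sim$gait_freq * tt)
      acc[, 3] <- acc[, 3] +
        0.4 * sim$gait_amp * sin(2 * pi * sim$gait_freq * tt + pi / 3)
    }
    ch <- sample.int(sim$n_channels, length(tt), replace = TRUE)
    wl_ch <- rssi$wl * (1 - 0.003 * (ch - (sim$n_channels + 1) / 2))
    ph <- (4 * pi * d / wl_ch + rnorm(length(tt), 0, sim$phase_noise_sd)) %%
      (2 * pi)
    rows[[i]] <- data.frame(
      t = tt,
      a_v = pmax(-3, pmin(3, acc[, 1])),
      a_l = pmax(-3, pmin(3, acc[, 2])),
      a_f = pmax(-3, pmin(3, acc[, 3])),
      rssi = rs, antenna_id = aid, phase = ph, channel = ch,
      participant_id = participant_id, gender = as.integer(gender),
      stringsAsFactors = FALSE)
  }
  stream <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  if (is.null(stream)) stream <- empty_stream()
  stream <- stream[order(stream$t), , drop = FALSE]
  stream <- validate_stream(stream, room)
  structure(list(stream = stream, annotations = ann, script = script,
                 room = room,
                 manifest = list(seed = sim$seed,
                                 participant_id = participant_id,
                                 gender = as.integer(gender),
                                 n_obs = nrow(stream),
                                 span = max(ends))),
            class = "sim_trial")
}

empty_stream <- function() {
  data.frame(t = numeric(0), a_v = numeric(0), a_l = numeric(0),
             a_f = numeric(0), rssi = numeric(0),
             antenna_id = character(0), phase = numeric(0),
             channel = integer(0), participant_id = character(0),
             gender = integer(0), stringsAsFactors = FALSE)
}
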