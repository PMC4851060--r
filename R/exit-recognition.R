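## Streaming activity assignment and bed/chair exit alerting.
##
## Each arriving observation's filtered marginals are pooled with those of
## the previous 1 s of observations (window (t' - 1, t']); the argmax of
## the pooled scores is the assigned activity.  The 1-s pool is long
## enough to drown isolated misclassifications but shorter than the
## minimum posture-transition duration (1.75 s), so genuine transitions
## are not averaged away.  A small finite-state machine then raises
## alerts on alarm-worthy transitions, with a 1.75-s per-kind refractory
## period (two same-kind exits cannot physically occur faster).

SCORE_WINDOW <- 1.0        # seconds of marginals pooled by the score function
SUPPRESSION_S <- 1.75      # refractory period per alert kind

BED_PREV <- c(3L, 1L)      # Lying, Sitting-on-bed
BED_NEXT <- c(4L, 2L)      # Ambulating, Sitting-on-chair
CHAIR_PREV <- 2L           # Sitting-on-chair

#' Score-function label assignment
#'
#' Sums the marginal probability vectors of all observations with
#' timestamps in `(t_prime - 1, t_prime]` and returns the argmax class.
#' Ties are broken to the previously assigned activity when it is among
#' the tied classes, otherwise to the lowest class index (hysteresis
#' against chatter at decision boundaries).
#'
#' @param marginal_history list with `t` (numeric vector of observation
#'   times) and `m` (matrix of marginals, rows aligned with `t`).
#' @param t_prime time of the observation being assigned.
#' @param prev previously assigned activity code or `NULL`.
#' @return activity code (integer).
#' @export
score_assign <- function(marginal_history, t_prime, prev = NULL) {
  sel <- marginal_history$t > t_prime - SCORE_WINDOW &
    marginal_history$t <= t_prime
  if (!any(sel)) stop("no marginals in the 1-s score window at t = ", t_prime)
  s <- colSums(marginal_history$m[sel, , drop = FALSE])
  top <- which(s >= max(s) - 1e-12)
  if (!is.null(prev) && prev %in% top) return(as.integer(prev))
  as.integer(min(top))
}

#' Initial recognizer state
#'
#' @return a `recognizer_state`: no assigned activity yet, no alerts.
#' @export
recognizer_state <- function() {
  structure(list(activity = NULL,
                 last_alert = c(bed = -Inf, chair = -Inf)),
            class = "recognizer_state")
}

#' One step of the exit-detection state machine
#'
#' Applies the transition rules to a newly assigned activity: a bed exit
#' fires when `Lying` or `Sitting-on-bed` is followed by `Ambulating` or
#' `Sitting-on-chair`; a chair exit fires when `Sitting-on-chair` is
#' followed by any other activity (bed-to-chair and chair-to-bed direct
#' transfers are covered, since transitions can be missed while
#' ambulating).  An alert whose kind fired within the last 1.75 s
#' (inclusive) is suppressed.  The first assignment of a stream never
#' alerts.  The state's current activity is updated unconditionally.
#'
#' @param state a `recognizer_state`.
#' @param new_label assigned activity code.
#' @param t timestamp of the triggering observation (seconds).
#' @param participant_id carried into emitted alerts.
#' @return `list(state = updated state, alerts = data.frame(t, kind,
#'   participant_id))` with zero or one row.
#' @export
fsm_step <- function(state, new_label, t, participant_id = NA_character_) {
  new_label <- as.integer(new_label)
  stopifnot(new_label %in% activity_labels())
  prev <- state$activity
  kind <- NULL
  if (!is.null(prev)) {
    if (prev %in% BED_PREV && new_label %in% BED_NEXT) kind <- "bed"
    else if (prev == CHAIR_PREV && new_label != CHAIR_PREV) kind <- "chair"
  }
  alerts <- data.frame(t = numeric(0), kind = character(0),
                       participant_id = character(0),
                       stringsAsFactors = FALSE)
  if (!is.null(kind)) {
    if (t - state$last_alert[[kind]] > SUPPRESSION_S) {
      alerts <- data.frame(t = t, kind = kind,
                           participant_id = participant_id,
                           stringsAsFactors = FALSE)
      state$last_alert[[kind]] <- t
    }
  }
  state$activity <- new_label
  list(state = state, alerts = alerts)
}

#' Run the full recognizer over a trial stream
#'
#' Pure streaming pipeline: per observation, causal feature extraction,
#' online marginal inference, score-function assignment and one FSM step.
#' No lookahead is used anywhere, so alerts carry the timestamp of the
#' observation that triggered them.
#'
#' @param model a fitted [crf_model()].
#' @param stream a time-sorted `sensor_stream`.
#' @param room a [room_config()].
#' @param use_score use the 1-s score function (default); `FALSE` assigns
#'   the raw per-observation marginal argmax instead (diagnostic baseline).
#' @return list with `labels` (data.frame `t`, `label`), `alerts`
#'   (data.frame `t`, `kind`, `participant_id`) and `marginals`
#'   (T x K matrix).
#' @export
recognize_stream <- function(model, stream, room, use_score = TRUE) {
  n <- nrow(stream)
  if (n == 0) {
    return(list(labels = data.frame(t = numeric(0), label = integer(0)),
                alerts = data.frame(t = numeric(0), kind = character(0),
                                    participant_id = character(0)),
                marginals = matrix(numeric(0), 0, n_classes())))
  }
  X <- featurize_trial(stream, room)
  m <- online_marginals(model, X)      # row t depends only on rows <= t
  pid <- as.character(stream$participant_id[1])
  state <- recognizer_state()
  labels <- integer(n)
  alerts <- vector("list", n)
  for (i in seq_len(n)) {
    lab <- if (use_score) {
      score_assign(list(t = stream$t[seq_len(i)],
                        m = m[seq_len(i), , drop = FALSE]),
                   stream$t[i], prev = state$activity)
    } else {
      max.col(m[i, , drop = FALSE], ties.method = "first")
    }
    step <- fsm_step(state, lab, stream$t[i], participant_id = pid)
    state <- step$state
    labels[i] <- lab
    if (nrow(step$alerts)) alerts[[i]] <- step$alerts
  }
  alerts <- do.call(rbind, alerts[!vapply(alerts, is.null, logical(1))])
  if (is.null(alerts)) {
    alerts <- data.frame(t = numeric(0), kind = character(0),
                         participant_id = character(0),
                         stringsAsFactors = FALSE)
  }
  list(labels = data.frame(t = stream$t, label = labels),
       alerts = alerts, marginals = m)
}
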