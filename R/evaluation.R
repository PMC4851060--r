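## Event-level alarm scoring.
##
## Ground-truth exits are derived from the annotation boundaries with the
## same transition rules the recognizer uses.  An alert is a true positive
## if (i) it occurs while the person is performing the post-exit activity
## (alert time inside the annotation interval that starts at the exit
## boundary), or (ii) the ground-truth exit occurs no more than T = 5 s
## after the alert (early alerts).  Matching is greedy earliest-first and
## one-to-one within each alert kind.  Matched-pair delays are signed
## (alert time minus boundary time; negative = early alert).

#' Ground-truth exit events from annotations
#'
#' Scans consecutive annotation intervals and emits a bed exit at every
#' boundary where `{Lying, Sitting-on-bed}` is followed by
#' `{Ambulating, Sitting-on-chair}` and a chair exit where
#' `Sitting-on-chair` is followed by any other label.  `end` is the end of
#' the post-transition interval (used by TP criterion (i)).
#'
#' @param annotations an `annotations` data.frame.
#' @return data.frame with columns `kind`, `t` (boundary time), `end`.
#' @export
extract_ground_truth_exits <- function(annotations) {
  n <- nrow(annotations)
  out <- data.frame(kind = character(0), t = numeric(0), end = numeric(0),
                    stringsAsFactors = FALSE)
  if (n < 2) return(out)
  prev <- annotations$label[-n]
  nxt <- annotations$label[-1]
  at <- annotations$start[-1]
  iend <- annotations$end[-1]
  bed <- prev %in% BED_PREV & nxt %in% BED_NEXT
  chair <- prev == CHAIR_PREV & nxt != CHAIR_PREV
  out <- rbind(
    data.frame(kind = rep("bed", sum(bed)), t = at[bed], end = iend[bed],
               stringsAsFactors = FALSE),
    data.frame(kind = rep("chair", sum(chair)), t = at[chair],
               end = iend[chair], stringsAsFactors = FALSE))
  out[order(out$t), , drop = FALSE]
}

#' Match alerts against ground-truth exits
#'
#' Greedy earliest-first one-to-one matching within each kind.  An alert
#' at time `a` qualifies for a truth at `g` (post-exit interval ending at
#' `e`) if `g <= a < e` (criterion i) or `g` lies in `(a, a + T]`
#' (criterion ii).  Unmatched alerts are false positives, unmatched truths
#' false negatives; each matched pair records the signed delay `a - g`.
#'
#' @param alerts data.frame with `t`, `kind` (time-sorted).
#' @param truths data.frame with `kind`, `t` and optionally `end`; when
#'   `end` is absent a 1.75-s post-boundary window (the minimum posture
#'   transition duration) is assumed.
#' @param T_tol tolerance T in seconds (default 5).
#' @return list per kind (`bed`, `chair`): `list(tp, fp, fn, delays)`.
#' @export
match_alerts <- function(alerts, truths, T_tol = 5) {
  if (is.null(truths$end)) truths$end <- truths$t + SUPPRESSION_S
  res <- list()
  for (kind in c("bed", "chair")) {
    a <- sort(alerts$t[alerts$kind == kind])
    tr <- truths[truths$kind == kind, , drop = FALSE]
    tr <- tr[order(tr$t), , drop = FALSE]
    matched <- rep(FALSE, nrow(tr))
    tp <- 0L; delays <- numeric(0)
    for (at in a) {
      ok <- !matched &
        ((tr$t <= at & at < tr$end) |                  # criterion (i)
           (tr$t > at & tr$t <= at + T_tol))           # criterion (ii)
      j <- which(ok)[1]
      if (!is.na(j)) {
        matched[j] <- TRUE
        tp <- tp + 1L
        delays <- c(delays, at - tr$t[j])
      }
    }
    res[[kind]] <- list(tp = tp, fp = length(a) - tp,
                        fn = sum(!matched), delays = delays)
  }
  res
}

#' Recall, precision and F-score from event counts
#'
#' `recall = TP/(TP+FN)`, `precision = TP/(TP+FP)`,
#' `F = 2*recall*precision/(recall+precision)`.  Ratios with a zero
#' denominator are returned as `NA` (undefined) and should be excluded
#' from fold averaging.
#'
#' @param tp,fp,fn nonnegative counts.
#' @return named numeric vector `recall`, `precision`, `f`.
#' @export
exit_metrics <- function(tp, fp, fn) {
  stopifnot(tp >= 0, fp >= 0, fn >= 0)
  recall <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
  precision <- if (tp + fp > 0) tp / (tp + fp) else NA_real_
  f <- if (!is.na(recall) && !is.na(precision) && recall + precision > 0) {
    2 * recall * precision / (recall + precision)
  } else NA_real_
  c(recall = recall, precision = precision, f = f)
}

#' Delay statistics
#'
#' Mean, standard deviation and median of matched-pair recognition delays
#' (seconds; negative values mean the alert preceded the annotated
#' boundary).  A single delay has SD 0; empty input gives `NA`s.
#'
#' @param delays numeric vector.
#' @return named numeric vector `mean`, `sd`, `median`.
#' @export
delay_stats <- function(delays) {
  if (!length(delays)) {
    return(c(mean = NA_real_, sd = NA_real_, median = NA_real_))
  }
  c(mean = mean(delays),
    sd = if (length(delays) == 1) 0 else sd(delays),
    median = median(delays))
}
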