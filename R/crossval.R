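## 10-fold cross-validation with a rotating 6/2/2 split.
##
## Trials are partitioned (seeded) into 10 subsets.  In rotation r the two
## subsets r, r+1 (mod 10) are the test set, r+2, r+3 the validation set
## (hyperparameter selection and dynamic weighting) and the remaining six
## the training set; over the 10 rotations every subset serves as test
## exactly twice.  Partitioning is by trial, not by observation, and is
## not participant-stratified (a participant's trials may appear on both
## sides of a split).

trial_sequences <- function(trials, room) {
  lapply(trials, function(tr) {
    X <- featurize_trial(tr$stream, room)
    list(X = X, y = label_at(tr$annotations, tr$stream$t), trial = tr)
  })
}

eval_trials <- function(model, seqs, room, use_score = TRUE, T_tol = 5) {
  counts <- list(bed = c(tp = 0L, fp = 0L, fn = 0L),
                 chair = c(tp = 0L, fp = 0L, fn = 0L))
  delays <- list(bed = numeric(0), chair = numeric(0))
  for (s in seqs) {
    rec <- recognize_stream(model, s$trial$stream, room,
                            use_score = use_score)
    truths <- extract_ground_truth_exits(s$trial$annotations)
    m <- match_alerts(rec$alerts, truths, T_tol = T_tol)
    for (kind in c("bed", "chair")) {
      counts[[kind]] <- counts[[kind]] +
        c(tp = m[[kind]]$tp, fp = m[[kind]]$fp, fn = m[[kind]]$fn)
      delays[[kind]] <- c(delays[[kind]], m[[kind]]$delays)
    }
  }
  list(counts = counts, delays = delays)
}

# scalar validation score for hyperparameter selection: mean of the
# defined bed/chair exit F-scores, falling back to the label-level macro F
val_score <- function(model, seqs, room) {
  ev <- eval_trials(model, seqs, room)
  fs <- c(exit_metrics(ev$counts$bed["tp"], ev$counts$bed["fp"],
                       ev$counts$bed["fn"])["f"],
          exit_metrics(ev$counts$chair["tp"], ev$counts$chair["fp"],
                       ev$counts$chair["fn"])["f"])
  if (all(is.na(fs))) {
    truth <- unlist(lapply(seqs, `[[`, "y"))
    pred <- unlist(lapply(seqs, function(s) predict_classes(model, s$X)))
    return(macro_f(truth, pred))
  }
  mean(fs, na.rm = TRUE)
}

#' Cross-validated exit-recognition evaluation
#'
#' Runs the full pipeline (feature extraction, dWCRF training with
#' hyperparameter selection on the validation subsets, streaming
#' recognition, event-level alarm scoring) under the rotating 6/2/2
#' 10-fold scheme and reports per-rotation and mean +/- SD recall /
#' precision / F-score per alert kind, plus pooled delay statistics.
#'
#' @param benchmark an `exit_benchmark` (or plain list of `sim_trial`s
#'   plus a `room` argument).
#' @param folds number of subsets (default 10; requires at least `folds`
#'   trials).
#' @param tau_grid,theta_grid hyperparameter grids searched by validation
#'   F-score.  Defaults bracket the operating points reported for the two
#'   room deployments.
#' @param seed integer seed controlling the fold partition.
#' @param room a [room_config()]; defaults to the benchmark's.
#' @param use_score use the 1-s score function in recognition.
#' @param verbose print per-rotation progress.
#' @return object of class `exit_cv`: `per_rotation` (data.frame),
#'   `summary` (mean/sd per kind and metric), `delays`, `delay_stats`,
#'   `fold_assignment` (manifest), `best_params` per rotation.
#' @export
crossval <- function(benchmark, folds = 10L,
                     tau_grid = c(0L, 1L, 2L, 4L, 8L),
                     theta_grid = c(1e-4, 3e-4, 1e-3, 1e-2, 1e-1),
                     seed = 1L, room = NULL, use_score = TRUE,
                     verbose = FALSE) {
  trials <- if (inherits(benchmark, "exit_benchmark")) benchmark$trials
            else benchmark
  if (is.null(room)) {
    if (!inherits(benchmark, "exit_benchmark")) {
      stop("room must be given when benchmark is a plain trial list")
    }
    room <- benchmark$room
  }
  n <- length(trials)
  if (n < folds) stop("need at least ", folds, " trials for ", folds,
                      "-fold cross-validation")
  set.seed(as.integer(seed))
  fold_of <- sample(rep_len(seq_len(folds), n))
  seqs <- trial_sequences(trials, room)

  rot_rows <- list(); best_params <- list()
  delays <- list(bed = numeric(0), chair = numeric(0))
  for (r in seq_len(folds)) {
    test_f <- ((r - 1):r %% folds) + 1L
    val_f <- ((r + 1):(r + 2) %% folds) + 1L
    train_f <- setdiff(seq_len(folds), c(test_f, val_f))
    tr_seqs <- seqs[fold_of %in% train_f]
    va_seqs <- seqs[fold_of %in% val_f]
    te_seqs <- seqs[fold_of %in% test_f]

    best <- NULL; best_v <- -Inf; best_hp <- c(NA, NA)
    for (th in theta_grid) {
      for (ta in tau_grid) {
        fit <- crf_fit(tr_seqs, va_seqs, tau = ta, theta = th,
                       seed = as.integer(seed) + r)
        v <- val_score(fit, va_seqs, room)
        if (is.na(v)) v <- -Inf
        if (v > best_v) {
          best_v <- v; best <- fit; best_hp <- c(tau = ta, theta = th)
        }
      }
    }
    ev <- eval_trials(best, te_seqs, room, use_score = use_score)
    row <- data.frame(rotation = r, tau = best_hp[["tau"]],
                      theta = best_hp[["theta"]])
    for (kind in c("bed", "chair")) {
      cnt <- ev$counts[[kind]]
      met <- exit_metrics(cnt[["tp"]], cnt[["fp"]], cnt[["fn"]])
      row[paste0(kind, "_", c("tp", "fp", "fn"))] <- as.list(cnt)
      row[paste0(kind, "_", names(met))] <- as.list(met)
      delays[[kind]] <- c(delays[[kind]], ev$delays[[kind]])
    }
    rot_rows[[r]] <- row
    best_params[[r]] <- best_hp
    if (verbose) {
      message(sprintf("rotation %d/%d: tau=%d theta=%g bedF=%.3f chairF=%.3f",
                      r, folds, best_hp[["tau"]], best_hp[["theta"]],
                      row$bed_f, row$chair_f))
    }
  }
  per_rotation <- do.call(rbind, rot_rows)
  metric_cols <- as.vector(outer(c("bed_", "chair_"),
                                 c("recall", "precision", "f"), paste0))
  summary <- data.frame(
    metric = metric_cols,
    mean = vapply(metric_cols,
                  function(cl) mean(per_rotation[[cl]], na.rm = TRUE),
                  numeric(1)),
    sd = vapply(metric_cols,
                function(cl) {
                  x <- per_rotation[[cl]][!is.na(per_rotation[[cl]])]
                  if (length(x) < 2) 0 else sd(x)
                }, numeric(1)),
    row.names = NULL)
  structure(list(per_rotation = per_rotation, summary = summary,
                 delays = delays,
                 delay_stats = lapply(delays, delay_stats),
                 fold_assignment = fold_of, seed = as.integer(seed),
                 best_params = best_params),
            class = "exit_cv")
}

#' @export
print.exit_cv <- function(x, ...) {
  cat("Exit-recognition cross-validation (", nrow(x$per_rotation),
      " rotations)\n", sep = "")
  s <- x$summary
  for (kind in c("bed", "chair")) {
    cat(sprintf("  %s exit:\n", kind))
    for (m in c("recall", "precision", "f")) {
      row <- s[s$metric == paste0(kind, "_", m), ]
      cat(sprintf("    %-9s %5.1f%% +/- %.1f\n", m,
                  100 * row$mean, 100 * row$sd))
    }
    d <- x$delay_stats[[kind]]
    cat(sprintf("    delay     %.2f +/- %.2f s (median %.2f s)\n",
                d[["mean"]], d[["sd"]], d[["median"]]))
  }
  invisible(x)
}
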