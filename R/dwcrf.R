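## Dynamically weighted linear-chain CRF.
##
## The objective maximized at fixed class weights w is the weighted
## per-position filtered log-likelihood
##   L(lambda, w) = sum_t w[y_t] * log p(y_t | x_{1..t}, lambda)
##                  - theta * ||lambda||^2,
## where p(y_t | x_{1..t}) is the same online (filtered) marginal the
## deployed recognizer uses, so training and inference share one
## factorization.  Training alternates this optimization with a dynamic
## re-weighting step that raises the weight of classes with poor
## validation F-score; tau caps the number of re-weighting rounds and
## tau = 0 reduces exactly to an unweighted CRF.

#' Construct a linear-chain CRF model object
#'
#' Low-level constructor used by [crf_fit()] and by tests; `unary` columns
#' must match `feature_schema` (plus an `(intercept)` column when
#' `intercept = TRUE`).
#'
#' @param unary K x P matrix of unary (state-feature) weights.
#' @param trans K x K matrix of transition weights
#'   (`trans[i, j]` scores a move from class `i` to class `j`).
#' @param feature_schema character vector of the P feature names `unary`
#'   expects (in order, including `(intercept)` if present).
#' @param class_weights positive length-K class weights `w`.
#' @param tau,theta hyperparameters: re-weighting rounds (nonnegative
#'   integer) and L2 regularization coefficient (nonnegative).
#' @param scaler `NULL` or `list(center, scale)` applied to raw features
#'   before scoring.
#' @param intercept logical; whether a constant-1 column is appended after
#'   scaling.
#' @param seed integer used during fitting.
#' @return object of class `crf_model`.
#' @export
crf_model <- function(unary, trans, feature_schema = colnames(unary),
                      class_weights = rep(1, n_classes()),
                      tau = 0L, theta = 0, scaler = NULL,
                      intercept = FALSE, seed = NA_integer_) {
  K <- n_classes()
  unary <- as.matrix(unary); trans <- as.matrix(trans)
  stopifnot(nrow(unary) == K, nrow(trans) == K, ncol(trans) == K,
            length(class_weights) == K)
  if (any(class_weights <= 0)) stop("class weights must be strictly positive")
  if (!all(is.finite(unary)) || !all(is.finite(trans))) {
    stop("model parameters must be finite")
  }
  if (is.null(feature_schema)) feature_schema <- paste0("f", seq_len(ncol(unary)))
  colnames(unary) <- feature_schema
  structure(list(unary = unary, trans = trans,
                 feature_schema = feature_schema,
                 class_weights = as.numeric(class_weights),
                 tau = as.integer(tau), theta = as.numeric(theta),
                 scaler = scaler, intercept = isTRUE(intercept),
                 seed = seed),
            class = "crf_model")
}

#' @export
print.crf_model <- function(x, ...) {
  cat("Linear-chain CRF (", ncol(x$unary), " features, K = ",
      nrow(x$unary), " classes)\n", sep = "")
  cat("  tau =", x$tau, " theta =", x$theta, "\n")
  cat("  class weights:", signif(x$class_weights, 4), "\n")
  invisible(x)
}

# apply scaler + intercept to a raw feature matrix, check schema
prepare_features <- function(model, X) {
  X <- as.matrix(X)
  raw_schema <- setdiff(model$feature_schema, "(intercept)")
  if (!is.null(colnames(X))) {
    if (!all(raw_schema %in% colnames(X))) {
      stop("feature matrix does not carry the model's schema; missing: ",
           paste(utils::head(setdiff(raw_schema, colnames(X)), 5),
                 collapse = ", "))
    }
    X <- X[, raw_schema, drop = FALSE]
  } else if (ncol(X) != length(raw_schema)) {
    stop("feature matrix has ", ncol(X), " columns; model expects ",
         length(raw_schema))
  }
  if (!is.null(model$scaler)) {
    X <- sweep(X, 2, model$scaler$center, "-")
    X <- sweep(X, 2, model$scaler$scale, "/")
  }
  if (model$intercept) X <- cbind(X, `(intercept)` = 1)
  X
}

#' Online (filtered) marginal probabilities
#'
#' Exact filtered distribution `p(y_t | x_{1..t})` for every position of a
#' sequence, via the forward sum-product recursion in log space (O(K^2)
#' per observation).  Because the recursion is causal, row `t` is
#' invariant to any observation after `t`.
#'
#' @param model a [crf_model()].
#' @param X feature matrix (rows = observations).  Raw features; the
#'   model's scaler/intercept are applied internally.
#' @return T x K matrix of probabilities; each row sums to 1.
#' @export
online_marginals <- function(model, X) {
  Xp <- prepare_features(model, X)
  logU <- Xp %*% t(model$unary)
  lm <- .crf_filter_cpp(logU, model$trans)
  m <- exp(lm)
  colnames(m) <- names(activity_labels())
  m
}

#' Per-position class prediction
#'
#' Argmax of the filtered marginals (ties to the lowest class index).
#' @inheritParams online_marginals
#' @return integer vector of activity codes.
#' @export
predict_classes <- function(model, X) {
  m <- online_marginals(model, X)
  max.col(m, ties.method = "first")
}

#' Weighted log-likelihood and exact gradient
#'
#' Evaluates the objective
#' \deqn{L(\lambda, w) = \sum_t w_{y_t} \log p(y_t | x_{1..t}, \lambda)
#'   - \vartheta \|\lambda\|^2}
#' for one or more labeled sequences and its exact
#' gradient with respect to all unary and transition weights (reverse-mode
#' differentiation through the forward recursion).
#'
#' @param model a [crf_model()]; its `theta` supplies the regularizer.
#' @param sequences one sequence `list(X = , y = )` or a list of such
#'   sequences.  `X` rows must match `y` length; features are passed
#'   through the model's scaler.
#' @param w positive class weights (default the model's).
#' @return `list(value = scalar, grad_unary = K x P, grad_trans = K x K)`.
#' @export
weighted_loglik_grad <- function(model, sequences, w = model$class_weights) {
  if (!is.null(sequences$X)) sequences <- list(sequences)
  if (length(w) != n_classes() || any(w <= 0)) {
    stop("w must be ", n_classes(), " positive class weights")
  }
  value <- 0
  gU <- matrix(0, nrow(model$unary), ncol(model$unary))
  gT <- matrix(0, n_classes(), n_classes())
  for (s in sequences) {
    Xp <- prepare_features(model, s$X)
    if (nrow(Xp) != length(s$y)) stop("sequence X/y length mismatch")
    logU <- Xp %*% t(model$unary)
    core <- .crf_wll_core_cpp(logU, model$trans, as.integer(s$y),
                              as.numeric(w))
    value <- value + core$value
    gU <- gU + crossprod(core$delta, Xp)
    gT <- gT + core$grad_trans
  }
  th <- model$theta
  value <- value - th * (sum(model$unary^2) + sum(model$trans^2))
  list(value = value,
       grad_unary = gU - 2 * th * model$unary,
       grad_trans = gT - 2 * th * model$trans)
}

# macro-averaged one-vs-rest F-score of per-position predictions;
# classes absent from truth give NA and are skipped in the macro mean
per_class_f <- function(truth, pred) {
  K <- n_classes()
  vapply(seq_len(K), function(k) {
    tp <- sum(pred == k & truth == k)
    fp <- sum(pred == k & truth != k)
    fn <- sum(pred != k & truth == k)
    if (tp + fn == 0) return(NA_real_)       # class absent
    if (2 * tp + fp + fn == 0) return(0)
    2 * tp / (2 * tp + fp + fn)
  }, numeric(1))
}

macro_f <- function(truth, pred) {
  f <- per_class_f(truth, pred)
  if (all(is.na(f))) return(NA_real_)
  mean(f, na.rm = TRUE)
}

#' Dynamic class-weight proposal
#'
#' Proposes new class weights from per-class validation F-scores:
#' `w_c` proportional to `1 + alpha * (1 - F_c)`, mean-normalized to 1, so
#' classes the model currently serves badly get a larger say in the next
#' optimization round.  Classes absent from the validation data keep raw
#' weight 1 (with a warning).  [crf_fit()] applies a monotone-acceptance
#' rule on top: a proposal is kept only if it does not decrease the
#' validation macro F-score.
#'
#' @param model a fitted or in-training [crf_model()].
#' @param val_seqs list of validation sequences `list(X, y)`.
#' @param state optional list with `weights` (current weights, used as the
#'   fallback) — the iteration state carried by [crf_fit()].
#' @param alpha weighting strength (default 1).
#' @return list with `weights` (proposed, mean 1), `f_scores` (per class),
#'   `macro_f`.
#' @export
compute_class_weights <- function(model, val_seqs, state = NULL, alpha = 1) {
  truth <- unlist(lapply(val_seqs, `[[`, "y"))
  pred <- unlist(lapply(val_seqs, function(s) predict_classes(model, s$X)))
  f <- per_class_f(truth, pred)
  if (any(is.na(f))) {
    warning("class(es) absent from validation data: ",
            paste(activity_name(which(is.na(f))), collapse = ", "),
            "; their weights held at 1")
  }
  raw <- ifelse(is.na(f), 1, 1 + alpha * (1 - f))
  w <- raw / mean(raw)
  list(weights = w, f_scores = f, macro_f = macro_f(truth, pred))
}

# Maximize the fixed-w objective by L-BFGS from a given start.
#
# Features arrive already scaled with the intercept appended (prepared
# once, not per evaluation).  The optimizer works on the per-position
# mean of the objective so the gradient tolerance (1e-5) is independent
# of dataset size; value and gradient are computed in one pass and
# memoized because optim asks for them separately.
optimize_lambda <- function(start_unary, start_trans, Xp_list, y_list, w,
                            theta, schema, pgtol = 1e-5, maxit = 500L) {
  K <- n_classes(); P <- ncol(start_unary)
  N <- sum(vapply(y_list, length, integer(1)))
  pack <- function(u, tr) c(as.numeric(u), as.numeric(tr))
  unpack <- function(par) {
    list(u = matrix(par[seq_len(K * P)], K, P,
                    dimnames = list(NULL, schema)),
         tr = matrix(par[K * P + seq_len(K * K)], K, K))
  }
  cache <- new.env(parent = emptyenv())
  evaluate <- function(par) {
    if (!is.null(cache$par) && identical(par, cache$par)) return(cache$res)
    p <- unpack(par)
    value <- 0
    gU <- matrix(0, K, P); gT <- matrix(0, K, K)
    for (i in seq_along(Xp_list)) {
      logU <- Xp_list[[i]] %*% t(p$u)
      core <- .crf_wll_core_cpp(logU, p$tr, y_list[[i]], w)
      value <- value + core$value
      gU <- gU + crossprod(core$delta, Xp_list[[i]])
      gT <- gT + core$grad_trans
    }
    value <- (value - theta * (sum(p$u^2) + sum(p$tr^2))) / N
    if (!is.finite(value)) {
      stop("non-finite CRF objective (theta = ", theta,
           "); check features for non-finite values")
    }
    res <- list(value = value,
                grad = pack(gU - 2 * theta * p$u,
                            gT - 2 * theta * p$tr) / N)
    cache$par <- par; cache$res <- res
    res
  }
  res <- optim(pack(start_unary, start_trans),
               fn = function(par) evaluate(par)$value,
               gr = function(par) evaluate(par)$grad,
               method = "L-BFGS-B",
               control = list(fnscale = -1, pgtol = pgtol, maxit = maxit))
  p <- unpack(res$par)
  list(unary = p$u, trans = p$tr, value = res$value,
       convergence = res$convergence, counts = res$counts)
}

#' Fit a dynamically weighted CRF
#'
#' Alternates (a) L-BFGS maximization of the weighted objective at fixed
#' class weights and (b) a dynamic re-weighting step driven by per-class
#' validation F-scores, for `tau` rounds after the initial unweighted
#' round.  A re-weighting proposal is kept only if the refitted model does
#' not decrease the validation macro F-score (monotone acceptance); the
#' returned model is the one with the best validation macro F-score seen.
#' `tau = 0` is exactly an unweighted CRF fit.  Deterministic: parameters
#' start at zero and data order is as given.
#'
#' @param train_seqs list of training sequences `list(X, y)` with raw
#'   (unscaled) feature matrices sharing column names.
#' @param val_seqs validation sequences used for the weight updates and
#'   model selection; defaults to `train_seqs` when absent.
#' @param tau number of re-weighting rounds (>= 0).
#' @param theta L2 regularization coefficient (>= 0).
#' @param seed integer seed (recorded; the fit itself is deterministic).
#' @param alpha re-weighting strength, see [compute_class_weights()].
#' @param standardize z-score features using training statistics (default
#'   TRUE; recommended — the schema mixes g, dBm, radians and seconds).
#' @param verbose print per-round progress to stderr.
#' @return a fitted [crf_model()]; attribute `"trace"` holds per-round
#'   weights, objective values and validation macro F-scores.
#' @export
crf_fit <- function(train_seqs, val_seqs = NULL, tau = 0L, theta = 1e-3,
                    seed = 1L, alpha = 1, standardize = TRUE,
                    verbose = FALSE) {
  if (!length(train_seqs)) stop("empty training set")
  if (!is.null(train_seqs$X)) train_seqs <- list(train_seqs)
  if (is.null(val_seqs)) val_seqs <- train_seqs
  if (!is.null(val_seqs$X)) val_seqs <- list(val_seqs)
  schema_raw <- colnames(train_seqs[[1]]$X)
  if (is.null(schema_raw)) {
    schema_raw <- paste0("f", seq_len(ncol(train_seqs[[1]]$X)))
    train_seqs <- lapply(train_seqs, function(s) {
      colnames(s$X) <- schema_raw; s })
    val_seqs <- lapply(val_seqs, function(s) {
      colnames(s$X) <- schema_raw; s })
  }
  scaler <- NULL
  if (standardize) {
    Xall <- do.call(rbind, lapply(train_seqs, `[[`, "X"))
    ctr <- colMeans(Xall)
    scl <- apply(Xall, 2, sd)
    scl[!is.finite(scl) | scl < 1e-8] <- 1
    scaler <- list(center = ctr, scale = scl)
  }
  schema <- c(schema_raw, "(intercept)")
  K <- n_classes(); P <- length(schema)
  set.seed(as.integer(seed))              # API contract; fit is deterministic

  w <- rep(1, K)
  unary <- matrix(0, K, P); trans <- matrix(0, K, K)
  trace <- list()
  best <- NULL; best_f <- -Inf; prev_f <- -Inf
  accepted_w <- w

  shell <- crf_model(unary, trans, feature_schema = schema, theta = theta,
                     scaler = scaler, intercept = TRUE)
  Xp_list <- lapply(train_seqs, function(s) prepare_features(shell, s$X))
  y_list <- lapply(train_seqs, function(s) as.integer(s$y))

  for (round in 0:max(0L, as.integer(tau))) {
    opt <- optimize_lambda(unary, trans, Xp_list, y_list, w, theta, schema)
    unary <- opt$unary; trans <- opt$trans
    model <- crf_model(unary, trans, feature_schema = schema,
                       class_weights = w, tau = as.integer(tau),
                       theta = theta, scaler = scaler, intercept = TRUE,
                       seed = as.integer(seed))
    cw <- compute_class_weights(model, val_seqs, alpha = alpha)
    trace[[round + 1]] <- list(round = round, weights = w,
                               objective = opt$value,
                               val_macro_f = cw$macro_f,
                               f_scores = cw$f_scores)
    if (verbose) {
      message(sprintf("round %d: objective %.4f, val macro-F %.4f",
                      round, opt$value, cw$macro_f))
    }
    if (is.na(cw$macro_f)) cw$macro_f <- -Inf
    if (cw$macro_f >= best_f) {
      best <- model; best_f <- cw$macro_f
    }
    if (round < tau) {
      if (cw$macro_f >= prev_f) {         # monotone acceptance
        accepted_w <- cw$weights
        prev_f <- cw$macro_f
      }
      w <- accepted_w
    }
  }
  attr(best, "trace") <- trace
  best
}

#' Serialize / restore a CRF model as JSON
#'
#' Versioned plain-text serialization of all parameters, hyperparameters
#' and the feature scaler.
#' @param model a [crf_model()].
#' @param path output (input) file path.
#' @return `write_crf_model` returns `path` invisibly; `read_crf_model`
#'   the restored model.
#' @export
write_crf_model <- function(model, path) {
  obj <- list(format = "rfidexit-crf", version = 1L,
              feature_schema = model$feature_schema,
              unary = model$unary, trans = model$trans,
              class_weights = model$class_weights,
              tau = model$tau, theta = model$theta,
              intercept = model$intercept, seed = model$seed,
              scaler = model$scaler)
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE,
                       matrix = "rowmajor")
  invisible(path)
}

#' @rdname write_crf_model
#' @export
read_crf_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(obj$format, "rfidexit-crf")) {
    stop("not an rfidexit CRF model file: ", path)
  }
  scaler <- obj$scaler
  if (!is.null(scaler) && length(scaler$center)) {
    raw_schema <- setdiff(obj$feature_schema, "(intercept)")
    scaler <- list(center = setNames(as.numeric(scaler$center), raw_schema),
                   scale = setNames(as.numeric(scaler$scale), raw_schema))
  }
  crf_model(obj$unary, obj$trans, feature_schema = obj$feature_schema,
            class_weights = obj$class_weights, tau = obj$tau,
            theta = obj$theta, scaler = scaler, intercept = obj$intercept,
            seed = obj$seed)
}
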