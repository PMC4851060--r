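# Shared fixture builders. Everything is generated in code; no stored data.

lab <- activity_labels()

# minimal hand-built stream data.frame (Room 2 antennas by default)
fix_stream <- function(t, antenna_id = "antenna1", a_v = 1, a_l = 0,
                       a_f = 0, rssi = -60, phase = 0, channel = 1L,
                       gender = 0L, participant_id = "p01") {
  n <- length(t)
  data.frame(t = t,
             a_v = rep_len(a_v, n), a_l = rep_len(a_l, n),
             a_f = rep_len(a_f, n),
             rssi = rep_len(rssi, n),
             antenna_id = rep_len(antenna_id, n),
             phase = rep_len(phase, n), channel = rep_len(channel, n),
             participant_id = rep_len(participant_id, n),
             gender = rep_len(gender, n), stringsAsFactors = FALSE)
}

write_stream_file <- function(df) {
  path <- tempfile(fileext = ".csv")
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  path
}

# random small CRF model (no scaler/intercept) for inference tests
rand_model <- function(P = 3, scale = 1, theta = 0) {
  crf_model(matrix(rnorm(4 * P, sd = scale), 4, P),
            matrix(rnorm(16, sd = scale), 4, 4), theta = theta)
}

# brute-force filtered marginals p(y_t | x_{1..t}) by explicit enumeration
# of all K^t label paths (the independent oracle for the forward recursion)
brute_filter <- function(logU, trans) {
  T_ <- nrow(logU); K <- ncol(logU)
  out <- matrix(NA_real_, T_, K)
  for (t in seq_len(T_)) {
    paths <- as.matrix(expand.grid(rep(list(seq_len(K)), t)))
    sc <- apply(paths, 1, function(p) {
      s <- sum(logU[cbind(seq_len(t), p)])
      if (t > 1) s <- s + sum(trans[cbind(p[-t], p[-1])])
      s
    })
    w <- exp(sc - max(sc))
    for (k in seq_len(K)) out[t, k] <- sum(w[paths[, t] == k]) / sum(w)
  }
  out
}

# easily separable synthetic labeled sequences: class-specific feature
# means far apart, so a CRF should reach ~perfect per-position accuracy
separable_seqs <- function(n_seq, T_ = 40, gap = 5, sd = 0.3,
                           classes = 1:4, seed = 1) {
  set.seed(seed)
  mu <- diag(gap, 4)[, seq_len(3), drop = FALSE]  # 3 features
  lapply(seq_len(n_seq), function(i) {
    # blocked labels cycling through the classes so every sequence covers
    # all of them (block order shuffled)
    n_blocks <- max(length(classes), ceiling(T_ / 10))
    y <- rep(sample(rep_len(classes, n_blocks)),
             each = ceiling(T_ / n_blocks))
    y <- y[seq_len(T_)]
    X <- mu[y, , drop = FALSE] + matrix(rnorm(T_ * 3, sd = sd), T_, 3)
    colnames(X) <- paste0("f", 1:3)
    list(X = X, y = y)
  })
}

# independent unweighted-CRF trainer: L-BFGS on the mean w=1 objective,
# written from scratch against the public weighted_loglik_grad() interface
# (the oracle for the tau = 0 degenerate-weight equivalence)
plain_crf_train <- function(seqs, theta, P_raw = 3) {
  K <- 4; P <- P_raw + 1
  schema <- c(paste0("f", seq_len(P_raw)), "(intercept)")
  N <- sum(vapply(seqs, function(s) length(s$y), integer(1)))
  shell <- function(par) {
    crf_model(matrix(par[1:(K * P)], K, P, dimnames = list(NULL, schema)),
              matrix(par[K * P + 1:(K * K)], K, K),
              theta = theta, intercept = TRUE)
  }
  fn <- function(par) {
    weighted_loglik_grad(shell(par), seqs, w = rep(1, 4))$value / N
  }
  gr <- function(par) {
    g <- weighted_loglik_grad(shell(par), seqs, w = rep(1, 4))
    c(as.numeric(g$grad_unary), as.numeric(g$grad_trans)) / N
  }
  res <- optim(rep(0, K * P + K * K), fn, gr, method = "L-BFGS-B",
               control = list(fnscale = -1, pgtol = 1e-5, maxit = 500))
  list(unary = matrix(res$par[1:(K * P)], K, P),
       trans = matrix(res$par[K * P + 1:(K * K)], K, K),
       counts = res$counts)
}

# imbalanced 2-class-dominant chains with a rare Ambulating-like class and
# overlapping features, for the weighting tests
imbalanced_seqs <- function(n_seq, T_ = 120, minority_frac = 0.03,
                            sep = 1.2, sd = 1, seed = 1) {
  set.seed(seed)
  mu <- rbind(c(sep, 0, 0), c(0, sep, 0), c(0, 0, sep), c(sep / 2, sep / 2, 0))
  lapply(seq_len(n_seq), function(i) {
    n_min <- max(1, round(T_ * minority_frac))
    y <- c(rep(3L, round(T_ * 0.55)), rep(1L, round(T_ * 0.3)))
    y <- c(y, rep(2L, T_ - length(y) - n_min), rep(4L, n_min))
    X <- mu[y, , drop = FALSE] + matrix(rnorm(length(y) * 3, sd = sd),
                                        length(y), 3)
    colnames(X) <- paste0("f", 1:3)
    list(X = X, y = y)
  })
}
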