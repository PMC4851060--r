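test_that("online_marginals matches the brute-force enumeration oracle", {
  set.seed(101)
  for (i in 1:10) {
    T_ <- sample(2:6, 1)
    m <- rand_model(P = 3)
    X <- matrix(rnorm(T_ * 3), T_, 3)
    got <- online_marginals(m, X)
    want <- brute_filter(X %*% t(m$unary), m$trans)
    expect_lt(max(abs(got - want)), 1e-9)
    expect_equal(unname(rowSums(got)), rep(1, T_), tolerance = 1e-9)
  }
})

test_that("marginal base cases: zero weights uniform; t = 1 is a softmax", {
  X <- matrix(rnorm(12), 4, 3)
  m0 <- crf_model(matrix(0, 4, 3), matrix(0, 4, 4))
  expect_equal(unname(online_marginals(m0, X)),
               matrix(0.25, 4, 4), tolerance = 1e-12)

  m <- rand_model(P = 3)
  u1 <- as.numeric(m$unary %*% X[1, ])
  expect_equal(unname(online_marginals(m, X)[1, ]),
               exp(u1) / sum(exp(u1)), tolerance = 1e-12)
})

test_that("filtering property: marginals at t ignore later observations", {
  set.seed(33)
  m <- rand_model(P = 4)
  X <- matrix(rnorm(40), 10, 4)
  full <- online_marginals(m, X)
  X2 <- X; X2[8:10, ] <- rnorm(12, sd = 5)    # perturb the future
  expect_equal(online_marginals(m, X2)[1:7, ], full[1:7, ])
})

test_that("log-space recursion stays finite where direct space overflows", {
  m <- crf_model(matrix(c(800, -800, 400, -400), 4, 1), matrix(0, 4, 4))
  X <- matrix(1, 6, 1)
  got <- online_marginals(m, X)
  expect_true(all(is.finite(got)))
  expect_equal(unname(rowSums(got)), rep(1, 6), tolerance = 1e-9)
  expect_gt(got[6, 1], 0.999)                 # score 800 dominates
})

test_that("weighted_loglik_grad matches central finite differences", {
  set.seed(202)
  T_ <- 5; P <- 3
  X <- matrix(rnorm(T_ * P), T_, P)
  y <- sample(1:4, T_, replace = TRUE)
  w <- runif(4, 0.5, 2)
  unary <- matrix(rnorm(4 * P), 4, P)
  trans <- matrix(rnorm(16), 4, 4)
  theta <- 0.05
  g <- weighted_loglik_grad(crf_model(unary, trans, theta = theta),
                            list(X = X, y = y), w = w)
  eps <- 1e-6
  val <- function(u, tr) {
    weighted_loglik_grad(crf_model(u, tr, theta = theta),
                         list(X = X, y = y), w = w)$value
  }
  for (idx in sample(length(unary), 6)) {
    up <- um <- unary; up[idx] <- up[idx] + eps; um[idx] <- um[idx] - eps
    expect_lt(abs((val(up, trans) - val(um, trans)) / (2 * eps) -
                    g$grad_unary[idx]), 1e-5)
  }
  for (idx in sample(16, 6)) {
    up <- um <- trans; up[idx] <- up[idx] + eps; um[idx] <- um[idx] - eps
    expect_lt(abs((val(unary, up) - val(unary, um)) / (2 * eps) -
                    g$grad_trans[idx]), 1e-5)
  }
})

test_that("weighted objective is linear in w and reduces to unweighted", {
  set.seed(203)
  m <- rand_model(P = 3, theta = 0.1)
  seqs <- list(list(X = matrix(rnorm(18), 6, 3), y = sample(1:4, 6, TRUE)))
  v1 <- weighted_loglik_grad(m, seqs, w = rep(1, 4))
  v2 <- weighted_loglik_grad(m, seqs, w = rep(2, 4))
  reg <- m$theta * (sum(m$unary^2) + sum(m$trans^2))
  expect_equal(v2$value + reg, 2 * (v1$value + reg), tolerance = 1e-10)

  # w = 1: value equals the sum of filtered per-position log-probabilities
  lm <- log(online_marginals(m, seqs[[1]]$X))
  expect_equal(v1$value, sum(lm[cbind(1:6, seqs[[1]]$y)]) - reg,
               tolerance = 1e-10)

  expect_error(weighted_loglik_grad(m, seqs, w = c(1, 1)), "positive")
  bad <- list(list(X = matrix(0, 3, 5), y = c(1L, 2L, 3L)))
  expect_error(weighted_loglik_grad(m, bad), "expects")
})

test_that("compute_class_weights follows the inverse-F rule", {
  # perfectly classified data keeps weights at (1,1,1,1)
  seqs <- separable_seqs(4, T_ = 40, gap = 6, sd = 0.2, seed = 5)
  fit <- crf_fit(seqs, tau = 0, theta = 1e-3)
  cw <- compute_class_weights(fit, seqs)
  expect_equal(cw$weights, rep(1, 4), tolerance = 1e-8)
  expect_equal(cw$macro_f, 1)

  # one class with F = 0 gets the strictly largest weight: force it by
  # handing a model a validation set whose class-4 features mimic class 1
  seqs2 <- separable_seqs(2, T_ = 40, gap = 6, sd = 0.2, classes = 1:3,
                          seed = 6)
  seqs2 <- lapply(seqs2, function(s) { s$y[1:10] <- 4L; s })
  cw2 <- compute_class_weights(fit, seqs2)
  expect_equal(which.max(cw2$weights), 4L)
  expect_true(all(cw2$weights[4] > cw2$weights[1:3]))
  expect_equal(mean(cw2$weights), 1)

  # class absent from validation data: weight held, warning raised
  expect_warning(
    cw3 <- compute_class_weights(fit, separable_seqs(2, classes = 1:2,
                                                     seed = 7)),
    "absent")
  expect_true(all(cw3$weights > 0))
})

test_that("tau = 0 fit reproduces a from-scratch unweighted CRF trainer", {
  seqs <- separable_seqs(3, T_ = 30, gap = 4, sd = 0.5, seed = 11)
  fit <- crf_fit(seqs, tau = 0, theta = 0.1, seed = 42, standardize = FALSE)

  res <- plain_crf_train(seqs, theta = 0.1)
  expect_equal(unname(fit$unary), res$unary, tolerance = 1e-8)
  expect_equal(fit$trans, res$trans, tolerance = 1e-8)
  expect_equal(fit$class_weights, rep(1, 4))
})

test_that("fit reaches ~perfect accuracy on separable chains", {
  seqs <- separable_seqs(4, T_ = 50, gap = 5, sd = 0.3, classes = c(1, 3),
                         seed = 21)
  fit <- suppressWarnings(crf_fit(seqs, tau = 0, theta = 1e-3))
  acc <- mean(unlist(lapply(seqs, function(s) {
    predict_classes(fit, s$X) == s$y
  })))
  expect_gte(acc, 0.99)
})

test_that("dynamic weighting does not hurt, and helps the minority class", {
  # paired comparison over seeds; medians compared (heavier seeds vary)
  f_min <- matrix(NA_real_, 6, 2)
  for (i in 1:6) {
    train <- imbalanced_seqs(6, T_ = 100, seed = 100 + i)
    val <- imbalanced_seqs(2, T_ = 100, seed = 200 + i)
    test <- imbalanced_seqs(2, T_ = 100, seed = 300 + i)
    for (j in 1:2) {
      tau <- c(0L, 4L)[j]
      fit <- crf_fit(train, val, tau = tau, theta = 1e-3)
      truth <- unlist(lapply(test, `[[`, "y"))
      pred <- unlist(lapply(test, function(s) predict_classes(fit, s$X)))
      tp <- sum(pred == 4 & truth == 4)
      f_min[i, j] <- 2 * tp / (2 * tp + sum(pred == 4 & truth != 4) +
                                 sum(pred != 4 & truth == 4))
    }
  }
  expect_gte(median(f_min[, 2]), median(f_min[, 1]))
})

test_that("transition weights are recovered from model-generated data", {
  # correctly-specified recovery experiment: labels drawn from the model's
  # own filtered per-position conditionals at a known lambda*; the
  # identifiable part of the transition matrix is its column-centered form
  # (a column shift is absorbable by class intercepts)
  set.seed(78)
  K <- 4; P <- 3
  unary_t <- matrix(rnorm(K * P), K, P)
  trans_t <- matrix(rnorm(16, sd = 1.5), K, K)
  true_m <- crf_model(unary_t, trans_t)
  seqs <- lapply(1:200, function(i) {
    X <- matrix(rnorm(50 * P), 50, P)
    colnames(X) <- paste0("f", 1:P)
    M <- online_marginals(true_m, X)
    list(X = X, y = apply(M, 1, function(p) sample(1:4, 1, prob = p)))
  })
  fit <- suppressWarnings(crf_fit(seqs, tau = 0, theta = 1e-4,
                                  standardize = FALSE))
  cc <- function(M) sweep(M, 2, colMeans(M))
  rho <- cor(as.numeric(cc(trans_t)), as.numeric(cc(fit$trans)),
             method = "spearman")
  expect_gt(rho, 0.8)
})

test_that("model JSON serialization round-trips", {
  seqs <- separable_seqs(2, T_ = 30, seed = 31)
  fit <- crf_fit(seqs, tau = 1, theta = 1e-2)
  path <- tempfile(fileext = ".json")
  write_crf_model(fit, path)
  back <- read_crf_model(path)
  expect_equal(back$unary, fit$unary)
  expect_equal(back$trans, fit$trans)
  expect_equal(back$scaler$center, fit$scaler$center)
  X <- seqs[[1]]$X
  expect_equal(online_marginals(back, X), online_marginals(fit, X))
})
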