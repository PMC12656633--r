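make_pls_problem <- function(n, p, k_true = 3, noise = 0, xnoise = 0,
                             seed = 1) {
  set.seed(seed)
  scores <- matrix(rnorm(n * k_true), n, k_true)
  load <- matrix(rnorm(p * k_true), k_true, p)
  X <- scores %*% load + matrix(rnorm(n * p, 0, xnoise), n, p)
  y <- drop(scores %*% rnorm(k_true)) + rnorm(n, 0, noise)
  list(X = X, y = y)
}

test_that("one exact latent factor is recovered perfectly", {
  set.seed(3)
  t <- rnorm(12)
  p <- rnorm(30)
  X <- tcrossprod(t, p)
  y <- 2.5 * t
  m <- fit_pls(X, y, 1)
  yhat <- predict(m, X)
  expect_lt(max(abs(yhat - y)), 1e-10)
  expect_equal(cor(y, yhat), 1, tolerance = 1e-12)
})

test_that("PLS with full factor count equals OLS on centered data", {
  prob <- make_pls_problem(20, 6, k_true = 6, noise = 0.3, seed = 4)
  m <- fit_pls(prob$X, prob$y, k = 6)
  ols <- lm(prob$y ~ prob$X)
  expect_lt(max(abs(predict(m, prob$X) - fitted(ols))), 1e-8)
})

test_that("NIPALS agrees with an independent PLS implementation", {
  skip_if_not_installed("mixOmics")
  prob <- make_pls_problem(20, 50, k_true = 5, noise = 0.1, seed = 5)
  colnames(prob$X) <- paste0("v", seq_len(50))
  m <- fit_pls(prob$X, prob$y, 4)
  ref <- mixOmics::pls(prob$X, prob$y, ncomp = 4, scale = FALSE,
                       mode = "regression")
  # compare on held-out random spectra: pins down the full regression vector
  set.seed(6)
  Xnew <- matrix(rnorm(10 * 50), 10, 50,
                 dimnames = list(NULL, colnames(prob$X)))
  ours <- predict(m, Xnew)
  theirs <- predict(ref, Xnew)$predict[, 1, 4]
  expect_lt(max(abs(ours - theirs)) / max(abs(theirs)), 1e-8)
})

test_that("model structure invariants hold", {
  prob <- make_pls_problem(25, 40, k_true = 4, noise = 0.2, xnoise = 0.02,
                           seed = 7)
  m <- fit_pls(prob$X, prob$y, 5)
  # score vectors pairwise orthogonal
  G <- crossprod(m$scores)
  offdiag <- G - diag(diag(G))
  expect_lt(max(abs(offdiag)) / max(diag(G)), 1e-8)
  # collapsed b reproduces sequential factor-space prediction
  Xc <- sweep(prob$X, 2, m$x_mean)
  yhat_seq <- m$y_mean + rep(0, 25)
  Xd <- Xc
  for (a in 1:5) {
    t <- drop(Xd %*% m$W[, a])
    yhat_seq <- yhat_seq + m$q[a] * t
    Xd <- Xd - tcrossprod(t, m$P[, a])
  }
  expect_lt(max(abs(predict(m, prob$X) - yhat_seq)), 1e-10)
  # deflation shrinks X in Frobenius norm at every factor
  Xd <- sweep(prob$X, 2, m$x_mean)
  norms <- numeric(6)
  norms[1] <- sum(Xd^2)
  for (a in 1:5) {
    t <- drop(Xd %*% m$W[, a])
    Xd <- Xd - tcrossprod(t, m$P[, a])
    norms[a + 1] <- sum(Xd^2)
  }
  expect_true(all(diff(norms) <= 1e-10))
})

test_that("predict respects centering, linearity and grid checks", {
  prob <- make_pls_problem(15, 20, seed = 8, noise = 0.1)
  m <- fit_pls(prob$X, prob$y, 3)
  expect_equal(predict(m, m$x_mean), m$y_mean, tolerance = 1e-12)
  x1 <- prob$X[1, ]; x2 <- prob$X[2, ]
  al <- 0.3
  expect_equal(predict(m, al * x1 + (1 - al) * x2),
               al * predict(m, x1) + (1 - al) * predict(m, x2),
               tolerance = 1e-10)
  expect_error(predict(m, matrix(0, 2, 19)), "channels")
})

test_that("degenerate fits are rejected with the factor index", {
  X <- matrix(rnorm(40), 10, 4)
  expect_error(fit_pls(X, rep(1, 10), 2), "constant")
  prob <- make_pls_problem(10, 4, k_true = 1, noise = 0, seed = 9)
  expect_error(fit_pls(prob$X, prob$y, 3), "factor 2")
  expect_error(fit_pls(prob$X, prob$y, 9), "n >= k \\+ 2")
})

test_that("LOOCV predicts each sample from the others", {
  prob <- make_pls_problem(10, 8, k_true = 2, noise = 0.2, seed = 10)
  cv <- loocv(prob$X, prob$y, 2)
  expect_length(cv$cv_predictions, 10)
  # brute-force fold loop oracle
  oracle <- sapply(seq_len(10), function(i) {
    m <- fit_pls(prob$X[-i, ], prob$y[-i], 2)
    predict(m, prob$X[i, ])
  })
  expect_lt(max(abs(cv$cv_predictions - oracle)), 1e-12)
  expect_equal(cv$SECV, sqrt(mean((prob$y - oracle)^2)),
               tolerance = 1e-12)
})

test_that("noiseless exact-rank data cross-validates perfectly", {
  prob <- make_pls_problem(12, 10, k_true = 2, noise = 0, seed = 11)
  cv <- loocv(prob$X, prob$y, 2)
  expect_lt(cv$SECV, 1e-8)
  expect_gt(cv$r_cval, 1 - 1e-10)
})

test_that("calibration statistics follow the declared conventions", {
  set.seed(12)
  y <- rnorm(20, 5, 2)
  y_cal <- y + rnorm(20, 0, 0.3)
  y_cv <- y + rnorm(20, 0, 0.5)
  k <- 3
  rep <- calibration_stats(y, y_cal, y_cv, k)
  expect_equal(rep$SEC, sqrt(sum((y - y_cal)^2) / (20 - 1 - k)),
               tolerance = 1e-12)
  expect_equal(rep$SECV, sqrt(mean((y - y_cv)^2)), tolerance = 1e-12)
  expect_equal(rep$r_cal, cor(y, y_cal), tolerance = 1e-12)
  # RPD * SECV recovers SD(y) identically
  expect_equal(rep$RPD * rep$SECV, sd(y), tolerance = 1e-12)
  expect_lte(abs(rep$r_cal), 1)
  expect_error(calibration_stats(y, y, y, 3), "perfect fit")
  expect_error(calibration_stats(rep(1, 10), rnorm(10), rnorm(10), 2),
               "zero variance")
})

test_that("training error is non-increasing in the number of factors", {
  prob <- make_pls_problem(18, 25, k_true = 4, noise = 0.3, xnoise = 0.02,
                           seed = 13)
  rmsec <- sapply(1:6, function(k) {
    m <- fit_pls(prob$X, prob$y, k)
    sqrt(mean((prob$y - predict(m, prob$X))^2))
  })
  expect_true(all(diff(rmsec) <= 1e-10))
})

test_that("factor selection minimizes SECV, first minimum on ties", {
  prob <- make_pls_problem(16, 12, k_true = 3, noise = 0.05, xnoise = 0.02,
                           seed = 14)
  sel <- select_factors(prob$X, prob$y, 6)
  expect_equal(sel$k, which.min(sel$secv))
  expect_length(sel$secv, 6)
  expect_equal(sel$cv$SECV, min(sel$secv), tolerance = 1e-15)
  expect_error(select_factors(prob$X, prob$y, 14), "n - 3")
})

test_that("factor selection recovers the component count on mixtures", {
  hits <- 0
  for (s in 1:20) {
    set.seed(200 + s)
    n <- 24; p <- 60; m <- 4
    S <- matrix(0, m, p)
    grid <- seq_len(p)
    centers <- c(10, 25, 40, 52)
    for (j in 1:m) S[j, ] <- exp(-(grid - centers[j])^2 / 50)
    C <- matrix(runif(n * m, 0, 2), n, m)
    X <- C %*% S + matrix(rnorm(n * p, 0, 0.01), n, p)
    y <- C[, 1]
    sel <- select_factors(X, y, 7)
    if (abs(sel$k - 4) <= 1) hits <- hits + 1
  }
  expect_gte(hits, 16)
})
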