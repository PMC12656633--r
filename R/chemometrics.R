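#' Fit a PLS1 regression model (NIPALS)
#'
#' Partial least squares with a single response, extracting latent factors
#' one at a time: each weight vector maximizes covariance between the
#' (deflated) spectra and the analyte, followed by deflation of both X and
#' y. Data are mean-centered internally; the per-factor weights, loadings
#' and y-loadings are collapsed into a single regression vector `b` so that
#' `yhat = y_mean + (x - x_mean) %*% b`.
#'
#' @param X Predictor matrix, n x p (preprocessed spectra).
#' @param y Response vector of length n (reference analyte values).
#' @param k Number of latent factors, `1 <= k`, with `n >= k + 2` and
#'   `p >= k`.
#' @return Object of class `pls_model`: `x_mean`, `y_mean`, `W` (weights),
#'   `P` (x-loadings), `q` (y-loadings), `scores`, `b`, `k`.
#' @export
fit_pls <- function(X, y, k) {
  X <- as.matrix(X)
  y <- as.numeric(y)
  n <- nrow(X); p <- ncol(X); k <- as.integer(k)
  if (k < 1) stop("k must be >= 1", call. = FALSE)
  if (length(y) != n) stop("length(y) != nrow(X)", call. = FALSE)
  if (n < k + 2)
    stop("need n >= k + 2 samples (n = ", n, ", k = ", k, ")",
         call. = FALSE)
  if (p < k) stop("need p >= k channels", call. = FALSE)
  if (stats::var(y) < 1e-24)
    stop("response y is constant; PLS undefined", call. = FALSE)

  cen <- mean_center(X, y)
  Xc <- cen$X; yc <- cen$y
  W <- P <- matrix(0, p, k)
  q <- numeric(k)
  Tm <- matrix(0, n, k)
  for (a in seq_len(k)) {
    w <- drop(crossprod(Xc, yc))
    nw <- sqrt(sum(w^2))
    if (nw < 1e-12)
      stop("rank exhausted at factor ", a,
           ": weight vector norm below 1e-12", call. = FALSE)
    w <- w / nw
    t <- drop(Xc %*% w)
    tt <- sum(t^2)
    pa <- drop(crossprod(Xc, t)) / tt
    qa <- sum(yc * t) / tt
    Xc <- Xc - tcrossprod(t, pa)
    yc <- yc - qa * t
    W[, a] <- w; P[, a] <- pa; q[a] <- qa; Tm[, a] <- t
  }
  # b = W (P'W)^-1 q collapses the factorization into one vector
  b <- drop(W %*% solve(crossprod(P, W), q))
  structure(list(x_mean = cen$x_mean, y_mean = cen$y_mean,
                 W = W, P = P, q = q, scores = Tm, b = b, k = k),
            class = "pls_model")
}

#' @export
print.pls_model <- function(x, ...) {
  cat(sprintf("pls_model: %d latent factors, %d channels\n",
              x$k, length(x$b)))
  invisible(x)
}

#' Predict from a PLS model
#'
#' @param object A `pls_model` from [fit_pls()].
#' @param newdata Matrix (or vector) on the same preprocessed grid as the
#'   training spectra.
#' @param ... Unused.
#' @return Numeric vector of predictions.
#' @export
predict.pls_model <- function(object, newdata, ...) {
  X <- if (is.null(dim(newdata))) matrix(newdata, nrow = 1)
       else as.matrix(newdata)
  if (ncol(X) != length(object$b))
    stop("newdata has ", ncol(X), " channels; model expects ",
         length(object$b), call. = FALSE)
  drop(object$y_mean + sweep(X, 2, object$x_mean) %*% object$b)
}

#' Leave-one-out cross-validation for PLS1
#'
#' Each sample is predicted once by a model fitted to all other samples
#' (exactly n refits). Mean-centering is recomputed inside every fold; an
#' optional `preprocess` hook recomputes any data-dependent pretreatment
#' (e.g. the MSC reference) from the training fold only, so no information
#' leaks from the held-out sample.
#'
#' @param X Predictor matrix, n x p.
#' @param y Response vector.
#' @param k Number of latent factors; `n >= k + 3`.
#' @param preprocess Optional `function(X_train, X_test)` returning
#'   `list(train = ..., test = ...)`, applied per fold. `NULL` means X is
#'   already fully preprocessed (whole-set preprocessing).
#' @return List: `cv_predictions` (length n), `SECV`
#'   (`sqrt(mean((y - yhat_cv)^2))`), `r_cval` (Pearson correlation of
#'   reference and held-out predictions).
#' @export
loocv <- function(X, y, k, preprocess = NULL) {
  X <- as.matrix(X)
  y <- as.numeric(y)
  n <- nrow(X)
  if (n < k + 3)
    stop("LOOCV needs n >= k + 3 (n = ", n, ", k = ", k, ")",
         call. = FALSE)
  pred <- numeric(n)
  for (i in seq_len(n)) {
    Xtr <- X[-i, , drop = FALSE]
    Xte <- X[i, , drop = FALSE]
    if (!is.null(preprocess)) {
      pp <- preprocess(Xtr, Xte)
      Xtr <- pp$train; Xte <- pp$test
    }
    m <- tryCatch(fit_pls(Xtr, y[-i], k),
                  error = function(e)
                    stop("LOOCV fold ", i, " (held out '",
                         if (!is.null(rownames(X))) rownames(X)[i] else i,
                         "'): ", conditionMessage(e), call. = FALSE))
    pred[i] <- predict(m, Xte)
  }
  list(cv_predictions = pred,
       SECV = sqrt(mean((y - pred)^2)),
       r_cval = stats::cor(y, pred))
}

#' Calibration statistics (SEC, SECV, r, RPD)
#'
#' Conventions: `SEC = sqrt(sum((y - yhat_cal)^2) / (n - 1 - k))` (degrees
#' of freedom adjusted for the fitted factors and the intercept),
#' `SECV = sqrt(sum((y - yhat_cv)^2) / n)`, `r_cal`/`r_cval` = Pearson
#' correlation between reference and predicted, and
#' `RPD = SD(y) / SECV` with the n-1 sample standard deviation. Plain RMSE
#' variants (`RMSEC`, 1/n denominator) are reported alongside so the
#' convention is auditable.
#'
#' @param y Reference values.
#' @param y_cal Fitted (training) predictions.
#' @param y_cv Held-out (LOOCV) predictions.
#' @param k Number of PLS factors used.
#' @return Object of class `calibration_report`: `k`, `SEC`, `SECV`,
#'   `RMSEC`, `r_cal`, `r_cval`, `RPD`, `sd_y`, `n`, `cv_predictions`.
#' @export
calibration_stats <- function(y, y_cal, y_cv, k) {
  y <- as.numeric(y); y_cal <- as.numeric(y_cal); y_cv <- as.numeric(y_cv)
  n <- length(y)
  if (length(y_cal) != n || length(y_cv) != n)
    stop("y, y_cal, y_cv must have equal length", call. = FALSE)
  if (n <= k + 1)
    stop("need n > k + 1 for SEC degrees of freedom", call. = FALSE)
  sd_y <- stats::sd(y)
  if (!is.finite(sd_y) || sd_y < 1e-24)
    stop("reference values have zero variance; r and RPD undefined",
         call. = FALSE)
  SEC <- sqrt(sum((y - y_cal)^2) / (n - 1 - k))
  RMSEC <- sqrt(mean((y - y_cal)^2))
  SECV <- sqrt(mean((y - y_cv)^2))
  if (SECV < 1e-24)
    stop("perfect fit: SECV = 0, RPD undefined", call. = FALSE)
  structure(list(k = as.integer(k), SEC = SEC, SECV = SECV, RMSEC = RMSEC,
                 r_cal = stats::cor(y, y_cal),
                 r_cval = stats::cor(y, y_cv),
                 RPD = sd_y / SECV, sd_y = sd_y, n = n,
                 cv_predictions = y_cv),
            class = "calibration_report")
}

#' @export
print.calibration_report <- function(x, ...) {
  cat(sprintf(
    "calibration_report (n = %d, k = %d)\n  SEC  = %.4g  r_cal  = %.4f\n  SECV = %.4g  r_cval = %.4f\n  RPD  = %.3f\n",
    x$n, x$k, x$SEC, x$r_cal, x$SECV, x$r_cval, x$RPD))
  invisible(x)
}

#' @export
as.data.frame.calibration_report <- function(x, ...) {
  data.frame(n = x$n, k = x$k, SEC = x$SEC, SECV = x$SECV,
             RMSEC = x$RMSEC, r_cal = x$r_cal, r_cval = x$r_cval,
             RPD = x$RPD, sd_y = x$sd_y)
}

#' Choose the number of PLS factors by minimal SECV
#'
#' Runs leave-one-out cross-validation for k = 1..k_max and returns the k
#' with the smallest SECV; exact ties go to the smaller k (parsimony).
#'
#' @param X Predictor matrix.
#' @param y Response vector.
#' @param k_max Largest factor count to consider; `k_max <= n - 3`.
#' @param preprocess Optional per-fold preprocessing hook (see [loocv()]).
#' @return List: `k` (chosen), `secv` (vector over 1..k_max), `cv` (the
#'   [loocv()] result at the chosen k).
#' @export
select_factors <- function(X, y, k_max, preprocess = NULL) {
  n <- nrow(as.matrix(X))
  k_max <- as.integer(k_max)
  if (k_max < 1) stop("k_max must be >= 1", call. = FALSE)
  if (k_max > n - 3)
    stop("k_max must be <= n - 3 for LOOCV", call. = FALSE)
  runs <- lapply(seq_len(k_max), function(k)
    loocv(X, y, k, preprocess = preprocess))
  secv <- vapply(runs, `[[`, numeric(1), "SECV")
  k_star <- which.min(secv)   # which.min returns the first (smallest k) tie
  list(k = k_star, secv = secv, cv = runs[[k_star]])
}
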