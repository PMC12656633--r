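#' Savitzky-Golay configuration for the second derivative
#'
#' The second-derivative pretreatment separates overlapping NIR bands and
#' removes baseline offset and slope. Defaults (15-point window, quadratic
#' local fit) are common NIRS practice for 512-channel spectra.
#'
#' @param window_points Odd integer window length, >= `polyorder + 2`.
#' @param polyorder Local polynomial degree, >= 2 (the derivative order).
#' @return An object of class `sg_config`.
#' @export
sg_config <- function(window_points = 15L, polyorder = 2L) {
  window_points <- as.integer(window_points)
  polyorder <- as.integer(polyorder)
  if (window_points %% 2L != 1L)
    stop("window_points must be odd", call. = FALSE)
  if (polyorder < 2L)
    stop("polyorder must be >= 2 for a second derivative", call. = FALSE)
  if (polyorder >= window_points)
    stop("polyorder must be smaller than window_points", call. = FALSE)
  structure(list(window_points = window_points, polyorder = polyorder,
                 derivative_order = 2L),
            class = "sg_config")
}

#' Savitzky-Golay second derivative of a spectra set
#'
#' Local least-squares polynomial differentiation, exact on polynomials up
#' to the fit degree. Requires a uniform grid (within 1e-6 relative
#' spacing). Edge channels where the window does not fit are trimmed rather
#' than extrapolated, and the grid is trimmed accordingly, so no fabricated
#' values enter downstream calibration.
#'
#' @param s A [spectra_set()].
#' @param cfg An [sg_config()].
#' @return A [spectra_set()] on the trimmed grid, units absorbance nm^-2,
#'   provenance appended `"d2"`.
#' @export
second_derivative <- function(s, cfg = sg_config()) {
  stopifnot(inherits(s, "spectra_set"), inherits(cfg, "sg_config"))
  grid <- as.numeric(s$grid)
  p <- length(grid)
  w <- cfg$window_points
  if (w > p)
    stop("window_points (", w, ") exceeds channel count (", p, ")",
         call. = FALSE)
  d <- diff(grid)
  h <- mean(d)
  if (max(abs(d - h)) > 1e-6 * abs(h))
    stop("second_derivative requires a uniform wavelength grid", call. = FALSE)
  # central row of the SG differentiation filter, scaled for spacing h
  F <- signal::sgolay(p = cfg$polyorder, n = w, m = 2L, ts = h)
  cc <- F[(w + 1L) %/% 2L, ]
  half <- (w - 1L) %/% 2L
  keep <- (half + 1L):(p - half)
  out <- matrix(0, nrow(s$absorbance), length(keep))
  for (k in seq_along(keep)) {
    i <- keep[k]
    out[, k] <- s$absorbance[, (i - half):(i + half), drop = FALSE] %*% cc
  }
  spectra_set(grid[keep], out, s$sample_ids,
              provenance = c(s$provenance, "d2"))
}

#' Multiplicative scatter correction reference
#'
#' @param spectrum Reference spectrum (numeric vector on the set's grid),
#'   or `NULL` to use the mean spectrum of the set being corrected
#'   (standard MSC, and the aquagram convention).
#' @param source Label recording where the reference came from.
#' @return An object of class `msc_reference`.
#' @export
msc_reference <- function(spectrum = NULL,
                          source = if (is.null(spectrum)) "dataset-mean"
                                   else "supplied") {
  if (!is.null(spectrum)) {
    spectrum <- as.numeric(spectrum)
    if (any(!is.finite(spectrum)))
      stop("MSC reference contains non-finite values", call. = FALSE)
  }
  structure(list(spectrum = spectrum, source = source),
            class = "msc_reference")
}

#' Multiplicative scatter correction
#'
#' For each spectrum `x`, fits `x ~ a + b * ref` by ordinary least squares
#' over all channels and returns `(x - a) / b`, removing per-sample
#' multiplicative gain and additive offset caused by scatter.
#'
#' @param s A [spectra_set()].
#' @param ref An [msc_reference()]; default uses the mean spectrum of `s`.
#' @return A [spectra_set()] with provenance appended `"msc"`.
#' @export
msc <- function(s, ref = msc_reference()) {
  stopifnot(inherits(s, "spectra_set"), inherits(ref, "msc_reference"))
  r <- if (is.null(ref$spectrum)) colMeans(s$absorbance) else ref$spectrum
  if (length(r) != length(s$grid))
    stop("MSC reference length does not match grid", call. = FALSE)
  vr <- stats::var(r)
  if (!is.finite(vr) || vr < 1e-24)
    stop("MSC reference is (numerically) constant", call. = FALSE)
  rc <- r - mean(r)
  out <- s$absorbance
  for (i in seq_len(nrow(out))) {
    x <- s$absorbance[i, ]
    b <- sum(rc * (x - mean(x))) / sum(rc * rc)
    if (abs(b) < 1e-12)
      stop("degenerate MSC fit (|b| < 1e-12) for sample '",
           s$sample_ids[i], "'", call. = FALSE)
    a <- mean(x) - b * mean(r)
    out[i, ] <- (x - a) / b
  }
  spectra_set(s$grid, out, s$sample_ids,
              provenance = c(s$provenance, "msc"))
}

#' Mean-center a predictor matrix and response
#'
#' Standard PLS pre-step; the stored means are reused at prediction time.
#'
#' @param X Numeric matrix, n x p, n >= 2.
#' @param y Numeric response vector of length n (optional).
#' @return List with `X` (centered), `y` (centered or NULL), `x_mean`,
#'   `y_mean`.
#' @export
mean_center <- function(X, y = NULL) {
  X <- as.matrix(X)
  if (nrow(X) < 2) stop("mean_center needs n >= 2", call. = FALSE)
  x_mean <- colMeans(X)
  Xc <- sweep(X, 2, x_mean)
  y_mean <- NULL
  yc <- NULL
  if (!is.null(y)) {
    if (length(y) != nrow(X)) stop("length(y) != nrow(X)", call. = FALSE)
    y_mean <- mean(y)
    yc <- y - y_mean
  }
  list(X = Xc, y = yc, x_mean = x_mean, y_mean = y_mean)
}
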