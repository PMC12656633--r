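#' Water matrix coordinates for aquagrams
#'
#' Conserved NIR wavelength bands attributed to water species (free water,
#' dimers, solvation shells, hydrogen-bonded clusters, strongly bound
#' water). The default set contains the 13 coordinates discussed for the
#' purslane water matrix: 1348, 1360, 1410, 1429, 1441 (water dimer), 1447
#' and 1454 (solvation shell), 1465/1478/1485 (2/3/4 hydrogen bonds), 1503
#' (strongly bound water), 1521 and 1559 nm (structural water). Any other
#' published coordinate list (e.g. a full 19-coordinate set) can be passed
#' in as a custom set.
#'
#' @param wavelengths Numeric vector of coordinate wavelengths in nm.
#' @param labels Unique labels, default the wavelength itself.
#' @param source Tag recording where the list came from.
#' @return Object of class `water_matrix_coordinates`: data.frame with
#'   `label`, `requested_nm`, plus the `source` attribute.
#' @export
water_matrix_coordinates <- function(
    wavelengths = c(1348, 1360, 1410, 1429, 1441, 1447, 1454, 1465,
                    1478, 1485, 1503, 1521, 1559),
    labels = paste0(wavelengths, "nm"),
    source = "default") {
  wavelengths <- as.numeric(wavelengths)
  if (any(!is.finite(wavelengths)))
    stop("coordinate wavelengths must be finite", call. = FALSE)
  if (anyDuplicated(labels))
    stop("coordinate labels must be unique", call. = FALSE)
  if (length(labels) != length(wavelengths))
    stop("labels and wavelengths differ in length", call. = FALSE)
  structure(data.frame(label = as.character(labels),
                       requested_nm = wavelengths,
                       stringsAsFactors = FALSE),
            source = source, class = c("water_matrix_coordinates",
                                       "data.frame"))
}

#' Compute an aquagram profile
#'
#' Applies multiplicative scatter correction with the analyzed set's own
#' mean spectrum as reference, then standardizes each wavelength over the
#' sample set, `Aq = (A - mu) / sigma` (mu, sigma = per-wavelength mean and
#' standard deviation of the MSC-corrected spectra), and extracts the
#' water-matrix coordinate columns. Each requested coordinate is mapped to
#' the nearest grid channel; the actual channel wavelength is recorded.
#' Operates on raw absorbance only, never on derivative spectra.
#'
#' @param s A [spectra_set()] of raw spectra, n >= 2 samples.
#' @param coords A [water_matrix_coordinates()] set within the grid span.
#' @return Object of class `aquagram_profile`: `values`
#'   (n_samples x n_coords, unitless standardized absorbance), `coords`
#'   (with `actual_nm` and `channel` columns added), `sample_ids`.
#' @export
aquagram <- function(s, coords = water_matrix_coordinates()) {
  stopifnot(inherits(s, "spectra_set"))
  if ("d2" %in% s$provenance)
    stop("aquagrams are defined on raw absorbance, not derivative spectra",
         call. = FALSE)
  n <- nrow(s$absorbance)
  if (n < 2) stop("aquagram needs at least 2 samples", call. = FALSE)
  grid <- as.numeric(s$grid)
  if (any(coords$requested_nm < min(grid) | coords$requested_nm > max(grid)))
    stop("coordinate(s) outside the grid span: ",
         paste(coords$requested_nm[coords$requested_nm < min(grid) |
                                   coords$requested_nm > max(grid)],
               collapse = ", "), call. = FALSE)
  corrected <- if ("msc" %in% s$provenance) s else msc(s)
  A <- corrected$absorbance
  mu <- colMeans(A)
  sigma <- apply(A, 2, stats::sd)
  channel <- vapply(coords$requested_nm,
                    function(w) which.min(abs(grid - w)), integer(1))
  bad <- sigma[channel] < 1e-12
  if (any(bad))
    stop("degenerate coordinate(s), sd < 1e-12 at ",
         paste(grid[channel[bad]], "nm", collapse = ", "), call. = FALSE)
  Z <- sweep(sweep(A, 2, mu), 2, sigma, "/")
  values <- Z[, channel, drop = FALSE]
  cinfo <- as.data.frame(coords)
  cinfo$actual_nm <- grid[channel]
  cinfo$channel <- channel
  colnames(values) <- cinfo$label
  rownames(values) <- s$sample_ids
  structure(list(values = values, coords = cinfo,
                 sample_ids = s$sample_ids),
            class = "aquagram_profile")
}

#' @export
print.aquagram_profile <- function(x, ...) {
  cat(sprintf("aquagram_profile: %d samples x %d coordinates (%s)\n",
              nrow(x$values), ncol(x$values),
              paste(range(x$coords$actual_nm), collapse = "-")))
  invisible(x)
}

#' Group-averaged aquagram
#'
#' Arithmetic mean of the aquagram values per group and coordinate (the
#' radar-chart curves, e.g. oxalate-content bins). Because each coordinate
#' is standardized over all samples, the size-weighted mean over groups is
#' zero at every coordinate.
#'
#' @param p An `aquagram_profile` from [aquagram()].
#' @param groups Vector of group labels, one per sample; no empty groups.
#' @return Matrix `n_groups x n_coords` of group means, rownames = group
#'   labels (in order of first appearance).
#' @export
group_average_aquagram <- function(p, groups) {
  stopifnot(inherits(p, "aquagram_profile"))
  if (length(groups) != nrow(p$values))
    stop("need one group label per sample", call. = FALSE)
  groups <- as.character(groups)
  if (anyNA(groups)) stop("every sample must be labeled", call. = FALSE)
  labs <- unique(groups)
  out <- t(vapply(labs, function(g) {
    idx <- groups == g
    if (!any(idx)) stop("empty group: ", g, call. = FALSE)
    colMeans(p$values[idx, , drop = FALSE])
  }, numeric(ncol(p$values))))
  rownames(out) <- labs
  out
}

#' Per-coordinate correlation with an analyte
#'
#' Pearson correlation between each aquagram coordinate and a reference
#' analyte vector (e.g. total oxalate, fresh-weight basis), sign preserved.
#'
#' @param p An `aquagram_profile`.
#' @param analyte Numeric vector, one value per sample, non-constant.
#' @return Named numeric vector of correlations, one per coordinate.
#' @export
coordinate_correlations <- function(p, analyte) {
  stopifnot(inherits(p, "aquagram_profile"))
  analyte <- as.numeric(analyte)
  if (length(analyte) != nrow(p$values))
    stop("analyte length must equal number of samples", call. = FALSE)
  if (stats::var(analyte) < 1e-24)
    stop("analyte is constant; correlation undefined", call. = FALSE)
  drop(stats::cor(analyte, p$values))
}

#' Export aquagram values for radar-chart plotting
#'
#' Writes a CSV with coordinates in increasing wavelength order and, for a
#' closed radar polygon, the first coordinate repeated as the final column.
#'
#' @param p An `aquagram_profile`, or a group-mean matrix from
#'   [group_average_aquagram()] together with the profile's coordinates.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_aquagram_csv <- function(p, path) {
  stopifnot(inherits(p, "aquagram_profile"))
  ord <- order(p$coords$actual_nm)
  vals <- p$values[, ord, drop = FALSE]
  closed <- cbind(vals, vals[, 1, drop = FALSE])
  colnames(closed)[ncol(closed)] <- paste0(colnames(vals)[1], "_close")
  df <- data.frame(sample_id = p$sample_ids, closed, check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
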