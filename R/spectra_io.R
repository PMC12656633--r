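#' Construct a wavelength grid
#'
#' A wavelength grid is a strictly increasing vector of wavelengths in nm.
#' The study instrument (512-channel InGaAs array) covers 900--1700 nm; the
#' grid is never assumed uniform, so all operations carry it explicitly.
#'
#' @param values Numeric vector of wavelengths in nm, strictly increasing,
#'   length >= 3, all finite.
#' @return A numeric vector of class `wavelength_grid`.
#' @export
wavelength_grid <- function(values) {
  values <- as.numeric(values)
  if (length(values) < 3)
    stop("wavelength grid must have at least 3 channels", call. = FALSE)
  if (!all(is.finite(values)))
    stop("wavelength grid contains non-finite values", call. = FALSE)
  if (any(diff(values) <= 0))
    stop("wavelength grid must be strictly increasing", call. = FALSE)
  structure(values, class = "wavelength_grid")
}

#' Construct a spectra set
#'
#' Binds an absorbance matrix (samples x channels, unitless absorbance) to a
#' wavelength grid and unique sample IDs, and tracks the chain of transforms
#' applied ("raw", "msc", "d2", ...).
#'
#' @param grid A [wavelength_grid()] or numeric vector coercible to one.
#' @param absorbance Numeric matrix, `n_samples x n_channels`, no missing
#'   values.
#' @param sample_ids Character vector of unique sample identifiers.
#' @param provenance Character vector of transform labels applied so far.
#' @return An object of class `spectra_set` with elements `grid`,
#'   `absorbance` (rownames = sample IDs), `sample_ids`, `provenance`.
#' @export
spectra_set <- function(grid, absorbance, sample_ids,
                        provenance = "raw") {
  if (!inherits(grid, "wavelength_grid")) grid <- wavelength_grid(grid)
  absorbance <- as.matrix(absorbance)
  storage.mode(absorbance) <- "double"
  sample_ids <- as.character(sample_ids)
  if (ncol(absorbance) != length(grid))
    stop("absorbance has ", ncol(absorbance), " channels but grid has ",
         length(grid), call. = FALSE)
  if (nrow(absorbance) != length(sample_ids))
    stop("number of sample IDs does not match number of spectra",
         call. = FALSE)
  if (anyDuplicated(sample_ids))
    stop("duplicate sample IDs: ",
         paste(unique(sample_ids[duplicated(sample_ids)]), collapse = ", "),
         call. = FALSE)
  if (nrow(absorbance) > 0 && any(!is.finite(absorbance)))
    stop("absorbance matrix contains missing or non-finite values",
         call. = FALSE)
  rownames(absorbance) <- sample_ids
  colnames(absorbance) <- format(as.numeric(grid), trim = TRUE)
  structure(list(grid = grid, absorbance = absorbance,
                 sample_ids = sample_ids,
                 provenance = as.character(provenance)),
            class = "spectra_set")
}

#' @export
print.spectra_set <- function(x, ...) {
  cat(sprintf("spectra_set: %d samples x %d channels (%.1f-%.1f nm)\n",
              nrow(x$absorbance), length(x$grid),
              min(x$grid), max(x$grid)))
  cat("  provenance:", paste(x$provenance, collapse = " -> "), "\n")
  invisible(x)
}

#' @export
dim.spectra_set <- function(x) dim(x$absorbance)

#' Read a wide-CSV spectral matrix
#'
#' Canonical interchange format: first column holds sample IDs, remaining
#' column headers are numeric wavelengths (nm) in strictly increasing order,
#' cells are absorbance values.
#'
#' @param path Path to an existing CSV file.
#' @return A [spectra_set()] with provenance `"raw"`.
#' @export
read_spectra_csv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- utils::read.csv(path, check.names = FALSE, colClasses = "character")
  if (ncol(raw) < 4)
    stop("spectra CSV needs an ID column plus >= 3 wavelength columns",
         call. = FALSE)
  wl <- suppressWarnings(as.numeric(colnames(raw)[-1]))
  if (any(is.na(wl)))
    stop("non-numeric wavelength header(s): ",
         paste(colnames(raw)[-1][is.na(wl)], collapse = ", "), call. = FALSE)
  if (any(diff(wl) <= 0))
    stop("wavelength header is not strictly increasing", call. = FALSE)
  ids <- raw[[1]]
  mat <- matrix(NA_real_, nrow(raw), length(wl))
  for (j in seq_along(wl)) {
    v <- suppressWarnings(as.numeric(raw[[j + 1]]))
    bad <- which(is.na(v) & !is.na(raw[[j + 1]]) & nzchar(raw[[j + 1]]))
    if (any(is.na(v)))
      stop("non-numeric or missing value in row ",
           if (length(bad)) bad[1] else which(is.na(v))[1],
           ", wavelength ", wl[j], call. = FALSE)
    mat[, j] <- v
  }
  spectra_set(wl, mat, ids, provenance = "raw")
}

#' Write a spectra set as wide CSV
#'
#' Full float precision, column order = grid order, deterministic output.
#'
#' @param s A [spectra_set()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_spectra_csv <- function(s, path) {
  stopifnot(inherits(s, "spectra_set"))
  df <- data.frame(sample_id = s$sample_ids, check.names = FALSE,
                   stringsAsFactors = FALSE)
  vals <- as.data.frame(s$absorbance)
  colnames(vals) <- format(as.numeric(s$grid), digits = 15, trim = TRUE)
  df <- cbind(df, vals)
  ok <- tryCatch({
    utils::write.csv(format(df, digits = 17, trim = TRUE, scientific = FALSE),
                     path, row.names = FALSE, quote = FALSE)
    TRUE
  }, error = function(e) FALSE, warning = function(w) FALSE)
  if (!ok) stop("cannot write spectra CSV to ", path, call. = FALSE)
  invisible(path)
}

#' Read sample metadata from long CSV
#'
#' Expected columns: `sample_id, population, series, treatment,
#' moisture_pct, analyte, basis, value`. One row per (sample, analyte,
#' basis); design fields must be constant within a sample.
#'
#' @param path Path to the metadata CSV.
#' @return A `sample_meta` object (see [sample_meta()]).
#' @export
read_sample_meta <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("sample_id", "population", "series", "treatment",
            "moisture_pct", "analyte", "basis", "value")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("metadata CSV missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  design <- unique(df[c("sample_id", "population", "series", "treatment",
                        "moisture_pct")])
  values <- df[c("sample_id", "analyte", "basis", "value")]
  sample_meta(design, values)
}

#' Construct sample metadata
#'
#' Per-sample design factors (population, series 1-3, treatment) plus
#' moisture percentage and reference analyte values tagged with their basis
#' (`"dm"` = g/100 g dry matter, `"fw"` = g/100 g fresh weight, or any
#' caller-chosen basis label).
#'
#' @param design data.frame with columns `sample_id, population, series,
#'   treatment, moisture_pct`; one row per sample.
#' @param values data.frame with columns `sample_id, analyte, basis, value`.
#' @return An object of class `sample_meta`.
#' @export
sample_meta <- function(design, values) {
  design <- as.data.frame(design, stringsAsFactors = FALSE)
  values <- as.data.frame(values, stringsAsFactors = FALSE)
  if (anyDuplicated(design$sample_id))
    stop("duplicate sample_id in design: ",
         paste(unique(design$sample_id[duplicated(design$sample_id)]),
               collapse = ", "), call. = FALSE)
  if (!all(design$treatment %in% c("fresh", "blanched", "pickled")))
    stop("treatment must be one of fresh, blanched, pickled", call. = FALSE)
  if (!all(design$series %in% 1:3))
    stop("series must be an integer in 1..3", call. = FALSE)
  m <- design$moisture_pct
  if (any(!is.finite(m) | m < 0 | m >= 100))
    stop("moisture_pct must lie in [0, 100)", call. = FALSE)
  extra <- setdiff(values$sample_id, design$sample_id)
  if (length(extra))
    stop("reference values for unknown sample(s): ",
         paste(unique(extra), collapse = ", "), call. = FALSE)
  structure(list(design = design, values = values), class = "sample_meta")
}

#' @export
print.sample_meta <- function(x, ...) {
  cat(sprintf("sample_meta: %d samples, analytes: %s\n",
              nrow(x$design),
              paste(unique(x$values$analyte), collapse = ", ")))
  invisible(x)
}

#' Pair spectra with metadata
#'
#' Aligns metadata to the spectra set's sample order. Every spectrum must
#' have exactly one metadata row; offending IDs are listed on error. The
#' spectra order is never changed.
#'
#' @param s A [spectra_set()].
#' @param meta A [sample_meta()].
#' @return An object of class `nir_dataset`: `spectra`, `design` (row order
#'   = spectra order), `values`.
#' @export
join_metadata <- function(s, meta) {
  stopifnot(inherits(s, "spectra_set"), inherits(meta, "sample_meta"))
  missing_ids <- setdiff(s$sample_ids, meta$design$sample_id)
  extra_ids <- setdiff(meta$design$sample_id, s$sample_ids)
  if (length(missing_ids) || length(extra_ids)) {
    msg <- c(if (length(missing_ids))
               paste0("no metadata for: ",
                      paste(missing_ids, collapse = ", ")),
             if (length(extra_ids))
               paste0("metadata without spectra: ",
                      paste(extra_ids, collapse = ", ")))
    stop("spectra/metadata misalignment; ", paste(msg, collapse = "; "),
         call. = FALSE)
  }
  design <- meta$design[match(s$sample_ids, meta$design$sample_id), ,
                        drop = FALSE]
  rownames(design) <- NULL
  structure(list(spectra = s, design = design, values = meta$values),
            class = "nir_dataset")
}

#' @export
print.nir_dataset <- function(x, ...) {
  cat(sprintf("nir_dataset: %d samples x %d channels\n",
              nrow(x$spectra$absorbance), length(x$spectra$grid)))
  invisible(x)
}

#' Extract reference analyte values from a paired dataset
#'
#' Total lookup: errors when any sample lacks a value for the requested
#' analyte/basis pair.
#'
#' @param ds An `nir_dataset` from [join_metadata()].
#' @param analyte Analyte name, e.g. `"oxalate"`.
#' @param basis Basis flag, e.g. `"fw"` or `"dm"`.
#' @return Numeric vector in the dataset's sample order.
#' @export
reference_values <- function(ds, analyte, basis) {
  stopifnot(inherits(ds, "nir_dataset"))
  v <- ds$values[ds$values$analyte == analyte & ds$values$basis == basis, ]
  idx <- match(ds$design$sample_id, v$sample_id)
  if (any(is.na(idx))) {
    have <- unique(paste(ds$values$analyte, ds$values$basis, sep = "_"))
    stop("no reference value '", analyte, "' on basis '", basis,
         "' for sample(s): ",
         paste(ds$design$sample_id[is.na(idx)], collapse = ", "),
         " (stored: ", paste(have, collapse = ", "), ")", call. = FALSE)
  }
  v$value[idx]
}

#' Average replicate spectra sharing a sample ID prefix
#'
#' The study averaged several measurement points per sample before
#' modelling. Averaging is an explicit pre-step: rows mapped to the same
#' group label are replaced by their mean spectrum.
#'
#' @param s A [spectra_set()].
#' @param groups Character vector, one label per spectrum; spectra with the
#'   same label are averaged. Output order = first occurrence of each label.
#' @return A [spectra_set()] with one spectrum per group and provenance
#'   appended `"avg"`.
#' @export
average_replicates <- function(s, groups) {
  stopifnot(inherits(s, "spectra_set"),
            length(groups) == nrow(s$absorbance))
  groups <- as.character(groups)
  labs <- unique(groups)
  mat <- t(vapply(labs, function(g) {
    colMeans(s$absorbance[groups == g, , drop = FALSE])
  }, numeric(ncol(s$absorbance))))
  spectra_set(s$grid, mat, labs, provenance = c(s$provenance, "avg"))
}
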