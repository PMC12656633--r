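# polynomial rolling hash of the deparsed config; stamped into every output
# file so a report can be traced to the exact configuration that produced
# it; the output location is not part of the scientific configuration
config_hash <- function(cfg) {
  cfg$out_dir <- NULL
  bytes <- utf8ToInt(paste(deparse(cfg), collapse = "\n"))
  h <- 0
  for (b in bytes) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", h)
}

#' Configuration of an end-to-end calibration run
#'
#' Exactly one input source: either CSV paths (`spectra_csv` +
#' `meta_csv`) or a simulation config (`sim`).
#'
#' @param spectra_csv,meta_csv Paths to the wide spectra CSV and long
#'   metadata CSV.
#' @param sim A [synth_config()] to simulate the study instead of reading
#'   files.
#' @param analyte,basis Reference value to calibrate against (default
#'   oxalate on the fresh-weight basis, matching wet-tissue spectra).
#' @param preprocess Character vector, ordered subset of
#'   `c("msc", "d2")`.
#' @param sg An [sg_config()] for the derivative step.
#' @param k_max Largest PLS factor count screened by LOOCV.
#' @param msc_per_fold If `TRUE` (default) the MSC reference is recomputed
#'   from the training fold inside every LOOCV fold; `FALSE` reproduces
#'   whole-set preprocessing.
#' @param subset_treatment Optional treatment filter (`"fresh"`,
#'   `"blanched"`, `"pickled"`); `NULL` = all samples pooled.
#' @param coords Aquagram coordinates for the optional aquagram export.
#' @param out_dir Output directory (created if needed); `NULL` = no files
#'   written.
#' @param seed Integer seed used for any simulation.
#' @return Object of class `run_config`.
#' @export
run_config <- function(spectra_csv = NULL, meta_csv = NULL, sim = NULL,
                       analyte = "oxalate", basis = "fw",
                       preprocess = c("msc", "d2"), sg = sg_config(),
                       k_max = 10L, msc_per_fold = TRUE,
                       subset_treatment = NULL,
                       coords = water_matrix_coordinates(),
                       out_dir = NULL, seed = 1L) {
  from_files <- !is.null(spectra_csv) || !is.null(meta_csv)
  if (from_files && !is.null(sim))
    stop("give either CSV paths or a simulation config, not both",
         call. = FALSE)
  if (from_files && (is.null(spectra_csv) || is.null(meta_csv)))
    stop("file input needs both spectra_csv and meta_csv", call. = FALSE)
  if (!from_files && is.null(sim))
    stop("exactly one input source required (files or sim)", call. = FALSE)
  if (!all(preprocess %in% c("msc", "d2")))
    stop("preprocess steps must be among 'msc', 'd2'", call. = FALSE)
  if (k_max < 1) stop("k_max must be >= 1", call. = FALSE)
  structure(list(spectra_csv = spectra_csv, meta_csv = meta_csv, sim = sim,
                 analyte = analyte, basis = basis,
                 preprocess = preprocess, sg = sg,
                 k_max = as.integer(k_max),
                 msc_per_fold = isTRUE(msc_per_fold),
                 subset_treatment = subset_treatment, coords = coords,
                 out_dir = out_dir, seed = as.integer(seed)),
            class = "run_config")
}

stage_error <- function(stage, expr) {
  tryCatch(expr, error = function(e)
    stop("[", stage, "] ", conditionMessage(e), call. = FALSE))
}

# matrix-level preprocessing used both whole-set and per-fold
apply_chain <- function(X, grid, steps, sg, msc_ref = NULL) {
  s <- spectra_set(grid, X, sprintf("r%04d", seq_len(nrow(X))))
  for (st in steps) {
    s <- switch(st,
                msc = msc(s, if (is.null(msc_ref)) msc_reference()
                             else msc_reference(msc_ref)),
                d2 = second_derivative(s, sg))
  }
  list(X = s$absorbance, grid = as.numeric(s$grid))
}

#' Run an end-to-end NIR calibration
#'
#' Loads or simulates a paired dataset, applies the preprocessing chain,
#' screens PLS factor counts by leave-one-out cross-validation (minimum
#' SECV), fits the final model, and reports SEC, SECV, r_cal, r_cval and
#' RPD together with the per-sample cross-validation predictions. When
#' `cfg$out_dir` is set, writes `report.csv`, `cv_predictions.csv`,
#' `predicted_vs_reference.csv` and `run_log.txt`, each stamped with the
#' config hash; partial outputs are removed if any stage fails.
#'
#' @param cfg A [run_config()].
#' @return List: `report` (a `calibration_report`), `k`, `secv_curve`,
#'   `model` (the final `pls_model`), `n`, `y`, `y_cal`, `dataset`,
#'   `config_hash`, `paths` (written files, if any).
#' @export
run_calibration <- function(cfg) {
  stopifnot(inherits(cfg, "run_config"))
  hash <- config_hash(cfg)
  written <- character(0)
  on_fail <- function() if (length(written)) unlink(written)

  ds <- stage_error("input", {
    if (!is.null(cfg$sim)) {
      simulate_study(cfg$sim, cfg$seed)$dataset
    } else {
      join_metadata(read_spectra_csv(cfg$spectra_csv),
                    read_sample_meta(cfg$meta_csv))
    }
  })
  if (!is.null(cfg$subset_treatment)) {
    keep <- ds$design$treatment %in% cfg$subset_treatment
    if (!any(keep))
      stop("[input] no samples with treatment ",
           paste(cfg$subset_treatment, collapse = "/"), call. = FALSE)
    sub <- spectra_set(ds$spectra$grid,
                       ds$spectra$absorbance[keep, , drop = FALSE],
                       ds$spectra$sample_ids[keep],
                       provenance = ds$spectra$provenance)
    vals <- ds$values[ds$values$sample_id %in% sub$sample_ids, ,
                      drop = FALSE]
    ds <- join_metadata(sub, sample_meta(ds$design[keep, , drop = FALSE],
                                         vals))
  }
  y <- stage_error("input", reference_values(ds, cfg$analyte, cfg$basis))
  grid0 <- as.numeric(ds$spectra$grid)
  X0 <- ds$spectra$absorbance

  res <- stage_error("preprocess+model", {
    if (cfg$msc_per_fold && "msc" %in% cfg$preprocess) {
      # MSC reference (training-fold mean) recomputed inside each fold;
      # the derivative is per-sample and carries no fold statistics
      hook <- function(Xtr, Xte) {
        ref <- colMeans(Xtr)
        tr <- apply_chain(Xtr, grid0, cfg$preprocess, cfg$sg, msc_ref = ref)
        te <- apply_chain(Xte, grid0, cfg$preprocess, cfg$sg, msc_ref = ref)
        list(train = tr$X, test = te$X)
      }
      sel <- select_factors(X0, y, cfg$k_max, preprocess = hook)
      full <- apply_chain(X0, grid0, cfg$preprocess, cfg$sg)
      list(sel = sel, X = full$X)
    } else {
      full <- apply_chain(X0, grid0, cfg$preprocess, cfg$sg)
      sel <- select_factors(full$X, y, cfg$k_max)
      list(sel = sel, X = full$X)
    }
  })
  st <- stage_error("stats", {
    model <- fit_pls(res$X, y, res$sel$k)
    y_cal <- predict(model, res$X)
    list(report = calibration_stats(y, y_cal, res$sel$cv$cv_predictions,
                                    res$sel$k),
         model = model, y_cal = y_cal)
  })
  report <- st$report
  model <- st$model
  y_cal <- st$y_cal

  paths <- character(0)
  if (!is.null(cfg$out_dir)) {
    tryCatch({
      dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
      p_rep <- file.path(cfg$out_dir, "report.csv")
      rep_df <- cbind(as.data.frame(report), config_hash = hash)
      utils::write.csv(rep_df, p_rep, row.names = FALSE)
      written <- c(written, p_rep)
      p_cv <- file.path(cfg$out_dir, "cv_predictions.csv")
      utils::write.csv(data.frame(sample_id = ds$design$sample_id,
                                  reference = y,
                                  cv_predicted = report$cv_predictions,
                                  config_hash = hash),
                       p_cv, row.names = FALSE)
      written <- c(written, p_cv)
      p_sc <- file.path(cfg$out_dir, "predicted_vs_reference.csv")
      utils::write.csv(data.frame(sample_id = ds$design$sample_id,
                                  reference = y, calibrated = y_cal,
                                  cv_predicted = report$cv_predictions,
                                  config_hash = hash),
                       p_sc, row.names = FALSE)
      written <- c(written, p_sc)
      p_log <- file.path(cfg$out_dir, "run_log.txt")
      writeLines(c(
        paste0("config_hash: ", hash),
        paste0("seed: ", cfg$seed),
        sprintf("grid: %.1f-%.1f nm, %d channels", min(grid0), max(grid0),
                length(grid0)),
        paste0("n: ", report$n),
        paste0("k_star: ", res$sel$k),
        paste0("preprocess: ", paste(cfg$preprocess, collapse = "+"),
               if (cfg$msc_per_fold) " (msc per fold)" else ""),
        paste0("analyte: ", cfg$analyte, " [", cfg$basis, "]"),
        "config:", deparse(cfg)), p_log)
      written <- c(written, p_log)
      paths <- written
    }, error = function(e) {
      on_fail()
      stop("[output] ", conditionMessage(e), call. = FALSE)
    })
  }
  list(report = report, k = res$sel$k, secv_curve = res$sel$secv,
       model = model, n = report$n, y = y, y_cal = y_cal, dataset = ds,
       config_hash = hash, paths = paths)
}

#' Validate a spectra + metadata file pair
#'
#' Reads both files, checks alignment, and returns a small summary; errors
#' carry the offending sample IDs.
#'
#' @param spectra_csv Path to the wide spectra CSV.
#' @param meta_csv Path to the long metadata CSV.
#' @return List: `n_samples`, `n_channels`, `grid_span`, `analytes`.
#' @export
validate_dataset <- function(spectra_csv, meta_csv) {
  ds <- join_metadata(read_spectra_csv(spectra_csv),
                      read_sample_meta(meta_csv))
  list(n_samples = nrow(ds$spectra$absorbance),
       n_channels = length(ds$spectra$grid),
       grid_span = range(as.numeric(ds$spectra$grid)),
       analytes = unique(paste(ds$values$analyte, ds$values$basis,
                               sep = "_")))
}
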