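#' Gaussian absorption band of a chemical component
#'
#' Synthetic spectra are built Beer-Lambert style as sums of Gaussian
#' bands, linear in concentration. Band shape is a modelling convention,
#' not a spectroscopic fit.
#'
#' @param center_nm Band center in nm.
#' @param width_nm Gaussian sigma in nm, > 0.
#' @param amplitude Absorbance per unit concentration at the band center
#'   (may be negative, e.g. for depletion of a water species).
#' @return Object of class `component_band`.
#' @export
component_band <- function(center_nm, width_nm, amplitude) {
  if (width_nm <= 0) stop("band width must be > 0", call. = FALSE)
  structure(list(center_nm = center_nm, width_nm = width_nm,
                 amplitude = amplitude), class = "component_band")
}

#' Evaluate a set of component bands on a wavelength grid
#'
#' Sum of Gaussians `amplitude * exp(-(lambda - center)^2 / (2 width^2))`,
#' exactly linear in the amplitudes. An empty band list gives the zero
#' vector.
#'
#' @param bands List of [component_band()] objects.
#' @param grid Wavelength grid (nm).
#' @return Numeric vector, one absorbance value per grid channel.
#' @export
pure_spectrum <- function(bands, grid) {
  grid <- as.numeric(grid)
  out <- numeric(length(grid))
  for (b in bands) {
    stopifnot(inherits(b, "component_band"))
    if (b$center_nm < min(grid) || b$center_nm > max(grid))
      stop("band center ", b$center_nm, " nm outside grid span",
           call. = FALSE)
    out <- out + b$amplitude *
      exp(-(grid - b$center_nm)^2 / (2 * b$width_nm^2))
  }
  out
}

#' Configuration of the synthetic purslane NIR study
#'
#' Encodes the statistical structure the analysis assumes: water-dominated
#' absorbance on a 512-channel 900-1700 nm grid, oxalate absorption bands
#' at the wavelengths where fresh-sample second-derivative spectra differ
#' (980, 1162, 1408, 1425, 1448, 1470 nm), an oxalate-dependent shift of
#' spectral weight from a free-water band (~1375 nm) to a bound-water band
#' (~1460 nm), per-sample multiplicative/additive scatter, i.i.d. noise
#' fixed by a signal-to-noise ratio, and the study design of 4 populations
#' x 3 monthly series x 3 treatments (36 composite samples). Group
#' dry-matter oxalate levels and the treatment-specific fresh-weight
#' ranges and moisture ranges reproduce the reported study conditions.
#'
#' @param grid Wavelength grid; default 512 channels over 900-1700 nm.
#' @param components Named list: analyte -> list of [component_band()].
#' @param water_bands Bands of the bulk water background (scaled by
#'   moisture fraction).
#' @param snr Signal-to-noise ratio: noise SD = SD of the analyte signal
#'   contribution across the dataset divided by `snr`. Default 20.
#' @param noise_sd Optional explicit noise SD overriding `snr`.
#' @param sigma_log_gain SD of the per-sample log multiplicative gain.
#' @param sigma_offset SD of the per-sample additive offset.
#' @param conc_ranges Named list of fresh-weight oxalate ranges (g/100 g)
#'   per treatment.
#' @param moisture_ranges Named list of moisture percentage ranges per
#'   treatment.
#' @param group_dm data.frame of the generating dry-matter oxalate group
#'   parameters: `series`, `treatment`, `mean`, `sd` (g/100 g DM).
#' @param populations Population labels (replicates within each group).
#' @return Object of class `synth_config`.
#' @export
synth_config <- function(
    grid = seq(900, 1700, length.out = 512),
    components = list(
      oxalate = c(
        lapply(c(980, 1162, 1408, 1425, 1448, 1470), function(cn)
          component_band(cn, 15, 0.002)),
        list(component_band(1375, 30, -0.008),   # free-water depletion
             component_band(1460, 40,  0.008)))  # bound-water growth
    ),
    water_bands = list(component_band(970, 45, 0.40),
                       component_band(1190, 50, 0.50),
                       component_band(1450, 55, 1.00)),
    snr = 20,
    noise_sd = NULL,
    sigma_log_gain = 0.05,
    sigma_offset = 0.01,
    conc_ranges = list(fresh = c(2.52, 7.97),
                       blanched = c(0.73, 4.35),
                       pickled = c(1.58, 5.05)),
    moisture_ranges = list(fresh = c(88.4, 92.4),
                           blanched = c(87.8, 93.7),
                           pickled = c(75.7, 83.8)),
    group_dm = data.frame(
      series = rep(1:3, each = 3),
      treatment = rep(c("fresh", "blanched", "pickled"), 3),
      mean = c(61.84, 19.07, 10.48,
               33.38, 22.29, 17.40,
               34.60, 34.36, 18.31),
      sd = c(17.99, 7.90, 3.46,
             3.85, 6.00, 5.44,
             4.91, 1.88, 4.65)),
    populations = c("P1", "P2", "P3", "P4")) {
  stopifnot(all(vapply(water_bands, inherits, logical(1),
                       "component_band")))
  for (r in conc_ranges)
    if (any(r <= 0)) stop("concentration ranges must be positive",
                          call. = FALSE)
  structure(list(grid = wavelength_grid(grid), components = components,
                 water_bands = water_bands, snr = snr,
                 noise_sd = noise_sd,
                 sigma_log_gain = sigma_log_gain,
                 sigma_offset = sigma_offset,
                 conc_ranges = conc_ranges,
                 moisture_ranges = moisture_ranges,
                 group_dm = group_dm, populations = populations),
            class = "synth_config")
}

# run code with a locally seeded RNG, restoring global state afterwards
with_seed <- function(seed, code) {
  if (is.null(seed)) stop("a seed is mandatory for generation", call. = FALSE)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv())
  on.exit(if (had) assign(".Random.seed", old, envir = globalenv())
          else suppressWarnings(rm(".Random.seed", envir = globalenv())))
  set.seed(as.integer(seed))
  force(code)
}

#' Simulate NIR spectra from known concentrations
#'
#' Builds `A = moisture/100 * water + C %*% S` (S = pure component
#' spectra), then applies per-sample multiplicative gain
#' (`exp(N(0, sigma_log_gain))`), additive offset (`N(0, sigma_offset)`)
#' and i.i.d. Gaussian channel noise. The noise SD is the SD of the
#' concentration-dependent signal `C %*% S` divided by `cfg$snr` unless
#' `cfg$noise_sd` is set. Bit-identical output for a fixed seed.
#'
#' @param concentrations Matrix n x m, columns named by analyte
#'   (fresh-weight g/100 g); all values >= 0.
#' @param cfg A [synth_config()].
#' @param seed Integer seed (mandatory).
#' @param moisture_pct Moisture percentage per sample; default midpoint of
#'   the fresh range.
#' @param sample_ids Sample identifiers; default `"s01"...`.
#' @param design Optional data.frame with per-sample `population`,
#'   `series`, `treatment` (defaults: `"P1"`, 1, `"fresh"`).
#' @return List: `spectra` (a [spectra_set()]), `meta` (a [sample_meta()]
#'   recording the true concentrations, basis `"fw"`, and moisture).
#' @export
simulate_spectra <- function(concentrations, cfg = synth_config(), seed,
                             moisture_pct = NULL, sample_ids = NULL,
                             design = NULL) {
  C <- as.matrix(concentrations)
  if (is.null(colnames(C)))
    colnames(C) <- names(cfg$components)[seq_len(ncol(C))]
  miss <- setdiff(colnames(C), names(cfg$components))
  if (length(miss))
    stop("no component bands for analyte(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  if (any(C < 0)) stop("concentrations must be >= 0", call. = FALSE)
  n <- nrow(C)
  grid <- as.numeric(cfg$grid)
  if (is.null(moisture_pct))
    moisture_pct <- rep(mean(cfg$moisture_ranges$fresh), n)
  moisture_pct <- rep_len(moisture_pct, n)
  if (is.null(sample_ids)) sample_ids <- sprintf("s%02d", seq_len(n))
  S <- t(vapply(colnames(C), function(a)
    pure_spectrum(cfg$components[[a]], grid), numeric(length(grid))))
  water <- pure_spectrum(cfg$water_bands, grid)
  signal <- C %*% S
  base <- (moisture_pct / 100) %o% water + signal
  noise_sd <- if (!is.null(cfg$noise_sd)) cfg$noise_sd
              else stats::sd(as.vector(signal)) / cfg$snr
  A <- with_seed(seed, {
    gain <- exp(stats::rnorm(n, 0, cfg$sigma_log_gain))
    offset <- stats::rnorm(n, 0, cfg$sigma_offset)
    noise <- matrix(stats::rnorm(n * length(grid), 0, noise_sd),
                    n, length(grid))
    base * gain + offset + noise
  })
  spectra <- spectra_set(cfg$grid, A, sample_ids, provenance = "raw")
  if (is.null(design))
    design <- data.frame(population = "P1", series = 1L,
                         treatment = "fresh")
  des <- data.frame(sample_id = sample_ids,
                    population = rep_len(design$population, n),
                    series = rep_len(design$series, n),
                    treatment = rep_len(design$treatment, n),
                    moisture_pct = moisture_pct,
                    stringsAsFactors = FALSE)
  vals <- do.call(rbind, lapply(colnames(C), function(a)
    data.frame(sample_id = sample_ids, analyte = a, basis = "fw",
               value = C[, a], stringsAsFactors = FALSE)))
  list(spectra = spectra, meta = sample_meta(des, vals))
}

#' Simulate the full purslane study
#'
#' Draws dry-matter oxalate values for every series x treatment group from
#' the configured group means/SDs (truncated at zero by resampling, with
#' the resample count recorded), one replicate per population, samples a
#' moisture percentage from the treatment's range, converts to a
#' fresh-weight concentration, and synthesizes spectra. With the default
#' design this yields 4 populations x 3 series x 3 treatments = 36
#' composite samples, 4 replicates per series/treatment group.
#'
#' @param cfg A [synth_config()].
#' @param seed Integer seed (mandatory).
#' @return List: `spectra`, `meta` (reference oxalate on both `"dm"` and
#'   `"fw"` bases), `dataset` (the joined `nir_dataset`),
#'   `group_summaries` (series, treatment, mean, sd, n of the dry-matter
#'   draws), `truncation_resamples` (count).
#' @export
simulate_study <- function(cfg = synth_config(), seed) {
  gd <- cfg$group_dm
  npop <- length(cfg$populations)
  resamples <- 0L
  out <- with_seed(seed, {
    rows <- NULL
    for (i in seq_len(nrow(gd))) {
      dm <- stats::rnorm(npop, gd$mean[i], gd$sd[i])
      while (any(dm <= 0)) {
        bad <- dm <= 0
        resamples <- resamples + sum(bad)
        dm[bad] <- stats::rnorm(sum(bad), gd$mean[i], gd$sd[i])
      }
      mr <- cfg$moisture_ranges[[gd$treatment[i]]]
      moist <- stats::runif(npop, mr[1], mr[2])
      rows <- rbind(rows, data.frame(
        population = cfg$populations, series = gd$series[i],
        treatment = gd$treatment[i], oxalate_dm = dm,
        moisture_pct = moist, stringsAsFactors = FALSE))
    }
    rows$oxalate_fw <- dm_to_fw(rows$oxalate_dm, rows$moisture_pct)
    rows
  })
  ids <- sprintf("%s_S%d_%s", out$population, out$series,
                 substr(out$treatment, 1, 2))
  # spectra seed is derived so the two generation stages stay independent
  sim <- simulate_spectra(
    matrix(out$oxalate_fw, ncol = 1,
           dimnames = list(NULL, "oxalate")),
    cfg, seed = (as.integer(seed) + 104729L) %% 2147483647L,
    moisture_pct = out$moisture_pct, sample_ids = ids,
    design = out[c("population", "series", "treatment")])
  vals_dm <- data.frame(sample_id = ids, analyte = "oxalate",
                        basis = "dm", value = out$oxalate_dm,
                        stringsAsFactors = FALSE)
  meta <- sample_meta(sim$meta$design, rbind(sim$meta$values, vals_dm))
  agg <- stats::aggregate(oxalate_dm ~ series + treatment, data = out,
                          function(v) c(mean = mean(v), sd = stats::sd(v),
                                        n = length(v)))
  gs <- data.frame(series = agg$series, treatment = agg$treatment,
                   mean = agg$oxalate_dm[, "mean"],
                   sd = agg$oxalate_dm[, "sd"],
                   n = as.integer(agg$oxalate_dm[, "n"]),
                   stringsAsFactors = FALSE)
  gs <- gs[order(gs$series, match(gs$treatment,
                                  c("fresh", "blanched", "pickled"))), ]
  rownames(gs) <- NULL
  list(spectra = sim$spectra, meta = meta,
       dataset = join_metadata(sim$spectra, meta),
       group_summaries = gs, truncation_resamples = resamples)
}
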