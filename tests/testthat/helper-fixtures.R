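# in-code fixtures shared across test files

# small random spectra set on a uniform grid
toy_spectra <- function(n = 5, p = 40, seed = 1, lo = 1000, hi = 1390) {
  set.seed(seed)
  grid <- seq(lo, hi, length.out = p)
  base <- 0.5 + 0.4 * exp(-(grid - mean(grid))^2 / (2 * 80^2))
  A <- t(sapply(seq_len(n), function(i)
    base * runif(1, 0.8, 1.2) + rnorm(1, 0, 0.05) +
      0.02 * sin(grid / runif(1, 20, 60)) + rnorm(p, 0, 0.002)))
  spectra_set(grid, A, sprintf("s%d", seq_len(n)))
}

# long-format metadata matching toy_spectra IDs
toy_meta <- function(ids, oxalate_dm = seq_along(ids) + 10) {
  design <- data.frame(sample_id = ids, population = "P1", series = 1L,
                       treatment = "fresh", moisture_pct = 90,
                       stringsAsFactors = FALSE)
  values <- data.frame(sample_id = ids, analyte = "oxalate", basis = "dm",
                       value = oxalate_dm, stringsAsFactors = FALSE)
  sample_meta(design, values)
}

# group summaries as printed for the three-series treatment comparison
study_summaries <- function() {
  data.frame(
    series = rep(1:3, each = 3),
    treatment = rep(c("fresh", "blanched", "pickled"), 3),
    mean = c(61.84, 19.07, 10.48,
             33.38, 22.29, 17.40,
             34.60, 34.36, 18.31),
    sd = c(17.99, 7.90, 3.46,
           3.85, 6.00, 5.44,
           4.91, 1.88, 4.65),
    n = 4L, stringsAsFactors = FALSE)
}

# raw replicates with exactly a prescribed mean and sd (n = 4)
raw_from_summary <- function(m, s, n = 4) {
  v <- scale(seq_len(n))[, 1]       # mean 0, sd 1
  m + s * v
}
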