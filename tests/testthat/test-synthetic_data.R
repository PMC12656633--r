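test_that("pure spectra are Gaussian sums, linear in amplitude", {
  grid <- seq(900, 1700, length.out = 161)  # 5 nm steps, centers on-grid
  b1 <- component_band(1450, 15, 1)
  v1 <- pure_spectrum(list(b1), grid)
  expect_equal(v1[grid == 1450], 1)
  expect_equal(which.max(v1), which(grid == 1450))
  expect_equal(pure_spectrum(list(), grid), numeric(161))
  b2 <- component_band(1200, 30, 0.4)
  both <- pure_spectrum(list(b1, b2), grid)
  expect_equal(both, v1 + pure_spectrum(list(b2), grid), tolerance = 1e-15)
  expect_error(component_band(1450, 0, 1), "width")
  expect_error(pure_spectrum(list(component_band(500, 10, 1)), grid),
               "outside grid")
})

test_that("noise- and scatter-free simulation is exactly linear", {
  cfg <- synth_config(noise_sd = 0, sigma_log_gain = 0, sigma_offset = 0)
  conc <- matrix(c(1, 2, 4), ncol = 1, dimnames = list(NULL, "oxalate"))
  sim <- simulate_spectra(conc, cfg, seed = 1, moisture_pct = 90)
  grid <- as.numeric(cfg$grid)
  water <- pure_spectrum(cfg$water_bands, grid)
  oxa <- pure_spectrum(cfg$components$oxalate, grid)
  for (i in 1:3)
    expect_lt(max(abs(sim$spectra$absorbance[i, ] -
                        (0.9 * water + conc[i] * oxa))), 1e-12)
  # doubling concentration doubles the analyte contribution exactly
  d21 <- sim$spectra$absorbance[2, ] - sim$spectra$absorbance[1, ]
  expect_lt(max(abs((sim$spectra$absorbance[3, ] -
                       sim$spectra$absorbance[2, ]) - 2 * d21)), 1e-10)
})

test_that("simulation is reproducible and validates inputs", {
  conc <- matrix(runif(8, 1, 6), ncol = 1, dimnames = list(NULL, "oxalate"))
  a <- simulate_spectra(conc, synth_config(), seed = 99)
  b <- simulate_spectra(conc, synth_config(), seed = 99)
  expect_identical(a$spectra$absorbance, b$spectra$absorbance)
  c2 <- simulate_spectra(conc, synth_config(), seed = 100)
  expect_false(identical(a$spectra$absorbance, c2$spectra$absorbance))
  expect_error(simulate_spectra(matrix(-1, 1, 1,
                                       dimnames = list(NULL, "oxalate")),
                                synth_config(), seed = 1), ">= 0")
  expect_error(simulate_spectra(matrix(1, 1, 1,
                                       dimnames = list(NULL, "citrate")),
                                synth_config(), seed = 1), "citrate")
  # generation does not disturb the global RNG stream
  set.seed(7); before <- runif(3)
  set.seed(7); invisible(runif(1))
  invisible(simulate_spectra(conc, synth_config(), seed = 5))
  expect_identical(c(runif(2)), before[2:3])
})

test_that("MSC recovers the scatter-free spectrum up to affine ambiguity", {
  cfg <- synth_config(noise_sd = 0)
  conc <- matrix(runif(12, 2, 8), ncol = 1,
                 dimnames = list(NULL, "oxalate"))
  clean <- simulate_spectra(conc,
                            synth_config(noise_sd = 0, sigma_log_gain = 0,
                                         sigma_offset = 0),
                            seed = 55, moisture_pct = 90)
  scattered <- simulate_spectra(conc, cfg, seed = 55, moisture_pct = 90)
  corrected <- msc(scattered$spectra)
  for (i in 1:12)
    expect_gt(cor(corrected$absorbance[i, ], clean$spectra$absorbance[i, ]),
              0.999)
})

test_that("the simulated study reproduces the design and both bases", {
  st <- simulate_study(seed = 7)
  expect_equal(nrow(st$spectra$absorbance), 36)
  gs <- st$group_summaries
  expect_equal(nrow(gs), 9)
  expect_true(all(gs$n == 4))
  expect_setequal(unique(st$meta$design$population),
                  c("P1", "P2", "P3", "P4"))
  expect_setequal(unique(st$meta$design$treatment),
                  c("fresh", "blanched", "pickled"))
  fw <- reference_values(st$dataset, "oxalate", "fw")
  dm <- reference_values(st$dataset, "oxalate", "dm")
  moist <- st$dataset$design$moisture_pct
  expect_lt(max(abs(fw - dm_to_fw(dm, moist))), 1e-12)
  # moisture stays within the treatment-specific ranges
  fresh <- st$dataset$design$treatment == "fresh"
  expect_true(all(moist[fresh] >= 88.4 & moist[fresh] <= 92.4))
  pick <- st$dataset$design$treatment == "pickled"
  expect_true(all(moist[pick] >= 75.7 & moist[pick] <= 83.8))
  expect_identical(simulate_study(seed = 7)$spectra$absorbance,
                   st$spectra$absorbance)
})

test_that("generating group means order fresh > blanched >= pickled", {
  gd <- synth_config()$group_dm
  for (s in 1:3) {
    m <- gd$mean[gd$series == s]
    names(m) <- gd$treatment[gd$series == s]
    expect_gt(m["fresh"], m["blanched"])
    expect_gte(m["blanched"], m["pickled"])
  }
})

test_that("simulated group summaries recover the generating effect sizes", {
  # with n = 4 per group a single draw's eta^2 is noisy, so the envelope
  # is checked on the per-series median over 20 seeded replicates
  gd <- synth_config()$group_dm
  devs <- matrix(NA_real_, 20, 3)
  for (s in 1:20) {
    st <- simulate_study(seed = s)
    for (ser in 1:3) {
      gs <- st$group_summaries[st$group_summaries$series == ser, ]
      eta <- anova_from_summaries(gs$mean, gs$sd, gs$n)$eta_squared
      gen <- gd[gd$series == ser, ]
      devs[s, ser] <-
        eta - anova_from_summaries(gen$mean, gen$sd, 4)$eta_squared
    }
  }
  expect_true(all(abs(apply(devs, 2, median)) <= 0.15))
})

test_that("more noise degrades cross-validated accuracy", {
  med_r <- sapply(c(10, 2, 0.5), function(snr) {
    rs <- sapply(1:5, function(s) {
      cfg <- synth_config(snr = snr)
      set.seed(400 + s)
      conc <- matrix(runif(24, 0.73, 7.97), ncol = 1,
                     dimnames = list(NULL, "oxalate"))
      sim <- simulate_spectra(conc, cfg, seed = 400 + s)
      loocv(msc(sim$spectra)$absorbance, conc[, 1], 3)$r_cval
    })
    median(rs)
  })
  expect_true(all(diff(med_r) < 0))
})
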