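test_that("the water baseline is deterministic with the documented structure", {
  grid <- seq(1100, 1850, by = 0.5)
  b1 <- water_baseline(grid)
  b2 <- water_baseline(grid)
  expect_identical(b1, b2)
  expect_gt(b1[grid == 1450], b1[grid == 1300])
  expect_error(water_baseline(seq(900, 1500, 0.5)),
               class = "aquaphot_parameter_error")
  # stripping the broad band leaves exactly the twelve C sub-band
  # Gaussians; closely spaced neighbours (10-14 nm apart at sd 8 nm)
  # merge, so peaks are checked against the construction, not counted
  residual <- b1 - exp(-0.5 * ((grid - 1450) / 60)^2)
  mids <- band_midpoints()[paste0("C", 1:12)]
  expected <- Reduce(`+`, lapply(mids, function(mu)
    0.05 * exp(-0.5 * ((grid - mu) / 8)^2)))
  expect_equal(residual, expected, tolerance = 1e-12)
  pk <- detect_peaks(residual, grid, min_prominence = 0.05)
  pk <- pk[pk$sign == "positive", ]
  expect_gte(nrow(pk), 3)
  expect_true(all(vapply(pk$wavelength,
                         function(w) min(abs(w - mids)) <= 8, logical(1))))
})

test_that("dose-response references follow the yield model", {
  cfg0 <- synthetic_config(seed = 2, dimer_noise_sd = 0)
  ref0 <- simulate_dose_response(cfg0)
  expect_equal(ref0$tt_conc,
               cfg0$dimer_yield * ref0$uvc_dose * ref0$dna_conc)
  expect_true(all(ref0$tt_conc[ref0$uvc_dose == 0] == 0))
  for (dna in c(10, 20)) {
    sub <- ref0[ref0$dna_conc == dna, ]
    r2 <- suppressWarnings(summary(lm(tt_conc ~ uvc_dose, sub))$r.squared)
    expect_equal(r2, 1)     # lm warns about the perfect noise-free fit
  }
  ref <- simulate_dose_response(synthetic_config(seed = 2))
  expect_true(all(ref$tt_conc >= 0))
  expect_equal(ref$class_label, ifelse(ref$uvc_dose > 0, "irradiated",
                                       "nonirradiated"))
})

test_that("the generator is bit-reproducible under a fixed config", {
  cfg <- synthetic_config(seed = 13, n_per_group = 1)
  a <- simulate_dataset(cfg)
  b <- simulate_dataset(cfg)
  expect_identical(a$spectra$absorbance, b$spectra$absorbance)
  expect_identical(a$reference, b$reference)
  # the reference table matches the standalone dose-response generator
  expect_identical(a$reference, simulate_dose_response(cfg))
  # a different seed changes the data
  c2 <- simulate_dataset(synthetic_config(seed = 14, n_per_group = 1))
  expect_false(identical(a$spectra$absorbance, c2$spectra$absorbance))
})

test_that("spectra are affine in each driver when noise terms vanish", {
  quiet <- function(effects) synthetic_config(
    seed = 5, n_per_group = 2,
    design = data.frame(dna_conc = c(10, 10), uvc_dose = c(20, 20)),
    band_effects = effects, dimer_noise_sd = 0, noise_sd = 0,
    baseline_offset_sd = 0, baseline_slope_sd = 0,
    confounder_amplitude_sd = 0)
  base_eff <- list(dna_conc = c(C5 = 4e-4, C11 = -4e-4),
                   tt_conc = c(C5 = -5e-3, C11 = 5e-3))
  sim <- simulate_dataset(quiet(base_eff))
  # equal drivers, zero noise: identical spectra
  expect_equal(sim$spectra$absorbance[1, ], sim$spectra$absorbance[2, ],
               tolerance = 1e-15)
  # doubling one band effect adds exactly one more scaled band Gaussian
  dbl_eff <- base_eff
  dbl_eff$dna_conc["C5"] <- 8e-4
  sim2 <- simulate_dataset(quiet(dbl_eff))
  diff <- sim2$spectra$absorbance[1, ] - sim$spectra$absorbance[1, ]
  grid <- sim$spectra$wavelengths
  tab <- default_band_table()
  c5 <- tab[tab$name == "C5", ]
  gauss <- exp(-0.5 * ((grid - (c5$lo + c5$hi) / 2) / ((c5$hi - c5$lo) / 4))^2)
  expect_equal(diff, 4e-4 * 10 * gauss, tolerance = 1e-12)
})

test_that("unknown band names in effects are a config error", {
  expect_error(synthetic_config(band_effects = list(dna_conc = c(C99 = 1))),
               class = "aquaphot_config_error")
  expect_error(synthetic_config(noise_sd = -1),
               class = "aquaphot_parameter_error")
})

test_that("the confounder is generated independently of the response", {
  cfg <- synthetic_config(seed = 19,
                          design = expand.grid(dna_conc = 20,
                                               uvc_dose = c(0, 5, 10, 15, 20)),
                          n_per_group = 8, confounder_amplitude_sd = 0.05)
  sim <- simulate_dataset(cfg)
  conf_shape <- exp(-0.5 * ((sim$spectra$wavelengths - 1750) / 40)^2)
  conf_scores <- as.numeric(sim$spectra$absorbance %*% conf_shape)
  expect_lt(abs(cor(conf_scores, sim$reference$tt_conc)), 0.3)
})
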