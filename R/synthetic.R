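#' Configuration for the synthetic NIR spectra generator
#'
#' Bundles every parameter of the seeded generator: the wavelength grid,
#' the experimental design (DNA concentration x UVC dose cells with
#' replicates), the photoproduct yield model, and the spectral effect
#' model (signed water-band perturbations per driver, instrument noise,
#' baseline drift, and a response-independent confounder component).
#'
#' Default band effects encode the qualitative aquaphotomic picture the
#' generator emulates: dissolved DNA raises absorbance in the free-water
#' band C5 (S0) and lowers it in the strongly hydrogen-bonded band C11
#' (S4), while cyclobutane-dimer formation does the reverse. All
#' magnitudes are invented generator defaults, not physical claims.
#'
#' @param seed integer seed fixing the full output bit-for-bit.
#' @param wavelength_range grid limits in nm (default 1100-1850).
#' @param step grid spacing in nm (default 0.5).
#' @param n_per_group replicates per design cell.
#' @param design `data.frame` with columns `dna_conc` (uM) and `uvc_dose`
#'   (kJ/m2); default the full factorial of concentrations
#'   {5, 10, 15, 20} uM and doses {0, 5, 10, 15, 20} kJ/m2.
#' @param band_effects list with elements `dna_conc` and `tt_conc`, each
#'   a named vector of signed absorbance effects (AU per uM) placed at
#'   water-band centers; names must exist in `band_table`.
#' @param dimer_yield cyclobutane-dimer yield in uM per (kJ/m2 x uM DNA).
#' @param dimer_noise_sd sd (uM) of the truncated-at-zero Gaussian noise
#'   on the generated dimer concentrations.
#' @param noise_sd per-wavelength white-noise sd (AU).
#' @param baseline_offset_sd sd of the per-sample baseline offset (AU).
#' @param baseline_slope_sd sd of the per-sample baseline slope (AU/nm).
#' @param confounder_amplitude_sd sd of the per-sample amplitude of the
#'   response-independent confounder component (AU).
#' @param confounder_shape optional per-wavelength shape vector of the
#'   confounder; default a broad Gaussian at 1750 nm (sd 40 nm, unit
#'   peak), far from the C bands.
#' @param band_table band table used to resolve band names (default
#'   [default_band_table()]).
#' @return an object of class `synthetic_config`.
#' @export
synthetic_config <- function(seed = 1,
                             wavelength_range = c(1100, 1850),
                             step = 0.5,
                             n_per_group = 2,
                             design = expand.grid(dna_conc = c(5, 10, 15, 20),
                                                  uvc_dose = c(0, 5, 10, 15, 20)),
                             band_effects = list(
                               dna_conc = c(C5 = 4e-4, C11 = -4e-4),
                               tt_conc = c(C5 = -5e-3, C11 = 5e-3)),
                             dimer_yield = 0.005,
                             dimer_noise_sd = 0.14,
                             noise_sd = 5e-4,
                             baseline_offset_sd = 1e-3,
                             baseline_slope_sd = 2e-6,
                             confounder_amplitude_sd = 1e-3,
                             confounder_shape = NULL,
                             band_table = default_band_table()) {
  grid <- seq(wavelength_range[1], wavelength_range[2], by = step)
  validate_wavelength_grid(grid)
  design <- as.data.frame(design)
  stopifnot(all(c("dna_conc", "uvc_dose") %in% names(design)))
  sds <- c(dimer_noise_sd, noise_sd, baseline_offset_sd, baseline_slope_sd,
           confounder_amplitude_sd)
  if (any(sds < 0))
    .stop2("aquaphot_parameter_error", "sd parameters must be >= 0")
  for (driver in names(band_effects)) {
    unknown <- setdiff(names(band_effects[[driver]]), band_table$name)
    if (length(unknown))
      .stop2("aquaphot_config_error", "unknown band name(s) in band_effects$%s: %s",
             driver, paste(unknown, collapse = ", "))
  }
  structure(list(seed = as.integer(seed), grid = grid,
                 n_per_group = as.integer(n_per_group), design = design,
                 band_effects = band_effects, dimer_yield = dimer_yield,
                 dimer_noise_sd = dimer_noise_sd, noise_sd = noise_sd,
                 baseline_offset_sd = baseline_offset_sd,
                 baseline_slope_sd = baseline_slope_sd,
                 confounder_amplitude_sd = confounder_amplitude_sd,
                 confounder_shape = confounder_shape,
                 band_table = band_table,
                 generator = list(algorithm = "base-R Mersenne-Twister rnorm",
                                  draw_order = c("tt_noise (all samples)",
                                                 "per sample: offset, slope, confounder amplitude, noise vector"))),
            class = "synthetic_config")
}

#' Deterministic pseudo-water absorbance baseline
#'
#' A fixed stand-in for the first overtone of water: one broad Gaussian
#' band centered at 1450 nm (amplitude 1 AU, sd 60 nm) plus twelve small
#' sub-bands (amplitude 0.05 AU, sd 8 nm) at the C1-C12 band midpoints.
#' Contains no randomness.
#'
#' @param grid wavelength vector in nm, within 1000-2000 nm.
#' @return numeric absorbance vector on `grid`.
#' @export
water_baseline <- function(grid) {
  grid <- as.numeric(grid)
  if (min(grid) < 1000 || max(grid) > 2000)
    .stop2("aquaphot_parameter_error",
           "water baseline is defined for 1000-2000 nm (grid %g-%g)",
           min(grid), max(grid))
  base <- exp(-0.5 * ((grid - 1450) / 60)^2)
  mids <- band_midpoints()[paste0("C", 1:12)]
  for (mu in mids) base <- base + 0.05 * exp(-0.5 * ((grid - mu) / 8)^2)
  base
}

# reference table; assumes the RNG has already been seeded
.make_reference <- function(config) {
  design <- config$design[rep(seq_len(nrow(config$design)),
                              each = config$n_per_group), , drop = FALSE]
  n <- nrow(design)
  tt_base <- config$dimer_yield * design$uvc_dose * design$dna_conc
  z <- rnorm(n)
  tt <- pmax(0, tt_base + z * config$dimer_noise_sd)
  data.frame(sample_id = sprintf("S%03d", seq_len(n)),
             dna_conc = design$dna_conc,
             uvc_dose = design$uvc_dose,
             tt_conc = tt,
             class_label = ifelse(design$uvc_dose > 0, "irradiated",
                                  "nonirradiated"),
             batch = sprintf("B%d", ((seq_len(n) - 1) %% 9) + 1),
             stringsAsFactors = FALSE)
}

#' Simulate the dimer dose-response reference data
#'
#' Generates per-sample cyclobutane-dimer concentrations from the linear
#' yield model `tt = dimer_yield x dose x dna_conc` plus
#' truncated-at-zero Gaussian noise. With the default parameters, the
#' linear fit of dimer concentration on dose at a fixed DNA concentration
#' lands in the R^2 range typical of HPLC dose-response determinations
#' (roughly 0.85-0.97 at 10 samples per concentration).
#'
#' @param config a [synthetic_config()].
#' @return a `data.frame` (reference table) with `sample_id`, `dna_conc`,
#'   `uvc_dose`, `tt_conc`, `class_label`, `batch`.
#' @export
simulate_dose_response <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  set.seed(config$seed)
  .make_reference(config)
}

# unit-peak Gaussian at the band midpoint, sd = half-width / 2
.band_shape <- function(grid, band_row) {
  mu <- (band_row$lo + band_row$hi) / 2
  s <- (band_row$hi - band_row$lo) / 4
  exp(-0.5 * ((grid - mu) / s)^2)
}

#' Simulate a synthetic NIR spectra dataset
#'
#' Generates the full sample x wavelength dataset the analysis modules
#' consume. Each spectrum is the deterministic water baseline plus signed
#' Gaussian band perturbations driven by the sample's DNA concentration
#' and generated dimer concentration, a linear baseline drift, a
#' response-independent confounder component, and white noise:
#' `a(l) = baseline(l) + sum_b effect_b x driver x g_b(l) + offset +
#' slope x (l - l_mid) + amp x confounder(l) + noise(l)`.
#'
#' Random draws follow a fixed, documented order (dimer noise for all
#' samples first, then per sample: offset, slope, confounder amplitude,
#' noise vector), and every draw is taken as a standard normal scaled by
#' its sd, so the stream — and hence the output for a given seed — does
#' not depend on which sd parameters are zero.
#'
#' @param config a [synthetic_config()].
#' @return a list with `spectra` (a [spectra_set()] whose metadata holds
#'   the reference values) and `reference` (the reference table, equal to
#'   [simulate_dose_response()] for the same config).
#' @export
simulate_dataset <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  set.seed(config$seed)
  ref <- .make_reference(config)
  grid <- config$grid
  m <- length(grid)
  n <- nrow(ref)
  baseline <- water_baseline(grid)
  conf <- config$confounder_shape %||% exp(-0.5 * ((grid - 1750) / 40)^2)
  if (length(conf) != m)
    .stop2("aquaphot_config_error",
           "confounder_shape has length %d, grid has %d", length(conf), m)
  shapes <- list()
  for (driver in names(config$band_effects)) {
    eff <- config$band_effects[[driver]]
    G <- vapply(names(eff), function(b)
      .band_shape(grid, config$band_table[config$band_table$name == b, ]),
      numeric(m))
    shapes[[driver]] <- as.numeric(G %*% eff)  # combined effect shape, AU/uM
  }
  lambda_mid <- (grid[1] + grid[m]) / 2
  A <- matrix(0, n, m)
  for (i in seq_len(n)) {
    z_off <- rnorm(1); z_slope <- rnorm(1); z_amp <- rnorm(1)
    z_noise <- rnorm(m)
    spec <- baseline
    for (driver in names(shapes))
      spec <- spec + shapes[[driver]] * ref[[driver]][i]
    A[i, ] <- spec +
      config$baseline_offset_sd * z_off +
      config$baseline_slope_sd * z_slope * (grid - lambda_mid) +
      config$confounder_amplitude_sd * z_amp * conf +
      config$noise_sd * z_noise
  }
  spectra <- spectra_set(A, grid, ref)
  list(spectra = spectra, reference = ref)
}
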