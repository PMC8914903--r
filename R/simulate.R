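#' Default per-treatment leaf nutrient means
#'
#' Mass-fraction means (%) of nitrogen, phosphorus and potassium in leaves for
#' the three nitrogen fertilisation treatments N0 (none), N1 (low) and N2
#' (high). Only between-treatment ratios are anchored by field observation:
#' nitrogen rises under fertilisation then falls back at high rates
#' (N1/N0 = 1.28, N2/N0 = 1.13), while phosphorus and potassium uptake are
#' depressed by added nitrogen (P: N0/N1 = 1.47, N0/N2 = 1.93;
#' K: N0/N2 = 1.40, N1/N2 = 1.37). Absolute levels are set to typical leaf
#' mass fractions (N0 nitrogen 2.5%, N0 phosphorus 0.45%, N2 potassium 1.5%).
#'
#' @return Tibble with columns `treatment`, `nitrogen`, `phosphorus`,
#'   `potassium` (one row per treatment, in %).
#' @export
#' @examples
#' m <- default_nutrient_means()
#' m$nitrogen[m$treatment == "N1"] / m$nitrogen[m$treatment == "N0"] # 1.28
default_nutrient_means <- function() {
  n0_nitrogen <- 2.5
  n0_phosphorus <- 0.45
  n2_potassium <- 1.5
  tibble::tibble(
    treatment = c("N0", "N1", "N2"),
    nitrogen = n0_nitrogen * c(1, 1.28, 1.13),
    phosphorus = n0_phosphorus / c(1, 1.47, 1.93),
    potassium = n2_potassium * c(1.40, 1.37, 1)
  )
}

#' Shape parameters of the parametric leaf reflectance model
#'
#' The generator composes a leaf spectrum from a flat baseline, a green-peak
#' Gaussian near 550 nm, a chlorophyll absorption trough near 670 nm, a
#' logistic red edge rising to the near-infrared plateau, and narrow
#' nutrient-linked micro-features near 480, 610 and 820 nm that leave most of
#' their signature in the high-frequency detail of the curve. Amplitudes are
#' in reflectance units, positions and widths in nm.
#'
#' @param baseline Flat background reflectance.
#' @param green_amp0,green_amp_per_n Green-peak amplitude at zero nitrogen and
#'   its increase per % nitrogen.
#' @param green_center,green_width Green-peak position and Gaussian sd.
#' @param dip_amp0,dip_amp_per_n Red-valley (chlorophyll absorption) depth and
#'   its increase per % nitrogen.
#' @param dip_center,dip_width Red-valley position and Gaussian sd.
#' @param nir_amp Height of the near-infrared plateau above baseline.
#' @param red_edge_base Red-edge inflection wavelength at the reference
#'   nitrogen content (2.5%).
#' @param red_edge_width Logistic width of the red edge.
#' @param red_edge_shift_per_n Red-edge shift (nm) per % nitrogen above the
#'   reference content.
#' @param micro_p_amp,micro_k_amp,micro_n_amp Amplitudes of the narrow
#'   phosphorus- (480 nm), potassium- (610 nm) and nitrogen-linked (820 nm)
#'   micro-features at the reference nutrient levels.
#' @return Named list of parameters.
#' @export
leaf_params <- function(baseline = 0.08,
                        green_amp0 = 0.06, green_amp_per_n = 0.012,
                        green_center = 550, green_width = 20,
                        dip_amp0 = 0.035, dip_amp_per_n = 0.006,
                        dip_center = 670, dip_width = 14,
                        nir_amp = 0.42,
                        red_edge_base = 715, red_edge_width = 10,
                        red_edge_shift_per_n = 8,
                        micro_p_amp = 0.008, micro_k_amp = 0.008,
                        micro_n_amp = 0.006) {
  as.list(environment())
}

# reference nutrient levels the per-% terms are anchored to
.n_ref <- 2.5
.p_ref <- 0.45
.k_ref <- 2.1

# deterministic part of the reflectance curve (vectorised over wavelength)
leaf_curve <- function(wavelengths, nitrogen, phosphorus, potassium,
                       params = leaf_params(),
                       nuisance = list(red_edge = 0, baseline = 0,
                                       plateau = 0, green = 0, dip = 0)) {
  p <- params
  gauss <- function(center, width) exp(-(wavelengths - center)^2 / (2 * width^2))
  red_edge <- p$red_edge_base + p$red_edge_shift_per_n * (nitrogen - .n_ref) +
    nuisance$red_edge
  (p$baseline + nuisance$baseline) +
    (p$green_amp0 + p$green_amp_per_n * nitrogen + nuisance$green) *
      gauss(p$green_center, p$green_width) -
    (p$dip_amp0 + p$dip_amp_per_n * nitrogen + nuisance$dip) *
      gauss(p$dip_center, p$dip_width) +
    (p$nir_amp + nuisance$plateau) *
      stats::plogis((wavelengths - red_edge) / p$red_edge_width) +
    p$micro_p_amp * (phosphorus / .p_ref) * gauss(480, 4) +
    p$micro_k_amp * (potassium / .k_ref) * gauss(610, 4) +
    p$micro_n_amp * (nitrogen / .n_ref) * gauss(820, 5)
}

#' Simulate a single leaf reflectance spectrum
#'
#' @param nitrogen,phosphorus,potassium Nutrient contents (mass fraction, %);
#'   all must be positive.
#' @param wavelengths Strictly increasing wavelength grid in nm, within
#'   350-1100 nm.
#' @param noise_sd Standard deviation of additive homoscedastic Gaussian band
#'   noise (reflectance units).
#' @param params Curve shape parameters, see [leaf_params()].
#' @param nuisance Optional per-sample nuisance offsets (red-edge shift in nm,
#'   baseline/plateau/green/dip amplitude shifts) representing leaf-to-leaf
#'   structural variation unrelated to nutrient status.
#' @return One-row spectra tibble (`sample_id` plus one column per band).
#' @export
#' @examples
#' s <- simulate_leaf_spectrum(2.5, 0.45, 2.1, seq(400, 1000, by = 2))
simulate_leaf_spectrum <- function(nitrogen, phosphorus, potassium,
                                   wavelengths, noise_sd = 0,
                                   params = leaf_params(),
                                   nuisance = list(red_edge = 0, baseline = 0,
                                                   plateau = 0, green = 0,
                                                   dip = 0)) {
  if (any(c(nitrogen, phosphorus, potassium) <= 0)) {
    abort("nutrient contents must all be positive.")
  }
  if (any(wavelengths < 350 | wavelengths > 1100)) {
    abort("wavelength grid must lie within 350-1100 nm.")
  }
  if (is.unsorted(wavelengths, strictly = TRUE)) {
    abort("wavelength grid must be strictly increasing.")
  }
  if (noise_sd < 0) abort("`noise_sd` must be non-negative.")
  r <- leaf_curve(wavelengths, nitrogen, phosphorus, potassium, params, nuisance)
  if (noise_sd > 0) r <- r + stats::rnorm(length(r), 0, noise_sd)
  r <- pmin(pmax(r, 1e-6), 1 - 1e-6)
  spc_tibble(matrix(r, nrow = 1), wavelengths, sample_id = "spectrum")
}

#' Simulation configuration
#'
#' Defaults describe the emulated study: 72 leaf samples, 24 per nitrogen
#' treatment, reflectance on a 400-1000 nm grid of 1001 bands (0.6 nm
#' spacing), band noise sd 0.002 reflectance units, 4% within-treatment
#' coefficient of variation on nutrient contents, and leaf-to-leaf nuisance
#' variation (red-edge jitter 1.5 nm, baseline sd 0.006, plateau sd 0.015,
#' green/dip amplitude sd 0.004/0.003).
#'
#' @param n_per_treatment Samples per treatment.
#' @param wavelength_start,wavelength_end,n_bands Wavelength grid (nm). At
#'   least 707 bands so that all wavelet coefficient positions used in
#'   downstream selection exist on the grid.
#' @param noise_sd Additive band-noise sd (reflectance units), >= 0.
#' @param nutrient_means Per-treatment nutrient means, as from
#'   [default_nutrient_means()].
#' @param nutrient_cv Within-treatment coefficient of variation of each
#'   nutrient content (0 for exact treatment means).
#' @param nuisance_sd Named list of sds for per-sample nuisance offsets
#'   (`red_edge` in nm; `baseline`, `plateau`, `green`, `dip` in reflectance
#'   units). Set all to 0 for purely nutrient-driven spectra.
#' @param params Curve shape parameters, see [leaf_params()].
#' @param seed Integer seed making the whole dataset reproducible.
#' @return Config list of class `sim_config`.
#' @export
sim_config <- function(n_per_treatment = 24,
                       wavelength_start = 400, wavelength_end = 1000,
                       n_bands = 1001,
                       noise_sd = 0.002,
                       nutrient_means = default_nutrient_means(),
                       nutrient_cv = 0.04,
                       nuisance_sd = list(red_edge = 1.5, baseline = 0.006,
                                          plateau = 0.015, green = 0.004,
                                          dip = 0.003),
                       params = leaf_params(),
                       seed = NULL) {
  if (n_bands < 707) abort("`n_bands` must be at least 707.")
  if (wavelength_end <= wavelength_start) {
    abort("`wavelength_end` must exceed `wavelength_start`.")
  }
  if (noise_sd < 0) abort("`noise_sd` must be non-negative.")
  if (n_per_treatment < 1) abort("`n_per_treatment` must be at least 1.")
  stopifnot(all(c("treatment", "nitrogen", "phosphorus", "potassium") %in%
    names(nutrient_means)))
  structure(as.list(environment()), class = "sim_config")
}

#' Generate a synthetic leaf spectra dataset
#'
#' Draws per-sample nutrient contents around the per-treatment means, renders
#' one reflectance spectrum per sample with [simulate_leaf_spectrum()]'s
#' model, and returns spectra plus sample table. Fully reproducible under
#' `config$seed`.
#'
#' @param config A [sim_config()].
#' @return List of class `npk_dataset` with elements `spectra` (wide spectra
#'   tibble), `samples` (tibble `sample_id`, `treatment`, `nitrogen`,
#'   `phosphorus`, `potassium`) and `config`.
#' @export
#' @examples
#' ds <- simulate_npk_dataset(sim_config(seed = 1))
#' nrow(ds$samples) # 72
simulate_npk_dataset <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  wl <- seq(config$wavelength_start, config$wavelength_end,
    length.out = config$n_bands
  )
  with_seed_if(config$seed, {
    samples <- purrr::pmap_dfr(
      config$nutrient_means,
      function(treatment, nitrogen, phosphorus, potassium) {
        n <- config$n_per_treatment
        draw <- function(mu) {
          pmax(mu * (1 + config$nutrient_cv * stats::rnorm(n)), 0.05 * mu)
        }
        tibble::tibble(
          sample_id = sprintf("%s-%02d", treatment, seq_len(n)),
          treatment = treatment,
          nitrogen = draw(nitrogen),
          phosphorus = draw(phosphorus),
          potassium = draw(potassium)
        )
      }
    )
    ns <- config$nuisance_sd
    refl <- purrr::pmap(
      samples[c("nitrogen", "phosphorus", "potassium")],
      function(nitrogen, phosphorus, potassium) {
        nuis <- list(
          red_edge = stats::rnorm(1, 0, ns$red_edge),
          baseline = stats::rnorm(1, 0, ns$baseline),
          plateau = stats::rnorm(1, 0, ns$plateau),
          green = stats::rnorm(1, 0, ns$green),
          dip = stats::rnorm(1, 0, ns$dip)
        )
        r <- leaf_curve(wl, nitrogen, phosphorus, potassium, config$params, nuis)
        if (config$noise_sd > 0) {
          r <- r + stats::rnorm(length(r), 0, config$noise_sd)
        }
        pmin(pmax(r, 1e-6), 1 - 1e-6)
      }
    )
    spectra <- spc_tibble(do.call(rbind, refl), wl, sample_id = samples$sample_id)
    structure(list(spectra = spectra, samples = samples, config = config),
      class = "npk_dataset"
    )
  })
}

#' @export
print.npk_dataset <- function(x, ...) {
  wl <- spc_wavelengths(x$spectra)
  cat(sprintf(
    "<npk_dataset> %d samples (%s), %d bands %.4g-%.4g nm\n",
    nrow(x$samples),
    paste(sprintf("%s: %d", names(table(x$samples$treatment)),
      table(x$samples$treatment)
    ), collapse = ", "),
    length(wl), min(wl), max(wl)
  ))
  invisible(x)
}
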