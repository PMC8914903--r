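# Internal helpers for the wide spectra-tibble representation:
# first column `sample_id`, remaining numeric columns named by wavelength (nm).

assert_spectra <- function(spectra, arg = "spectra") {
  if (!is.data.frame(spectra) || !"sample_id" %in% names(spectra)) {
    abort(sprintf("`%s` must be a data frame with a `sample_id` column.", arg))
  }
  wl <- spc_wavelengths(spectra)
  if (length(wl) < 2) {
    abort(sprintf("`%s` must contain at least two wavelength columns.", arg))
  }
  if (anyNA(wl)) {
    abort(sprintf("`%s` has band columns whose names are not wavelengths.", arg))
  }
  if (is.unsorted(wl, strictly = TRUE)) {
    abort(sprintf("wavelength grid of `%s` must be strictly increasing.", arg))
  }
  invisible(spectra)
}

#' Wavelength grid of a spectra table
#'
#' @param spectra A spectra tibble: `sample_id` plus one numeric column per
#'   band, columns named by wavelength in nm.
#' @return Numeric vector of wavelengths.
#' @export
spc_wavelengths <- function(spectra) {
  suppressWarnings(as.numeric(band_cols(spectra)))
}

band_cols <- function(spectra) {
  nm <- names(spectra)
  nm[!nm %in% c("sample_id", "replicate", "treatment")]
}

# samples x bands numeric matrix, rownames = sample ids
spc_matrix <- function(spectra) {
  m <- as.matrix(spectra[band_cols(spectra)])
  rownames(m) <- spectra$sample_id
  storage.mode(m) <- "double"
  m
}

# rebuild a spectra tibble from a matrix and a wavelength grid
spc_tibble <- function(m, wavelengths, sample_id = rownames(m)) {
  colnames(m) <- format_wl(wavelengths)
  out <- tibble::as_tibble(m)
  tibble::add_column(out, sample_id = sample_id, .before = 1)
}

format_wl <- function(wl) sprintf("%.10g", wl)

#' Pivot a spectra table to long format
#'
#' Convenience for plotting: one row per (sample, band).
#'
#' @inheritParams spc_wavelengths
#' @return Tibble with columns `sample_id`, `wavelength`, `reflectance`.
#' @export
spc_longer <- function(spectra) {
  assert_spectra(spectra)
  tidyr::pivot_longer(spectra, dplyr::all_of(band_cols(spectra)),
    names_to = "wavelength", values_to = "reflectance"
  ) |>
    dplyr::mutate(wavelength = as.numeric(.data$wavelength))
}

# seed-scoped evaluation; NULL seed leaves the RNG stream alone
with_seed_if <- function(seed, code) {
  if (is.null(seed)) code else withr::with_seed(as.integer(seed), code)
}
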