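#' Read and write spectra tables
#'
#' Spectra are stored as tab-delimited text: first column `sample_id`,
#' remaining columns one per band with the wavelength (nm) as header.
#' Reference spectra may be included as rows tagged `WHITE` / `DARK`.
#'
#' @param spectra Spectra tibble.
#' @param path File path.
#' @return `read_spectra()` returns the spectra tibble; `write_spectra()`
#'   returns `path` invisibly.
#' @export
write_spectra <- function(spectra, path) {
  assert_spectra(spectra)
  readr::write_tsv(spectra, path)
  invisible(path)
}

#' @rdname write_spectra
#' @export
read_spectra <- function(path) {
  out <- readr::read_tsv(path,
    col_types = readr::cols(
      sample_id = readr::col_character(),
      .default = readr::col_double()
    ),
    progress = FALSE
  )
  assert_spectra(out)
  out
}

#' Read and write per-sample nutrient tables
#'
#' Tab-delimited text with columns `sample_id`, `treatment`, `nitrogen`,
#' `phosphorus`, `potassium` (contents as mass fraction, %).
#'
#' @param samples Sample tibble.
#' @param path File path.
#' @return `read_sample_table()` returns the tibble; the writer returns
#'   `path` invisibly.
#' @export
write_sample_table <- function(samples, path) {
  readr::write_tsv(samples, path)
  invisible(path)
}

#' @rdname write_sample_table
#' @export
read_sample_table <- function(path) {
  readr::read_tsv(path,
    col_types = readr::cols(
      sample_id = readr::col_character(),
      treatment = readr::col_character(),
      .default = readr::col_double()
    ),
    progress = FALSE
  )
}
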