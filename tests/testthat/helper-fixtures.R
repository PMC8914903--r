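# Shared fixtures built in code.

# wide spectra tibble from a matrix of curves
make_spectra <- function(m, wavelengths, ids = sprintf("S%02d", seq_len(nrow(m)))) {
  colnames(m) <- sprintf("%.10g", wavelengths)
  out <- tibble::as_tibble(m, .name_repair = "minimal")
  tibble::add_column(out, sample_id = ids, .before = 1)
}

# random smooth-ish spectra for wavelet property tests
random_spectra_matrix <- function(n_samples, n_bands) {
  t(replicate(n_samples, cumsum(stats::rnorm(n_bands, sd = 0.05)) + 0.5))
}

# noiseless, jitter-free simulation config (nutrient-driven signal only)
clean_sim_config <- function(...) {
  sim_config(
    noise_sd = 0, nutrient_cv = 0,
    nuisance_sd = list(red_edge = 0, baseline = 0, plateau = 0, green = 0,
                       dip = 0),
    ...
  )
}

# red-edge inflection by brute-force maximum of the first derivative
# on 680-760 nm
inflection_position <- function(spectrum_row) {
  wl <- npkspec::spc_wavelengths(spectrum_row)
  d <- npkspec::spectral_derivative(spectrum_row)
  dv <- unlist(d[1, setdiff(names(d), "sample_id")], use.names = FALSE)
  idx <- which(wl >= 680 & wl <= 760)
  wl[idx][which.max(dv[idx])]
}
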