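# Table of the classical spectral windows (nm) used by the edge/peak features
.feature_windows <- list(
  blue = c(490, 530),
  yellow = c(560, 640),
  red_edge = c(680, 760),
  green = c(510, 560),
  red_valley = c(650, 690)
)

#' First derivative of spectra with respect to wavelength
#'
#' Central differences `(R[i+1] - R[i-1]) / (lambda[i+1] - lambda[i-1])` on
#' interior bands, one-sided differences at the two ends; the derivative grid
#' is the input grid.
#'
#' @param spectra Spectra tibble (>= 3 bands, strictly increasing grid).
#' @return Tibble of the same shape, values in reflectance / nm.
#' @export
spectral_derivative <- function(spectra) {
  assert_spectra(spectra)
  wl <- spc_wavelengths(spectra)
  if (length(wl) < 3) abort("need at least 3 bands for a derivative.")
  if (anyDuplicated(wl)) abort("wavelength grid contains duplicate bands.")
  m <- spc_matrix(spectra)
  n <- ncol(m)
  d <- m
  d[, 1] <- (m[, 2] - m[, 1]) / (wl[2] - wl[1])
  d[, n] <- (m[, n] - m[, n - 1]) / (wl[n] - wl[n - 1])
  i <- 2:(n - 1)
  d[, i] <- sweep(m[, i + 1, drop = FALSE] - m[, i - 1, drop = FALSE], 2,
    wl[i + 1] - wl[i - 1], "/"
  )
  spc_tibble(d, wl, sample_id = spectra$sample_id)
}

#' Reflectance at (nearest to) a target wavelength
#'
#' Looks up the band whose wavelength is nearest `target_nm`; exact-distance
#' ties resolve to the lower wavelength.
#'
#' @param spectra Spectra tibble.
#' @param target_nm Target wavelength (must lie within the grid range).
#' @return Numeric vector, one value per sample.
#' @export
band_reflectance <- function(spectra, target_nm) {
  assert_spectra(spectra)
  wl <- spc_wavelengths(spectra)
  if (target_nm < min(wl) || target_nm > max(wl)) {
    abort(sprintf("target %.4g nm is outside the %.4g-%.4g nm grid.",
      target_nm, min(wl), max(wl)
    ))
  }
  idx <- which.min(abs(wl - target_nm)) # which.min takes the first (lower) tie
  unname(spc_matrix(spectra)[, idx])
}

window_idx <- function(wl, window) which(wl >= window[1] & wl <= window[2])

#' Extract the 24 spectral characteristic variables
#'
#' Computes, per sample: the blue/yellow/red edge amplitudes (maximum first
#' derivative in 490-530, 560-640 and 680-760 nm) and their wavelengths
#' (`D_b`/`lambda_b`, `D_y`/`lambda_y`, `D_r`/`lambda_r`); the green-peak
#' reflectance maximum over 510-560 nm (`R_g`/`lambda_g`) and red-valley
#' reflectance minimum over 650-690 nm (`R_r`/`lambda_o`); the trapezoid
#' areas of the curve over the blue, yellow, red-edge and green windows
#' (`SD_b`, `SD_y`, `SD_r`, `SD_g`); and ten vegetation indices `VI1`-`VI10`
#' built from those quantities and from the reflectances at 800, 750, 720,
#' 705, 680 and 445 nm.
#'
#' Window endpoints are inclusive and single bands are matched by nearest
#' wavelength. The green peak and red valley are reflectance extrema by
#' default; `extrema_on = "derivative"` reads them literally as
#' first-derivative extrema instead. Areas integrate the reflectance curve by
#' default; `area_on = "derivative"` integrates the first derivative.
#'
#' @param spectra Spectra tibble whose grid covers 445-800 nm.
#' @param extrema_on Curve used for the green-peak / red-valley extrema.
#' @param area_on Curve integrated for the `SD_*` areas.
#' @return Tibble: `sample_id` plus 24 feature columns.
#' @export
#' @examples
#' ds <- simulate_npk_dataset(sim_config(seed = 1))
#' feats <- extract_features(ds$spectra)
extract_features <- function(spectra,
                             extrema_on = c("reflectance", "derivative"),
                             area_on = c("reflectance", "derivative")) {
  extrema_on <- match.arg(extrema_on)
  area_on <- match.arg(area_on)
  assert_spectra(spectra)
  wl <- spc_wavelengths(spectra)
  if (min(wl) > 445 || max(wl) < 800) {
    abort("wavelength grid must cover 445-800 nm for feature extraction.")
  }
  missing <- names(Filter(
    function(w) length(window_idx(wl, w)) < 2, .feature_windows
  ))
  if (length(missing) > 0) {
    abort(paste0(
      "grid does not resolve the spectral window(s): ",
      paste(missing, collapse = ", ")
    ))
  }
  m <- spc_matrix(spectra)
  d <- spc_matrix(spectral_derivative(spectra))

  win_max <- function(mat, window) {
    idx <- window_idx(wl, window)
    sub <- mat[, idx, drop = FALSE]
    j <- max.col(sub, ties.method = "first")
    list(value = sub[cbind(seq_len(nrow(sub)), j)], wavelength = wl[idx][j])
  }
  win_min <- function(mat, window) {
    r <- win_max(-mat, window)
    list(value = -r$value, wavelength = r$wavelength)
  }
  win_area <- function(mat, window) {
    idx <- window_idx(wl, window)
    unname(apply(mat[, idx, drop = FALSE], 1,
      function(y) pracma::trapz(wl[idx], y)
    ))
  }

  blue <- win_max(d, .feature_windows$blue)
  yellow <- win_max(d, .feature_windows$yellow)
  red <- win_max(d, .feature_windows$red_edge)
  ext_mat <- if (extrema_on == "reflectance") m else d
  green <- win_max(ext_mat, .feature_windows$green)
  valley <- win_min(ext_mat, .feature_windows$red_valley)
  area_mat <- if (area_on == "reflectance") m else d
  sd_b <- win_area(area_mat, .feature_windows$blue)
  sd_y <- win_area(area_mat, .feature_windows$yellow)
  sd_r <- win_area(area_mat, .feature_windows$red_edge)
  sd_g <- win_area(area_mat, .feature_windows$green)

  r_at <- function(t) band_reflectance(spectra, t)
  r800 <- r_at(800); r750 <- r_at(750); r720 <- r_at(720)
  r705 <- r_at(705); r680 <- r_at(680); r445 <- r_at(445)

  tibble::tibble(
    sample_id = spectra$sample_id,
    D_b = blue$value, lambda_b = blue$wavelength,
    D_y = yellow$value, lambda_y = yellow$wavelength,
    D_r = red$value, lambda_r = red$wavelength,
    R_g = green$value, lambda_g = green$wavelength,
    R_r = valley$value, lambda_o = valley$wavelength,
    SD_b = sd_b, SD_y = sd_y, SD_r = sd_r, SD_g = sd_g,
    VI1 = green$value / valley$value,
    VI2 = (green$value - valley$value) / (green$value + valley$value),
    VI3 = sd_r / sd_b,
    VI4 = sd_r / sd_y,
    VI5 = (sd_r - sd_b) / (sd_r + sd_b),
    VI6 = (sd_r - sd_y) / (sd_r + sd_y),
    VI7 = r800 / r680,
    VI8 = r750 / r720 - 1,
    VI9 = (r750 - r445) / (r705 - r445),
    VI10 = (r750 - r445) / (r750 + r705 - 2 * r445)
  )
}
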