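# Orthonormal Daubechies scaling filters (lowpass h, unit l2 norm, sum
# sqrt(2)); standard published constants. The quadrature mirror highpass is
# g[k] = (-1)^k h[L-1-k].
.db_filters <- list(
  db2 = c(
    0.48296291314453416, 0.83651630373780790, 0.22414386804201340,
    -0.12940952255126037
  ),
  db3 = c(
    0.33267055295008263, 0.80689150931109250, 0.45987750211849154,
    -0.13501102001025458, -0.08544127388202666, 0.03522629188570953
  ),
  db4 = c(
    0.23037781330889650, 0.71484657055291570, 0.63088076792985890,
    -0.02798376941685985, -0.18703481171909309, 0.03084138183556076,
    0.03288301166688520, -0.01059740178506903
  ),
  db5 = c(
    0.16010239797419293, 0.60382926979718960, 0.72430852843777290,
    0.13842814590132074, -0.24229488706638203, -0.03224486958463837,
    0.07757149384004572, -0.00624149021279827, -0.01258075199908200,
    0.00333572528547377
  )
)

qmf_highpass <- function(h) rev(h) * (-1)^(seq_along(h) - 1)

# half-point symmetric reflection of 1..n onto positions s (any integers)
reflect_index <- function(s, n) {
  u <- ((s - 1) %% (2 * n)) + 1
  ifelse(u <= n, u, 2 * n + 1 - u)
}

# frequency response (length-M DFT) of filter f upsampled by `up` on a
# circular domain of length M
upsampled_fft <- function(f, up, M) {
  v <- numeric(M)
  pos <- ((seq_along(f) - 1) * up) %% M + 1
  for (k in seq_along(f)) v[pos[k]] <- v[pos[k]] + f[k]
  stats::fft(v)
}

# core undecimated analysis: X is a bands x samples matrix; returns extended
# coefficient arrays [level, extended band, sample]
swt_bank <- function(X, h, levels, boundary) {
  n <- nrow(X)
  g <- qmf_highpass(h)
  if (boundary == "symmetric") {
    pad <- (length(h) - 1) * (2^levels - 1)
    M <- stats::nextn(n + 2 * pad, c(2, 3, 5))
    # centre the original signal; fill the margins by symmetric reflection
    s <- seq_len(M) - pad
    X <- X[reflect_index(s, n), , drop = FALSE]
  } else {
    pad <- 0
    M <- n
  }
  ns <- ncol(X)
  A <- array(0, c(levels, M, ns))
  D <- array(0, c(levels, M, ns))
  a <- stats::mvfft(X)
  for (j in seq_len(levels)) {
    up <- 2^(j - 1)
    Hj <- upsampled_fft(h, up, M)
    Gj <- upsampled_fft(g, up, M)
    D[j, , ] <- Re(stats::mvfft(Conj(Gj) * a, inverse = TRUE)) / M
    a <- Conj(Hj) * a
    A[j, , ] <- Re(stats::mvfft(a, inverse = TRUE)) / M
  }
  list(A = A, D = D, pad = pad, M = M)
}

#' Undecimated dyadic wavelet decomposition of a spectrum
#'
#' Decomposes a spectrum into `levels` approximation (low-frequency, `A_j`)
#' and detail (high-frequency, `D_j`) series on the dyadic scales
#' `2^1 ... 2^levels`, using an undecimated (stationary) filter bank so that
#' every series has the full length of the input and its coefficients stay
#' aligned with the wavelength grid. Analysis is by circular correlation with
#' the scale-`j` upsampled Daubechies filters; the signal is first extended
#' symmetrically (default) so band edges do not contaminate interior
#' coefficients. The transform is exactly invertible, see
#' [swt_reconstruct()].
#'
#' @param x Numeric spectrum, or a one-row spectra tibble.
#' @param basis Daubechies basis: `"db2"`, `"db3"`, `"db4"` or `"db5"`.
#' @param levels Decomposition depth (default 5); requires
#'   `2^levels <= length(x)`.
#' @param boundary `"symmetric"` (default) or `"periodic"` extension.
#' @param wavelengths Optional wavelength grid (taken from the tibble if `x`
#'   is one).
#' @return Object of class `dyadic_swt` with matrices `A` and `D`
#'   (`levels` rows, one column per input band).
#' @export
#' @examples
#' dec <- swt_decompose(sin(seq(0, 6 * pi, length.out = 128)), "db3")
#' max(abs(swt_reconstruct(dec) - sin(seq(0, 6 * pi, length.out = 128))))
swt_decompose <- function(x, basis = c("db2", "db3", "db4", "db5"),
                          levels = 5,
                          boundary = c("symmetric", "periodic"),
                          wavelengths = NULL) {
  basis <- match.arg(basis)
  boundary <- match.arg(boundary)
  if (is.data.frame(x)) {
    assert_spectra(x, "x")
    if (nrow(x) != 1) abort("`x` must be a single spectrum (one row).")
    wavelengths <- spc_wavelengths(x)
    x <- drop(spc_matrix(x))
  }
  x <- as.numeric(x)
  if (!all(is.finite(x))) abort("spectrum contains non-finite values.")
  n <- length(x)
  if (levels < 1) abort("`levels` must be at least 1.")
  if (2^levels > n) {
    abort(sprintf(
      "signal of %d bands is too short for %d levels; at most %d feasible.",
      n, levels, floor(log2(n))
    ))
  }
  bank <- swt_bank(matrix(x, ncol = 1), .db_filters[[basis]], levels, boundary)
  keep <- bank$pad + seq_len(n)
  structure(
    list(
      basis = basis, levels = levels, boundary = boundary,
      wavelengths = wavelengths, n = n,
      A = matrix(bank$A[, keep, 1], nrow = levels),
      D = matrix(bank$D[, keep, 1], nrow = levels),
      A_ext = matrix(bank$A[, , 1], nrow = levels),
      D_ext = matrix(bank$D[, , 1], nrow = levels),
      pad = bank$pad
    ),
    class = "dyadic_swt"
  )
}

#' Invert an undecimated dyadic wavelet decomposition
#'
#' Reconstructs the original spectrum from the coarsest approximation and all
#' detail series by the adjoint filter bank (synthesis by circular
#' convolution, averaging the two polyphase branches). Reconstruction is
#' exact to floating precision. Detail levels listed in `drop_details` are
#' zeroed first, which turns the inverse into a dyadic smoother.
#'
#' @param decomposition A `dyadic_swt` object.
#' @param drop_details Integer levels whose detail series are zeroed before
#'   inversion (default none).
#' @return Numeric vector, the reconstructed spectrum.
#' @export
swt_reconstruct <- function(decomposition, drop_details = integer()) {
  stopifnot(inherits(decomposition, "dyadic_swt"))
  h <- .db_filters[[decomposition$basis]]
  g <- qmf_highpass(h)
  levels <- decomposition$levels
  M <- ncol(decomposition$A_ext)
  a <- stats::fft(decomposition$A_ext[levels, ])
  for (j in rev(seq_len(levels))) {
    dj <- decomposition$D_ext[j, ]
    if (j %in% drop_details) dj <- numeric(M)
    up <- 2^(j - 1)
    Hj <- upsampled_fft(h, up, M)
    Gj <- upsampled_fft(g, up, M)
    a <- (Hj * a + Gj * stats::fft(dj)) / 2
  }
  rec <- Re(stats::fft(a, inverse = TRUE)) / M
  rec[decomposition$pad + seq_len(decomposition$n)]
}

#' Read a single wavelet coefficient
#'
#' @param decomposition A `dyadic_swt` object.
#' @param band_type `"A"` (approximation) or `"D"` (detail).
#' @param level Decomposition level, `1..levels`.
#' @param band_index Band position on the original grid (1-based).
#' @return The coefficient value.
#' @export
coefficient_at <- function(decomposition, band_type = c("A", "D"), level,
                           band_index) {
  stopifnot(inherits(decomposition, "dyadic_swt"))
  band_type <- match.arg(band_type)
  if (level < 1 || level > decomposition$levels) {
    abort(sprintf(
      "level %d out of range; decomposition has levels 1..%d.",
      level, decomposition$levels
    ))
  }
  if (band_index < 1 || band_index > decomposition$n) {
    abort(sprintf(
      "band index %d out of range 1..%d.", band_index, decomposition$n
    ))
  }
  if (band_type == "A") {
    decomposition$A[level, band_index]
  } else {
    decomposition$D[level, band_index]
  }
}

#' @export
print.dyadic_swt <- function(x, ...) {
  cat(sprintf(
    "<dyadic_swt> basis %s, %d levels, %d bands, %s boundary\n",
    x$basis, x$levels, x$n, x$boundary
  ))
  invisible(x)
}

#' Tidy a wavelet decomposition into a long tibble
#'
#' @param x A `dyadic_swt` object.
#' @param ... Unused.
#' @return Tibble with columns `series` ("A"/"D"), `level`, `band_index`,
#'   `wavelength` (NA when the input had no grid) and `value`.
#' @method tidy dyadic_swt
#' @export
tidy.dyadic_swt <- function(x, ...) {
  wl <- if (is.null(x$wavelengths)) rep(NA_real_, x$n) else x$wavelengths
  grid <- tidyr::expand_grid(
    series = c("A", "D"), level = seq_len(x$levels)
  )
  purrr::pmap_dfr(grid, function(series, level) {
    vals <- if (series == "A") x$A[level, ] else x$D[level, ]
    tibble::tibble(
      series = series, level = level, band_index = seq_len(x$n),
      wavelength = wl, value = vals
    )
  })
}
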