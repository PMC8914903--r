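#' Sample Pearson correlation coefficient
#'
#' @param x,y Numeric vectors of equal length (n >= 3), each with nonzero
#'   variance.
#' @return The correlation coefficient.
#' @export
pearson_r <- function(x, y) {
  if (length(x) != length(y)) abort("`x` and `y` must have equal length.")
  if (length(x) < 3) abort("need at least 3 observations.")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    abort("correlation undefined: zero variance.")
  }
  stats::cor(x, y)
}

#' Two-sided significance of a correlation coefficient
#'
#' Uses the t reference distribution `t = r * sqrt((n - 2) / (1 - r^2))` with
#' `n - 2` degrees of freedom; `|r| = 1` returns p = 0.
#'
#' @param r Correlation coefficient.
#' @param n Sample size (>= 3).
#' @return Tibble with `p`, `sig_05`, `sig_01` and `stars` ("", "*" or "**").
#' @export
correlation_significance <- function(r, n) {
  if (n < 3) abort("need n >= 3.")
  if (any(abs(r) > 1 + 1e-12)) abort("|r| cannot exceed 1.")
  p <- ifelse(abs(r) >= 1, 0, {
    t <- r * sqrt((n - 2) / pmax(1 - r^2, .Machine$double.eps))
    2 * stats::pt(-abs(t), df = n - 2)
  })
  tibble::tibble(
    p = p, sig_05 = p < 0.05, sig_01 = p < 0.01,
    stars = dplyr::case_when(p < 0.01 ~ "**", p < 0.05 ~ "*", TRUE ~ "")
  )
}

#' Correlate every variable of a feature table with a response
#'
#' One record per numeric variable; variables with zero variance get an
#' undefined (NA) coefficient flagged in `note` rather than an error.
#'
#' @param features Tibble of per-sample variables (a `sample_id` column is
#'   ignored).
#' @param y Numeric response aligned with the rows of `features`.
#' @return Tibble with `variable`, `r`, `p`, `sig_05`, `sig_01`, `stars`,
#'   `note`.
#' @export
correlation_table <- function(features, y) {
  vars <- setdiff(names(features), "sample_id")
  vars <- vars[vapply(features[vars], is.numeric, logical(1))]
  if (length(y) != nrow(features)) {
    abort("`y` must have one value per row of `features`.")
  }
  purrr::map_dfr(vars, function(v) {
    x <- features[[v]]
    if (stats::sd(x) == 0) {
      return(tibble::tibble(
        variable = v, r = NA_real_, p = NA_real_,
        sig_05 = FALSE, sig_01 = FALSE, stars = "",
        note = "constant variable; correlation undefined"
      ))
    }
    r <- pearson_r(x, y)
    sig <- correlation_significance(r, length(y))
    tibble::tibble(
      variable = v, r = r, p = sig$p, sig_05 = sig$sig_05,
      sig_01 = sig$sig_01, stars = sig$stars, note = ""
    )
  })
}

#' Per-band correlation of wavelet coefficients with a response
#'
#' Decomposes every spectrum under each requested basis and correlates each
#' coefficient series (one per basis, level, band position) with the
#' response across samples. This is the screening curve underlying wavelet
#' sensitivity-coefficient selection.
#'
#' @param spectra Spectra tibble.
#' @param y Numeric response (one value per spectrum row).
#' @param bases Daubechies bases to scan.
#' @param levels Decomposition depth.
#' @param boundary Extension rule, see [swt_decompose()].
#' @param band_type `"detail"`, `"approximation"` or `"both"`.
#' @return Tibble: `basis`, `band_type`, `level`, `band_index`, `wavelength`,
#'   `r` (NA where a coefficient series is constant across samples).
#' @export
coefficient_correlations <- function(spectra, y,
                                     bases = c("db2", "db3", "db4", "db5"),
                                     levels = 5,
                                     boundary = c("symmetric", "periodic"),
                                     band_type = c("detail", "approximation",
                                                   "both")) {
  boundary <- match.arg(boundary)
  band_type <- match.arg(band_type)
  bases <- match.arg(bases, several.ok = TRUE)
  assert_spectra(spectra)
  if (length(y) != nrow(spectra)) {
    abort("`y` must have one value per spectrum.")
  }
  wl <- spc_wavelengths(spectra)
  X <- t(spc_matrix(spectra)) # bands x samples
  types <- switch(band_type,
    detail = "D", approximation = "A", both = c("A", "D")
  )
  purrr::map_dfr(bases, function(basis) {
    bank <- swt_bank(X, .db_filters[[basis]], levels, boundary)
    keep <- bank$pad + seq_len(length(wl))
    purrr::map_dfr(types, function(ty) {
      arr <- if (ty == "D") bank$D else bank$A
      purrr::map_dfr(seq_len(levels), function(j) {
        C <- t(arr[j, keep, ]) # samples x bands
        sds <- apply(C, 2, stats::sd)
        r <- rep(NA_real_, ncol(C))
        ok <- sds > 0
        if (any(ok)) r[ok] <- drop(stats::cor(C[, ok, drop = FALSE], y))
        tibble::tibble(
          basis = basis,
          band_type = if (ty == "D") "detail" else "approximation",
          level = j, band_index = seq_along(wl), wavelength = wl, r = r
        )
      })
    })
  })
}

#' Select the top wavelet sensitivity coefficients
#'
#' Ranks every detail-series coefficient position across all requested bases
#' and levels by the absolute Pearson correlation of its values with the
#' response, and returns the `k` strongest. Ties are broken by basis order
#' (db2 < db3 < db4 < db5), then lower level, then lower band index.
#'
#' @inheritParams coefficient_correlations
#' @param k Number of coefficients to select (default 3).
#' @return Tibble of `k` rows sorted by decreasing `|r|`: `basis`, `level`,
#'   `band_index`, `wavelength`, `r`, plus a `name` like `db3_D4_448`.
#' @export
select_sensitivity_coefficients <- function(spectra, y,
                                            bases = c("db2", "db3", "db4",
                                                      "db5"),
                                            levels = 5, k = 3,
                                            boundary = c("symmetric",
                                                         "periodic")) {
  tab <- coefficient_correlations(spectra, y,
    bases = bases, levels = levels,
    boundary = boundary, band_type = "detail"
  )
  tab <- dplyr::filter(tab, !is.na(.data$r))
  if (k > nrow(tab)) {
    abort(sprintf("k = %d exceeds the %d candidate coefficients.", k, nrow(tab)))
  }
  tab |>
    dplyr::mutate(basis_rank = match(.data$basis, c("db2", "db3", "db4", "db5"))) |>
    dplyr::arrange(
      dplyr::desc(abs(.data$r)), .data$basis_rank, .data$level,
      .data$band_index
    ) |>
    head(k) |>
    dplyr::mutate(name = sprintf(
      "%s_D%d_%d", .data$basis, .data$level, .data$band_index
    )) |>
    dplyr::select(
      "basis", "level", "band_index", "wavelength", "r", "name"
    )
}

#' Extract selected wavelet coefficients as a predictor table
#'
#' Builds the per-sample predictor matrix for a set of selected sensitivity
#' coefficients (one column per coefficient, named as in the selection).
#'
#' @param spectra Spectra tibble.
#' @param selection Tibble from [select_sensitivity_coefficients()].
#' @inheritParams coefficient_correlations
#' @return Tibble: `sample_id` plus one numeric column per coefficient.
#' @export
sensitivity_predictors <- function(spectra, selection,
                                   boundary = c("symmetric", "periodic")) {
  boundary <- match.arg(boundary)
  assert_spectra(spectra)
  X <- t(spc_matrix(spectra))
  out <- tibble::tibble(sample_id = spectra$sample_id)
  for (basis in unique(selection$basis)) {
    rows <- selection[selection$basis == basis, ]
    bank <- swt_bank(X, .db_filters[[basis]], max(rows$level), boundary)
    for (i in seq_len(nrow(rows))) {
      out[[rows$name[i]]] <-
        bank$D[rows$level[i], bank$pad + rows$band_index[i], ]
    }
  }
  out
}
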