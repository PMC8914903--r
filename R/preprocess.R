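#' Radiometric correction against white and dark references
#'
#' Converts raw instrument counts to a reflectance factor using a white board
#' and dark-current reference: `(I - I_D) / (I_W - I_D)`. The default mode
#' applies a base-10 logarithm to that ratio, the literal form of the
#' correction as published for this instrument chain; `mode = "ratio"`
#' returns the plain reflectance factor.
#'
#' @param spectra Raw spectra tibble (`sample_id` plus band columns).
#' @param white,dark Reference spectra: one-row spectra tibbles (or numeric
#'   vectors) on the same wavelength grid.
#' @param mode `"log10-ratio"` (default) or `"ratio"`.
#' @return Corrected spectra tibble on the same grid.
#' @export
radiometric_correct <- function(spectra, white, dark,
                                mode = c("log10-ratio", "ratio")) {
  mode <- match.arg(mode)
  assert_spectra(spectra)
  wl <- spc_wavelengths(spectra)
  as_ref <- function(x, nm) {
    if (is.data.frame(x)) {
      assert_spectra(x, nm)
      if (!isTRUE(all.equal(spc_wavelengths(x), wl))) {
        abort(sprintf("`%s` is not on the same wavelength grid as `spectra`.", nm))
      }
      drop(spc_matrix(x))
    } else {
      if (length(x) != length(wl)) {
        abort(sprintf("`%s` must have one value per band.", nm))
      }
      as.numeric(x)
    }
  }
  iw <- as_ref(white, "white")
  id <- as_ref(dark, "dark")
  denom <- iw - id
  if (any(denom <= 0)) {
    bad <- wl[which(denom <= 0)[1]]
    abort(sprintf(
      "white reference does not exceed dark reference at band %.4g nm.", bad
    ))
  }
  m <- spc_matrix(spectra)
  ratio <- sweep(sweep(m, 2, id, "-"), 2, denom, "/")
  if (mode == "log10-ratio") {
    if (any(ratio <= 0)) {
      idx <- which(ratio <= 0, arr.ind = TRUE)[1, ]
      abort(sprintf(
        "sample '%s' does not exceed the dark reference at band %.4g nm; log10 correction undefined.",
        rownames(m)[idx[1]], wl[idx[2]]
      ))
    }
    ratio <- log10(ratio)
  }
  spc_tibble(ratio, wl, sample_id = spectra$sample_id)
}

#' Average replicate spectra per sample
#'
#' Band-wise arithmetic mean of replicate scans (typically four points per
#' leaf). Accepts either a spectra tibble with repeated `sample_id` rows, or a
#' list of spectra tibbles (whose wavelength grids must match).
#'
#' @param spectra Spectra tibble with repeated `sample_id`s, or list of
#'   spectra tibbles.
#' @return Spectra tibble with one row per sample; attribute `n_replicates`
#'   records the replicate count per sample.
#' @export
average_replicates <- function(spectra) {
  if (is.list(spectra) && !is.data.frame(spectra)) {
    grids <- lapply(spectra, spc_wavelengths)
    for (g in grids[-1]) {
      if (!isTRUE(all.equal(g, grids[[1]]))) {
        abort("replicate spectra are not on matching wavelength grids.")
      }
    }
    spectra <- dplyr::bind_rows(spectra)
  }
  assert_spectra(spectra)
  if (nrow(spectra) < 1) abort("need at least one replicate.")
  counts <- dplyr::count(spectra, .data$sample_id, name = "n_replicates")
  out <- spectra |>
    dplyr::select(dplyr::all_of(c("sample_id", band_cols(spectra)))) |>
    dplyr::group_by(.data$sample_id) |>
    dplyr::summarise(dplyr::across(dplyr::everything(), mean), .groups = "drop")
  # preserve first-appearance order
  out <- out[match(unique(spectra$sample_id), out$sample_id), ]
  attr(out, "n_replicates") <- counts
  out
}

#' Flag and remove outlying spectra
#'
#' Default method scores each spectrum by its Mahalanobis distance on the
#' first three principal-component scores of the spectra matrix and removes
#' samples beyond the chi-square cutoff (3 df) at `threshold`.
#'
#' @param spectra Spectra tibble.
#' @param samples Optional sample table filtered alongside.
#' @param method `"mahalanobis-pca"` or `"none"`.
#' @param threshold Chi-square probability cutoff (default 0.999).
#' @param n_pc Number of principal components scored.
#' @return List with `spectra`, `samples` (retained rows) and `removed`
#'   (tibble of `sample_id` and `score` for flagged samples; `score` is the
#'   squared Mahalanobis distance).
#' @export
remove_outliers <- function(spectra, samples = NULL,
                            method = c("mahalanobis-pca", "none"),
                            threshold = 0.999, n_pc = 3) {
  method <- match.arg(method)
  assert_spectra(spectra)
  if (method == "none") {
    return(list(
      spectra = spectra, samples = samples,
      removed = tibble::tibble(sample_id = character(), score = numeric())
    ))
  }
  if (nrow(spectra) < 10) {
    abort("mahalanobis-pca outlier screening needs at least 10 samples.")
  }
  m <- spc_matrix(spectra)
  pc <- stats::prcomp(m, center = TRUE, scale. = FALSE)
  scores <- pc$x[, seq_len(min(n_pc, ncol(pc$x))), drop = FALSE]
  d2 <- stats::mahalanobis(scores, colMeans(scores), stats::cov(scores))
  cut <- stats::qchisq(threshold, df = ncol(scores))
  bad <- d2 > cut
  removed <- tibble::tibble(sample_id = spectra$sample_id[bad], score = d2[bad])
  keep <- !bad
  list(
    spectra = spectra[keep, ],
    samples = if (is.null(samples)) NULL else samples[keep, ],
    removed = removed
  )
}

#' Split samples into modeling and validation sets
#'
#' Uniform random split (optionally stratified by a grouping vector),
#' reproducible under `seed`. With the default two-thirds fraction a
#' 72-sample set yields 48 modeling and 24 validation samples.
#'
#' @param sample_ids Character vector of sample ids (>= 3).
#' @param fraction Modeling fraction; modeling size is `round(fraction * n)`.
#' @param seed Integer seed.
#' @param stratify Optional vector (same length) of group labels; the split
#'   is then drawn within each group.
#' @return List of class `split_index`: `modeling_ids`, `validation_ids`,
#'   `seed`.
#' @export
split_modeling_validation <- function(sample_ids, fraction = 2 / 3,
                                      seed = NULL, stratify = NULL) {
  n <- length(sample_ids)
  if (n < 3) abort("need at least 3 samples to split.")
  if (anyDuplicated(sample_ids)) abort("`sample_ids` must be unique.")
  if (fraction <= 0 || fraction >= 1) abort("`fraction` must be in (0, 1).")
  modeling <- with_seed_if(seed, {
    if (is.null(stratify)) {
      sample(sample_ids, round(fraction * n))
    } else {
      stopifnot(length(stratify) == n)
      unlist(lapply(split(sample_ids, stratify), function(ids) {
        sample(ids, round(fraction * length(ids)))
      }), use.names = FALSE)
    }
  })
  structure(
    list(
      modeling_ids = sample_ids[sample_ids %in% modeling],
      validation_ids = sample_ids[!sample_ids %in% modeling],
      seed = seed
    ),
    class = "split_index"
  )
}

#' @export
print.split_index <- function(x, ...) {
  cat(sprintf(
    "<split_index> %d modeling / %d validation samples\n",
    length(x$modeling_ids), length(x$validation_ids)
  ))
  invisible(x)
}
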