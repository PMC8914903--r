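#' Coefficient of determination
#'
#' Sum-of-squares based: `1 - SS_res / SS_tot`, clipped below at 0. The
#' squared-correlation alternative (`method = "cor"`) coincides with it for
#' least-squares linear fits.
#'
#' @param y Measured values (non-constant, n >= 2).
#' @param y_hat Predicted values.
#' @param method `"ss"` (default) or `"cor"`.
#' @return R-squared in [0, 1].
#' @export
r_squared <- function(y, y_hat, method = c("ss", "cor")) {
  method <- match.arg(method)
  if (length(y) != length(y_hat)) abort("lengths differ.")
  if (length(y) < 2) abort("need at least 2 observations.")
  if (stats::var(y) == 0) abort("R-squared undefined for constant `y`.")
  if (method == "ss") {
    max(0, 1 - sum((y - y_hat)^2) / sum((y - mean(y))^2))
  } else {
    stats::cor(y, y_hat)^2
  }
}

#' Mean relative error (percent)
#'
#' `100 * mean(|y - y_hat| / y)`; all measured values must be positive.
#'
#' @inheritParams r_squared
#' @return MRE in percent.
#' @export
mre <- function(y, y_hat) {
  if (length(y) != length(y_hat)) abort("lengths differ.")
  if (any(y <= 0)) abort("MRE undefined: all measured values must be positive.")
  100 * mean(abs(y - y_hat) / y)
}

#' Root mean square error
#'
#' @inheritParams r_squared
#' @return RMSE in response units.
#' @export
rmse <- function(y, y_hat) {
  if (length(y) != length(y_hat)) abort("lengths differ.")
  sqrt(mean((y - y_hat)^2))
}

#' Normalised root mean square error
#'
#' RMSE divided by the mean of the measured values (dimensionless).
#'
#' @inheritParams r_squared
#' @return NRMSE.
#' @export
nrmse <- function(y, y_hat) {
  if (mean(y) <= 0) abort("NRMSE undefined: mean of `y` must be positive.")
  rmse(y, y_hat) / mean(y)
}

#' AHP weights of the composite model score
#'
#' Fixed expert-elicited weights of the three evaluation factors: 0.4648 on
#' the reciprocal of modeling R-squared, 0.2958 on validation MRE (as a
#' fraction) and 0.2394 on validation NRMSE. They sum to 1. This is the
#' single place the constants live.
#'
#' @return Named numeric vector `c(r_squared, mre, nrmse)`.
#' @export
ahp_weights <- function() {
  c(r_squared = 0.4648, mre = 0.2958, nrmse = 0.2394)
}

#' AHP-weighted composite model score T
#'
#' `T = (1 / R2) * w_R2 + (MRE / 100) * w_MRE + NRMSE * w_NRMSE`. Lower is
#' better; a perfect model scores `w_R2` = 0.4648. MRE is supplied in
#' percent, as conventionally reported, and enters the score as a fraction.
#'
#' @param r_squared Modeling R-squared (> 0).
#' @param mre Validation mean relative error, in percent.
#' @param nrmse Validation normalised RMSE.
#' @param weights Weights as from [ahp_weights()].
#' @return The composite score (unrounded; report to 4 decimals).
#' @export
#' @examples
#' round(t_score(0.974, 1.65, 0.0198), 4) # 0.4868
t_score <- function(r_squared, mre, nrmse, weights = ahp_weights()) {
  if (any(r_squared <= 0)) abort("composite score undefined for R-squared <= 0.")
  (1 / r_squared) * weights[["r_squared"]] +
    (mre / 100) * weights[["mre"]] +
    nrmse * weights[["nrmse"]]
}

#' Relative improvement of a candidate metric over a reference
#'
#' Signed percent change: `100 * (candidate - reference) / reference` for
#' larger-is-better metrics (R-squared), and
#' `100 * (reference - candidate) / reference` for smaller-is-better metrics
#' (MRE, NRMSE, T), so that a positive value always means the candidate
#' improved on the reference.
#'
#' @param reference,candidate Metric values (reference nonzero).
#' @param smaller_is_better Set `TRUE` for error-type metrics.
#' @return Signed percent improvement.
#' @export
#' @examples
#' relative_improvement(0.672, 0.906) # 34.8
relative_improvement <- function(reference, candidate,
                                 smaller_is_better = FALSE) {
  if (any(reference == 0)) abort("reference metric must be nonzero.")
  if (smaller_is_better) {
    100 * (reference - candidate) / reference
  } else {
    100 * (candidate - reference) / reference
  }
}

#' Evaluate a fitted model on a modeling/validation split
#'
#' Computes modeling R-squared from the model's predictions on the modeling
#' set, MRE / RMSE / NRMSE on the validation set, and the composite score T.
#'
#' @param model A fitted `npk_univariate`, `npk_pls` or `npk_nn` model (or
#'   anything with a `predict` method taking a data frame).
#' @param modeling,validation Data frames holding predictors and the
#'   response.
#' @param response Response column name.
#' @param model_id Label for the report row.
#' @return One-row tibble: `model_id`, `r_squared`, `mre`, `rmse`, `nrmse`,
#'   `t`, `n_modeling`, `n_validation`.
#' @export
evaluate_model <- function(model, modeling, validation, response,
                           model_id = class(model)[1]) {
  y_mod <- modeling[[response]]
  y_val <- validation[[response]]
  pred_mod <- predict(model, modeling)
  pred_val <- predict(model, validation)
  r2 <- r_squared(y_mod, pred_mod)
  m <- mre(y_val, pred_val)
  nr <- nrmse(y_val, pred_val)
  tibble::tibble(
    model_id = model_id,
    r_squared = r2, mre = m, rmse = rmse(y_val, pred_val), nrmse = nr,
    t = t_score(r2, m, nr),
    n_modeling = length(y_mod), n_validation = length(y_val)
  )
}

#' Compare evaluation reports and rank models
#'
#' Identifies, per response, the best model (minimum composite score T, ties
#' broken alphabetically by model id) and tabulates pairwise improvement
#' percentages for each metric with the appropriate direction (R-squared
#' larger-is-better; MRE, NRMSE and T smaller-is-better).
#'
#' @param reports Tibble of evaluation rows (as from [evaluate_model()]),
#'   optionally with a `response` column separating nutrients.
#' @return List of class `npk_comparison`: `best` (one row per response) and
#'   `improvements` (reference model, candidate model, metric, percent).
#' @export
compare_models <- function(reports) {
  if (!"response" %in% names(reports)) reports$response <- "response"
  if (any(table(reports$response) < 2)) {
    abort("need at least 2 reports per response to compare.")
  }
  best <- reports |>
    dplyr::group_by(.data$response) |>
    dplyr::arrange(.data$t, .data$model_id, .by_group = TRUE) |>
    dplyr::slice(1) |>
    dplyr::ungroup()
  metrics <- tibble::tibble(
    metric = c("r_squared", "mre", "nrmse", "t"),
    smaller_is_better = c(FALSE, TRUE, TRUE, TRUE)
  )
  improvements <- reports |>
    dplyr::group_by(.data$response) |>
    dplyr::group_modify(function(df, key) {
      pairs <- tidyr::expand_grid(
        reference = df$model_id, candidate = df$model_id
      ) |>
        dplyr::filter(.data$reference != .data$candidate)
      purrr::pmap_dfr(pairs, function(reference, candidate) {
        ref <- df[df$model_id == reference, ]
        cand <- df[df$model_id == candidate, ]
        dplyr::mutate(metrics,
          reference = reference, candidate = candidate,
          improvement = purrr::map2_dbl(
            .data$metric, .data$smaller_is_better,
            ~ relative_improvement(ref[[.x]], cand[[.x]], .y)
          )
        )
      })
    }) |>
    dplyr::ungroup() |>
    dplyr::select(
      "response", "reference", "candidate", "metric", "improvement"
    )
  structure(list(best = best, improvements = improvements),
    class = "npk_comparison"
  )
}

#' @export
print.npk_comparison <- function(x, ...) {
  cat("<npk_comparison> best model per response (minimum T):\n")
  print(x$best[c("response", "model_id", "r_squared", "mre", "nrmse", "t")])
  invisible(x)
}
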