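#' Configuration of the end-to-end diagnostic pipeline
#'
#' @param simulate A [sim_config()] describing the synthetic dataset, or
#'   `NULL` when reading from files.
#' @param spectra_path,samples_path Input files (used when `simulate` is
#'   `NULL`), formats as in [write_spectra()] / [write_sample_table()].
#' @param correction `NULL` (input already reflectance) or a list with
#'   elements `white`, `dark` (reference spectra) and optional `mode` passed
#'   to [radiometric_correct()].
#' @param outlier_method,outlier_threshold Passed to [remove_outliers()].
#' @param split_fraction Modeling fraction of the sample split.
#' @param responses Nutrient columns to model.
#' @param n_features Univariate predictors per nutrient (top absolute
#'   correlations among the 24 characteristic variables).
#' @param families Univariate model families to fit.
#' @param bases,wavelet_levels,selection_k,boundary Wavelet scan settings for
#'   [select_sensitivity_coefficients()].
#' @param selection_scope `"modeling"` (default; screening sees only the
#'   modeling samples, avoiding leakage into validation) or `"all"`.
#' @param pls_ncomp PLS components.
#' @param nn_hidden Hidden units of the neural network.
#' @param strict If `TRUE`, a model family whose domain assumptions fail on a
#'   selected predictor raises an error; otherwise the combination is skipped
#'   and logged.
#' @param out_dir Optional directory where every stage output is persisted as
#'   delimited text.
#' @param seed Master seed; simulation, split and network initialisation draw
#'   sub-seeds from it (`seed`, `seed + 1`, `seed + 2`).
#' @return Config list of class `npk_config`.
#' @export
npk_config <- function(simulate = sim_config(),
                       spectra_path = NULL, samples_path = NULL,
                       correction = NULL,
                       outlier_method = "mahalanobis-pca",
                       outlier_threshold = 0.999,
                       split_fraction = 2 / 3,
                       responses = c("nitrogen", "phosphorus", "potassium"),
                       n_features = 3,
                       families = c("linear", "parabolic", "exponential",
                                    "logarithmic"),
                       bases = c("db2", "db3", "db4", "db5"),
                       wavelet_levels = 5, selection_k = 3,
                       boundary = "symmetric",
                       selection_scope = c("modeling", "all"),
                       pls_ncomp = 2, nn_hidden = 10,
                       strict = FALSE,
                       out_dir = NULL, seed = 1) {
  selection_scope <- match.arg(selection_scope)
  if (is.null(simulate) && (is.null(spectra_path) || is.null(samples_path))) {
    abort("either `simulate` or both input paths must be given.")
  }
  if (!is.null(simulate)) stopifnot(inherits(simulate, "sim_config"))
  families <- match.arg(families, several.ok = TRUE)
  structure(as.list(environment()), class = "npk_config")
}

run_stage <- function(state, name, expr) {
  tryCatch(expr, error = function(e) {
    if (!is.null(state$out_dir)) {
      writeLines(
        sprintf("stage %s failed: %s", name, conditionMessage(e)),
        file.path(state$out_dir, "FAILED")
      )
    }
    abort(sprintf("stage %s: %s", name, conditionMessage(e)))
  })
}

#' Run the full diagnostic pipeline
#'
#' Executes simulate/load, optional radiometric correction, replicate
#' averaging, outlier screening, the modeling/validation split, feature
#' extraction and correlation screening, wavelet sensitivity-coefficient
#' selection, fits of every requested univariate family plus PLS and the
#' neural network per nutrient, evaluation of each fitted model
#' (modeling R-squared; validation MRE, RMSE, NRMSE; composite score T), and
#' a cross-model comparison. When `config$out_dir` is set, each stage's
#' output is persisted as delimited text so any number in the final report
#' can be recomputed from the run directory.
#'
#' @param config An [npk_config()].
#' @return Object of class `npk_run`: the dataset, split, feature table,
#'   correlation tables, wavelet selections, fitted models, `evaluation`
#'   tibble and `comparison`.
#' @export
#' @examples
#' \donttest{
#' run <- run_npk_pipeline(npk_config(seed = 1))
#' run$comparison$best
#' }
run_npk_pipeline <- function(config = npk_config()) {
  stopifnot(inherits(config, "npk_config"))
  state <- list(out_dir = config$out_dir)
  log <- character()
  note <- function(...) {
    log <<- c(log, sprintf("[%s] %s", format(Sys.time(), "%H:%M:%S"),
      sprintf(...)
    ))
  }
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  }
  persist <- function(obj, file, writer = readr::write_tsv) {
    if (!is.null(config$out_dir)) writer(obj, file.path(config$out_dir, file))
  }

  note("seed %d", config$seed)
  dataset <- run_stage(state, "input", {
    if (!is.null(config$simulate)) {
      sim <- config$simulate
      if (is.null(sim$seed)) sim$seed <- config$seed
      simulate_npk_dataset(sim)
    } else {
      list(
        spectra = read_spectra(config$spectra_path),
        samples = read_sample_table(config$samples_path)
      )
    }
  })
  spectra <- dataset$spectra
  samples <- dataset$samples
  note("input: %d samples, %d bands", nrow(samples),
    length(spc_wavelengths(spectra))
  )

  if (!is.null(config$correction)) {
    spectra <- run_stage(state, "correction", {
      do.call(radiometric_correct, c(
        list(spectra = spectra), config$correction
      ))
    })
    note("radiometric correction applied")
  }
  if (anyDuplicated(spectra$sample_id)) {
    spectra <- run_stage(state, "replicates", average_replicates(spectra))
    note("replicates averaged to %d samples", nrow(spectra))
  }
  screened <- run_stage(state, "outliers", remove_outliers(
    spectra, samples,
    method = config$outlier_method, threshold = config$outlier_threshold
  ))
  spectra <- screened$spectra
  samples <- screened$samples
  note("outlier screening removed %d sample(s)", nrow(screened$removed))
  persist(spectra, "spectra.tsv")
  persist(samples, "samples.tsv")
  persist(screened$removed, "outliers_removed.tsv")

  split <- run_stage(state, "split", split_modeling_validation(
    samples$sample_id, fraction = config$split_fraction,
    seed = config$seed + 1
  ))
  note("split: %d modeling / %d validation", length(split$modeling_ids),
    length(split$validation_ids)
  )
  persist(
    tibble::tibble(
      sample_id = c(split$modeling_ids, split$validation_ids),
      set = rep(c("modeling", "validation"),
        c(length(split$modeling_ids), length(split$validation_ids))
      )
    ),
    "split.tsv"
  )

  features <- run_stage(state, "features", extract_features(spectra))
  persist(features, "features.tsv")
  scope_ids <- if (config$selection_scope == "modeling") {
    split$modeling_ids
  } else {
    samples$sample_id
  }
  in_scope <- samples$sample_id %in% scope_ids
  is_modeling <- samples$sample_id %in% split$modeling_ids

  evaluation <- list()
  models <- list()
  correlations <- list()
  selections <- list()
  for (resp in config$responses) {
    y_scope <- samples[[resp]][in_scope]
    ctab <- run_stage(state, "correlation", correlation_table(
      features[in_scope, ], y_scope
    ))
    correlations[[resp]] <- ctab
    persist(ctab, sprintf("correlations_%s.tsv", resp))

    feat_data <- dplyr::left_join(features, samples, by = "sample_id")
    feat_mod <- feat_data[is_modeling, ]
    feat_val <- feat_data[!is_modeling, ]
    top_feats <- ctab |>
      dplyr::filter(!is.na(.data$r)) |>
      dplyr::arrange(dplyr::desc(abs(.data$r))) |>
      head(config$n_features)
    note("%s: top features %s", resp,
      paste(sprintf("%s (r=%.3f)", top_feats$variable, top_feats$r),
        collapse = ", "
      )
    )
    for (feat in top_feats$variable) {
      for (family in config$families) {
        fit <- run_stage(state, "univariate", {
          tryCatch(
            fit_univariate(feat_mod, feat, resp, family),
            error = function(e) {
              if (config$strict) {
                abort(sprintf(
                  "%s model on %s for %s: %s",
                  family, feat, resp, conditionMessage(e)
                ))
              }
              note("skipped %s on %s for %s: %s", family, feat, resp,
                conditionMessage(e)
              )
              NULL
            }
          )
        })
        if (is.null(fit)) next
        id <- sprintf("%s[%s]", family, feat)
        models[[resp]][[id]] <- fit
        ev <- run_stage(state, "evaluation", tryCatch(
          dplyr::mutate(
            evaluate_model(fit, feat_mod, feat_val, resp, model_id = id),
            response = resp, type = "univariate", .before = 1
          ),
          error = function(e) {
            if (config$strict) abort(conditionMessage(e))
            note("evaluation skipped for %s (%s): %s", id, resp,
              conditionMessage(e)
            )
            NULL
          }
        ))
        evaluation[[length(evaluation) + 1]] <- ev
      }
    }

    sel <- run_stage(state, "selection", select_sensitivity_coefficients(
      spectra[in_scope, ], y_scope,
      bases = config$bases, levels = config$wavelet_levels,
      k = config$selection_k, boundary = config$boundary
    ))
    selections[[resp]] <- sel
    persist(sel, sprintf("selection_%s.tsv", resp))
    note("%s: sensitivity coefficients %s", resp,
      paste(sprintf("%s (r=%.3f)", sel$name, sel$r), collapse = ", ")
    )
    preds <- run_stage(state, "predictors", sensitivity_predictors(
      spectra, sel,
      boundary = config$boundary
    ))
    pred_data <- dplyr::left_join(preds, samples, by = "sample_id")
    pred_mod <- pred_data[is_modeling, ]
    pred_val <- pred_data[!is_modeling, ]

    pls <- run_stage(state, "pls", fit_pls(
      pred_mod, sel$name, resp, ncomp = config$pls_ncomp
    ))
    models[[resp]][["pls"]] <- pls
    evaluation[[length(evaluation) + 1]] <- dplyr::mutate(
      evaluate_model(pls, pred_mod, pred_val, resp, model_id = "pls"),
      response = resp, type = "pls", .before = 1
    )
    nn <- run_stage(state, "nn", fit_nn(
      pred_mod, sel$name, resp,
      hidden = config$nn_hidden, seed = config$seed + 2
    ))
    models[[resp]][["nn"]] <- nn
    evaluation[[length(evaluation) + 1]] <- dplyr::mutate(
      evaluate_model(nn, pred_mod, pred_val, resp, model_id = "nn"),
      response = resp, type = "nn", .before = 1
    )
  }
  evaluation <- dplyr::bind_rows(evaluation)
  persist(evaluation, "evaluation.tsv")
  comparison <- run_stage(state, "comparison", compare_models(evaluation))
  persist(comparison$best, "comparison_best.tsv")
  persist(comparison$improvements, "comparison_improvements.tsv")
  if (!is.null(config$out_dir)) {
    eqs <- unlist(lapply(names(models), function(resp) {
      pls <- models[[resp]][["pls"]]
      sprintf("%s: %s", resp, equation_string(pls))
    }))
    writeLines(eqs, file.path(config$out_dir, "pls_equations.txt"))
    writeLines(log, file.path(config$out_dir, "log.txt"))
    cfg <- config
    cfg$out_dir <- NULL
    jsonlite::write_json(cfg, file.path(config$out_dir, "config.json"),
      auto_unbox = TRUE, force = TRUE, digits = NA
    )
  }
  structure(
    list(
      config = config, dataset = dataset, spectra = spectra,
      samples = samples, removed = screened$removed, split = split,
      features = features, correlations = correlations,
      selections = selections, models = models,
      evaluation = evaluation, comparison = comparison, log = log
    ),
    class = "npk_run"
  )
}

#' @export
print.npk_run <- function(x, ...) {
  cat(sprintf(
    "<npk_run> %d samples, %d fitted models across %s\n",
    nrow(x$samples), nrow(x$evaluation),
    paste(unique(x$evaluation$response), collapse = ", ")
  ))
  print(x$comparison)
  invisible(x)
}
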