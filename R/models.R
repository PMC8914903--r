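#' Fit a univariate diagnostic model
#'
#' Least-squares fit of one of the four classical univariate forms linking a
#' spectral variable x to nutrient content y: linear `y = a + b x`, parabolic
#' `y = a + b x + c x^2`, exponential `y = a exp(b x)` and logarithmic
#' `y = a + b ln(x)`. The exponential form is fit by nonlinear least squares
#' initialised from the log-linear solution (set
#' `exp_method = "log-linear"` to keep the log-linear solution itself, which
#' minimises error on the log scale).
#'
#' @param data Data frame holding predictor and response columns.
#' @param predictor,response Column names (strings).
#' @param family `"linear"`, `"parabolic"`, `"exponential"` or
#'   `"logarithmic"`.
#' @param exp_method Objective for the exponential family.
#' @return Object of class `npk_univariate` with named coefficients
#'   (`a`, `b` and, for parabolic, `c`), training fitted values and training
#'   R-squared.
#' @export
#' @examples
#' d <- data.frame(x = 1:10, y = 1 + 2 * (1:10))
#' coef(fit_univariate(d, "x", "y", "linear"))
fit_univariate <- function(data, predictor, response,
                           family = c("linear", "parabolic", "exponential",
                                      "logarithmic"),
                           exp_method = c("nls", "log-linear")) {
  family <- match.arg(family)
  exp_method <- match.arg(exp_method)
  x <- data[[predictor]]
  y <- data[[response]]
  if (is.null(x) || is.null(y)) abort("predictor or response column not found.")
  if (!all(is.finite(x)) || !all(is.finite(y))) {
    abort("non-finite values in predictor or response.")
  }
  n <- length(x)
  npar <- if (family == "parabolic") 3L else 2L
  if (n < npar) abort("too few samples for this family.")
  offenders <- function(bad) {
    ids <- if ("sample_id" %in% names(data)) data$sample_id[bad] else which(bad)
    paste(ids, collapse = ", ")
  }
  coefs <- switch(family,
    linear = {
      fit <- stats::lm(y ~ x)
      c(a = unname(coef(fit)[1]), b = unname(coef(fit)[2]))
    },
    parabolic = {
      fit <- stats::lm(y ~ x + I(x^2))
      c(a = unname(coef(fit)[1]), b = unname(coef(fit)[2]),
        c = unname(coef(fit)[3]))
    },
    exponential = {
      if (any(y <= 0)) {
        abort(paste0(
          "exponential fit needs positive responses; offending sample(s): ",
          offenders(y <= 0)
        ))
      }
      init <- stats::lm(log(y) ~ x)
      start <- list(a = exp(unname(coef(init)[1])), b = unname(coef(init)[2]))
      if (exp_method == "log-linear") {
        c(a = start$a, b = start$b)
      } else {
        fit <- minpack.lm::nlsLM(y ~ a * exp(b * x), start = start,
          control = minpack.lm::nls.lm.control(maxiter = 200)
        )
        c(a = unname(coef(fit)["a"]), b = unname(coef(fit)["b"]))
      }
    },
    logarithmic = {
      if (any(x <= 0)) {
        abort(paste0(
          "logarithmic fit needs positive predictor values; offending sample(s): ",
          offenders(x <= 0)
        ))
      }
      fit <- stats::lm(y ~ log(x))
      c(a = unname(coef(fit)[1]), b = unname(coef(fit)[2]))
    }
  )
  object <- structure(
    list(
      family = family, coefficients = coefs,
      predictor = predictor, response = response, n = n
    ),
    class = "npk_univariate"
  )
  object$fitted <- predict(object, x)
  object$r_squared <- r_squared(y, object$fitted)
  object
}

#' @export
coef.npk_univariate <- function(object, ...) object$coefficients

#' @export
predict.npk_univariate <- function(object, newdata, ...) {
  x <- if (is.data.frame(newdata)) newdata[[object$predictor]] else newdata
  cf <- object$coefficients
  switch(object$family,
    linear = cf["a"] + cf["b"] * x,
    parabolic = cf["a"] + cf["b"] * x + cf["c"] * x^2,
    exponential = cf["a"] * exp(cf["b"] * x),
    logarithmic = {
      if (any(x <= 0)) {
        abort("logarithmic model undefined for non-positive predictor values.")
      }
      cf["a"] + cf["b"] * log(x)
    }
  ) |> unname()
}

#' @export
print.npk_univariate <- function(x, ...) {
  cat(sprintf(
    "<npk_univariate> %s: %s ~ %s; R2 = %.4f\n",
    x$family, x$response, x$predictor, x$r_squared
  ))
  invisible(x)
}

#' @method tidy npk_univariate
#' @export
tidy.npk_univariate <- function(x, ...) {
  tibble::tibble(term = names(x$coefficients), estimate = unname(x$coefficients))
}

#' @method glance npk_univariate
#' @export
glance.npk_univariate <- function(x, ...) {
  tibble::tibble(
    r.squared = x$r_squared, family = x$family, predictor = x$predictor,
    nobs = x$n
  )
}

#' Fit a PLS1 regression and collapse it to a linear equation
#'
#' Partial least squares regression (NIPALS, single response): predictors and
#' response are mean-centred, latent components maximising covariance with
#' the response are extracted by deflation, and the model is collapsed back
#' to an intercept plus one coefficient per predictor on the original scale.
#' With `ncomp` equal to the predictor rank the solution coincides with
#' ordinary least squares.
#'
#' @param data Data frame holding the predictor and response columns.
#' @param predictors Character vector of predictor column names (the
#'   three selected wavelet sensitivity coefficients, in the reference
#'   design).
#' @param response Response column name.
#' @param ncomp Number of latent components (default 2).
#' @return Object of class `npk_pls`: `intercept`, named `coefficients`,
#'   per-component variance explained in X and y, training fitted values and
#'   R-squared.
#' @export
fit_pls <- function(data, predictors, response, ncomp = 2) {
  X <- as.matrix(data[predictors])
  y <- data[[response]]
  storage.mode(X) <- "double"
  n <- nrow(X); p <- ncol(X)
  if (!all(is.finite(X)) || !all(is.finite(y))) {
    abort("non-finite values in predictors or response.")
  }
  if (ncomp < 1 || ncomp > p) abort("`ncomp` must be between 1 and ncol(X).")
  if (n <= ncomp) abort("need more samples than components.")
  x_mean <- colMeans(X)
  y_mean <- mean(y)
  Xc <- sweep(X, 2, x_mean)
  yc <- y - y_mean
  if (qr(Xc)$rank < ncomp) {
    abort(sprintf(
      "predictor matrix has rank %d < ncomp = %d.", qr(Xc)$rank, ncomp
    ))
  }
  ssx_tot <- sum(Xc^2)
  ssy_tot <- sum(yc^2)
  if (ssy_tot == 0) {
    # constant response: flat model
    B <- rep(0, p)
  } else {
    W <- P <- matrix(0, p, ncomp)
    q <- numeric(ncomp)
    x_var <- y_var <- numeric(ncomp)
    Xd <- Xc; yd <- yc
    for (h in seq_len(ncomp)) {
      w <- drop(crossprod(Xd, yd))
      w <- w / sqrt(sum(w^2))
      t_h <- drop(Xd %*% w)
      tt <- sum(t_h^2)
      p_h <- drop(crossprod(Xd, t_h)) / tt
      q_h <- sum(yd * t_h) / tt
      Xd <- Xd - tcrossprod(t_h, p_h)
      yd <- yd - t_h * q_h
      W[, h] <- w; P[, h] <- p_h; q[h] <- q_h
      x_var[h] <- tt * sum(p_h^2) / ssx_tot
      y_var[h] <- q_h^2 * tt / ssy_tot
    }
    B <- drop(W %*% solve(crossprod(P, W), q))
  }
  object <- structure(
    list(
      intercept = y_mean - sum(x_mean * B),
      coefficients = stats::setNames(B, predictors),
      ncomp = ncomp, predictors = predictors, response = response, n = n,
      x_variance = if (ssy_tot == 0) rep(NA_real_, 0) else x_var,
      y_variance = if (ssy_tot == 0) rep(NA_real_, 0) else y_var
    ),
    class = "npk_pls"
  )
  object$fitted <- predict(object, data)
  object$r_squared <- if (ssy_tot == 0) NA_real_ else r_squared(y, object$fitted)
  object
}

#' @export
predict.npk_pls <- function(object, newdata, ...) {
  X <- as.matrix(newdata[object$predictors])
  drop(X %*% object$coefficients) + object$intercept
}

#' @export
coef.npk_pls <- function(object, ...) {
  c("(Intercept)" = object$intercept, object$coefficients)
}

#' Equation string of a linear-combination model
#'
#' @param model An `npk_pls` model.
#' @param digits Coefficient digits.
#' @return A string like `Y = 760.852 x X1 + 579.046 x X2 + ... + 7.325`.
#' @export
equation_string <- function(model, digits = 3) {
  stopifnot(inherits(model, "npk_pls"))
  terms <- sprintf(
    "%s x X%s", formatC(model$coefficients, format = "f", digits = digits),
    model$predictors
  )
  sprintf(
    "Y = %s + %s", paste(terms, collapse = " + "),
    formatC(model$intercept, format = "f", digits = digits)
  )
}

#' @export
print.npk_pls <- function(x, ...) {
  cat(sprintf(
    "<npk_pls> %s ~ %s; %d component(s); R2 = %.4f\n%s\n",
    x$response, paste(x$predictors, collapse = " + "), x$ncomp,
    x$r_squared, equation_string(x)
  ))
  invisible(x)
}

#' @method tidy npk_pls
#' @export
tidy.npk_pls <- function(x, ...) {
  tibble::tibble(
    term = c("(Intercept)", x$predictors),
    estimate = c(x$intercept, unname(x$coefficients))
  )
}

#' @method glance npk_pls
#' @export
glance.npk_pls <- function(x, ...) {
  tibble::tibble(
    r.squared = x$r_squared, ncomp = x$ncomp, nobs = x$n,
    x_variance_explained = sum(x$x_variance),
    y_variance_explained = sum(x$y_variance)
  )
}

#' Fit a single-hidden-layer neural network
#'
#' Feedforward network with one hidden layer (default 10 sigmoid units) and a
#' linear output, trained by full-batch quasi-Newton optimisation
#' ([nnet::nnet()]) on inputs and response min-max scaled to [0, 1] over the
#' training set. Deterministic under `seed`.
#'
#' @param data Data frame with predictor and response columns.
#' @param predictors Character vector of predictor column names.
#' @param response Response column name.
#' @param hidden Hidden units (default 10).
#' @param seed Integer seed for weight initialisation.
#' @param maxit Maximum training iterations.
#' @param decay Weight decay (default 0, no regularisation).
#' @return Object of class `npk_nn` wrapping the fitted network together
#'   with its scaling parameters, training fitted values and R-squared.
#' @export
fit_nn <- function(data, predictors, response, hidden = 10, seed = 1,
                   maxit = 2000, decay = 0) {
  X <- as.matrix(data[predictors])
  y <- data[[response]]
  storage.mode(X) <- "double"
  if (!all(is.finite(X)) || !all(is.finite(y))) {
    abort("non-finite values in predictors or response.")
  }
  x_min <- apply(X, 2, min); x_max <- apply(X, 2, max)
  if (any(x_max == x_min)) abort("constant predictor cannot be scaled.")
  y_min <- min(y); y_max <- max(y)
  if (y_max == y_min) abort("constant response cannot be scaled.")
  Xs <- sweep(sweep(X, 2, x_min), 2, x_max - x_min, "/")
  ys <- (y - y_min) / (y_max - y_min)
  fit <- with_seed_if(seed, nnet::nnet(Xs, ys,
    size = hidden, linout = TRUE, decay = decay, maxit = maxit,
    trace = FALSE, reltol = 1e-10, abstol = 1e-10
  ))
  object <- structure(
    list(
      fit = fit, predictors = predictors, response = response,
      hidden = hidden, seed = seed, n = nrow(X),
      x_min = x_min, x_max = x_max, y_min = y_min, y_max = y_max
    ),
    class = "npk_nn"
  )
  object$fitted <- predict(object, data)
  object$r_squared <- r_squared(y, object$fitted)
  object
}

#' @export
predict.npk_nn <- function(object, newdata, ...) {
  X <- as.matrix(newdata[object$predictors])
  Xs <- sweep(sweep(X, 2, object$x_min), 2, object$x_max - object$x_min, "/")
  ys <- drop(predict(object$fit, Xs))
  unname(ys * (object$y_max - object$y_min) + object$y_min)
}

#' @export
print.npk_nn <- function(x, ...) {
  cat(sprintf(
    "<npk_nn> %s ~ %s; %d hidden units; R2 = %.4f\n",
    x$response, paste(x$predictors, collapse = " + "), x$hidden, x$r_squared
  ))
  invisible(x)
}

#' @method tidy npk_nn
#' @export
tidy.npk_nn <- function(x, ...) {
  tibble::tibble(term = sprintf("w%d", seq_along(x$fit$wts)),
    estimate = x$fit$wts
  )
}

#' @method glance npk_nn
#' @export
glance.npk_nn <- function(x, ...) {
  tibble::tibble(
    r.squared = x$r_squared, hidden = x$hidden, nobs = x$n,
    converged = x$fit$convergence == 0
  )
}
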