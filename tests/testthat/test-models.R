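test_that("univariate families recover exact generating coefficients", {
  d <- data.frame(x = seq(0.5, 5, by = 0.5))
  d$y <- 1 + 2 * d$x
  lin <- fit_univariate(d, "x", "y", "linear")
  expect_equal(unname(coef(lin)), c(1, 2), tolerance = 1e-10)
  expect_equal(lin$r_squared, 1)

  d3 <- data.frame(x = c(-1, 0, 2))
  d3$y <- d3$x^2
  par <- fit_univariate(d3, "x", "y", "parabolic")
  expect_equal(unname(coef(par)), c(0, 0, 1), tolerance = 1e-8)

  de <- data.frame(x = seq(0, 2, length.out = 20))
  de$y <- 3 * exp(0.5 * de$x)
  ex <- fit_univariate(de, "x", "y", "exponential")
  expect_equal(unname(coef(ex)), c(3, 0.5), tolerance = 1e-6)
  ex_ll <- fit_univariate(de, "x", "y", "exponential", exp_method = "log-linear")
  expect_equal(unname(coef(ex_ll)), c(3, 0.5), tolerance = 1e-8)

  dl <- data.frame(x = seq(0.2, 4, by = 0.2))
  dl$y <- 2 + 3 * log(dl$x)
  lo <- fit_univariate(dl, "x", "y", "logarithmic")
  expect_equal(unname(coef(lo)), c(2, 3), tolerance = 1e-10)
})

test_that("univariate domain violations name the offending samples", {
  d <- data.frame(sample_id = c("a", "b", "c"), x = c(1, -2, 3), y = c(1, 2, 3))
  expect_error(fit_univariate(d, "x", "y", "logarithmic"), "b")
  d2 <- data.frame(sample_id = c("a", "b"), x = c(1, 2), y = c(1, -1))
  expect_error(fit_univariate(d2, "x", "y", "exponential"), "b")
  lo <- fit_univariate(
    data.frame(x = 1:5, y = log(1:5)), "x", "y", "logarithmic"
  )
  expect_error(predict(lo, -1), "non-positive")
})

test_that("univariate predictions evaluate the stored form", {
  d <- data.frame(x = 1:5)
  d$y <- 1 + 2 * d$x
  lin <- fit_univariate(d, "x", "y", "linear")
  expect_equal(predict(lin, 3), 7)
  expect_equal(predict(lin, data.frame(x = c(0, 10))), c(1, 21))
})

test_that("full-component PLS equals ordinary least squares", {
  set.seed(71)
  d <- data.frame(x1 = rnorm(30), x2 = rnorm(30), x3 = rnorm(30))
  d$y <- 2 + d$x1 - 2 * d$x2 + 0.5 * d$x3 + rnorm(30, 0, 0.2)
  pls <- fit_pls(d, c("x1", "x2", "x3"), "y", ncomp = 3)
  ols <- lm(y ~ x1 + x2 + x3, d)
  expect_equal(unname(coef(pls)), unname(coef(ols)), tolerance = 1e-8)
  expect_lt(max(abs(predict(pls, d) - unname(predict(ols, d)))), 1e-8)
})

test_that("PLS agrees with an independent NIPALS implementation at reduced rank", {
  skip_if_not_installed("mixOmics")
  set.seed(72)
  d <- data.frame(x1 = rnorm(25), x2 = rnorm(25), x3 = rnorm(25))
  d$y <- 1 + d$x1 + d$x2 + rnorm(25, 0, 0.3)
  for (nc in 1:2) {
    mine <- fit_pls(d, c("x1", "x2", "x3"), "y", ncomp = nc)
    ref <- mixOmics::pls(as.matrix(d[1:3]), d$y,
      ncomp = nc, mode = "regression", scale = FALSE
    )
    pref <- predict(ref, as.matrix(d[1:3]))$predict[, , nc]
    expect_equal(predict(mine, d), unname(pref), tolerance = 1e-10)
  }
})

test_that("PLS degenerate cases behave as specified", {
  set.seed(73)
  d <- data.frame(x1 = rnorm(15), x2 = rnorm(15), x3 = rnorm(15))
  d$y <- 5
  flat <- fit_pls(d, c("x1", "x2", "x3"), "y", ncomp = 2)
  expect_equal(unname(flat$coefficients), c(0, 0, 0))
  expect_equal(flat$intercept, 5)

  # centred model predicts the response mean at the predictor means
  d$y <- 1 + d$x1 + rnorm(15, 0, 0.1)
  pls <- fit_pls(d, c("x1", "x2", "x3"), "y", ncomp = 2)
  at_mean <- data.frame(x1 = mean(d$x1), x2 = mean(d$x2), x3 = mean(d$x3))
  expect_equal(predict(pls, at_mean), mean(d$y), tolerance = 1e-10)

  d$x3 <- d$x1 + d$x2 # rank 2
  expect_error(fit_pls(d, c("x1", "x2", "x3"), "y", ncomp = 3), "rank")
  expect_error(fit_pls(d, c("x1", "x2", "x3"), "y", ncomp = 0), "between")
})

test_that("PLS equation string mirrors the fitted coefficients", {
  d <- data.frame(x1 = 1:6, x2 = c(2, 1, 4, 3, 6, 5))
  d$y <- 1 + 2 * d$x1 - d$x2
  pls <- fit_pls(d, c("x1", "x2"), "y", ncomp = 2)
  eq <- equation_string(pls)
  expect_match(eq, "^Y = ")
  expect_match(eq, "2\\.000 x Xx1")
})

test_that("the neural network learns a linear map and is seed-deterministic", {
  set.seed(74)
  d <- data.frame(x1 = rnorm(60), x2 = rnorm(60), x3 = rnorm(60))
  d$y <- 1 + 2 * d$x1 - d$x2 + 0.5 * d$x3 + rnorm(60, 0, 0.01)
  nn1 <- fit_nn(d, c("x1", "x2", "x3"), "y", seed = 5)
  expect_gt(nn1$r_squared, 0.99)
  nn2 <- fit_nn(d, c("x1", "x2", "x3"), "y", seed = 5)
  expect_identical(nn1$fit$wts, nn2$fit$wts)
  expect_equal(predict(nn1, d), predict(nn2, d))
})

test_that("network predictions equal a manual forward pass through the weights", {
  set.seed(75)
  d <- data.frame(x1 = runif(30), x2 = runif(30), x3 = runif(30))
  d$y <- d$x1 + d$x2^2 + rnorm(30, 0, 0.05)
  nn <- fit_nn(d, c("x1", "x2", "x3"), "y", hidden = 4, seed = 2)
  X <- as.matrix(d[1:3])
  Xs <- sweep(sweep(X, 2, nn$x_min), 2, nn$x_max - nn$x_min, "/")
  w <- nn$fit$wts
  # layout: 4 hidden units x (bias + 3 inputs), then output bias + 4
  H <- matrix(w[1:16], nrow = 4, byrow = TRUE)
  out_w <- w[17:21]
  z <- plogis(cbind(1, Xs) %*% t(H))
  ys <- drop(cbind(1, z) %*% out_w)
  manual <- ys * (nn$y_max - nn$y_min) + nn$y_min
  expect_equal(predict(nn, d), manual, tolerance = 1e-10)
})

test_that("the network does not hallucinate signal from pure noise", {
  set.seed(76)
  r2_val <- replicate(20, {
    d <- data.frame(x1 = rnorm(48), x2 = rnorm(48), x3 = rnorm(48))
    d$y <- rnorm(48)
    v <- data.frame(x1 = rnorm(24), x2 = rnorm(24), x3 = rnorm(24))
    v$y <- rnorm(24)
    nn <- fit_nn(d, c("x1", "x2", "x3"), "y", seed = sample.int(1e6, 1))
    r_squared(v$y, predict(nn, v))
  })
  expect_lt(median(r2_val), 0.3)
})

test_that("model fits are invariant to sample order", {
  set.seed(77)
  d <- data.frame(x1 = rnorm(20), x2 = rnorm(20), x3 = rnorm(20))
  d$y <- 1 + d$x1 - d$x2 + rnorm(20, 0.1)
  perm <- sample(20)
  pls1 <- fit_pls(d, c("x1", "x2", "x3"), "y", ncomp = 2)
  pls2 <- fit_pls(d[perm, ], c("x1", "x2", "x3"), "y", ncomp = 2)
  expect_equal(coef(pls1), coef(pls2), tolerance = 1e-10)
  lin1 <- fit_univariate(d, "x1", "y", "linear")
  lin2 <- fit_univariate(d[perm, ], "x1", "y", "linear")
  expect_equal(coef(lin1), coef(lin2), tolerance = 1e-10)
})

test_that("tidy and glance summarise fitted models", {
  d <- data.frame(x = 1:10)
  d$y <- 2 * d$x + 1
  lin <- fit_univariate(d, "x", "y", "linear")
  expect_equal(tidy(lin)$term, c("a", "b"))
  expect_equal(glance(lin)$r.squared, 1)
  d$x2 <- c(3, 1, 4, 1, 5, 9, 2, 6, 5, 3)
  pls <- fit_pls(d, c("x", "x2"), "y", ncomp = 2)
  expect_equal(tidy(pls)$term[1], "(Intercept)")
  expect_equal(glance(pls)$ncomp, 2)
})
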