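test_that("pearson correlation matches a direct-summation oracle", {
  x <- 1:10
  expect_equal(pearson_r(x, 2 * x + 1), 1)
  expect_equal(pearson_r(x, -x), -1)
  set.seed(51)
  a <- rnorm(50)
  b <- 0.4 * a + rnorm(50)
  oracle <- sum((a - mean(a)) * (b - mean(b))) /
    sqrt(sum((a - mean(a))^2) * sum((b - mean(b))^2))
  expect_equal(pearson_r(a, b), oracle, tolerance = 1e-12)
  expect_error(pearson_r(rep(1, 10), rnorm(10)), "zero variance")
  expect_error(pearson_r(1:3, 1:4), "equal length")
})

test_that("correlation significance follows the t reference distribution", {
  expect_equal(correlation_significance(0, 30)$p, 1)
  s <- correlation_significance(0.905, 72)
  expect_true(s$sig_01 && s$sig_05)
  expect_equal(s$stars, "**")
  # independent oracle: two-sided t tail
  r <- 0.31; n <- 40
  t <- r * sqrt((n - 2) / (1 - r^2))
  expect_equal(correlation_significance(r, n)$p, 2 * pt(-t, n - 2))
  expect_equal(correlation_significance(1, 10)$p, 0)
  # monotone: larger |r| at fixed n never loses a flag
  flags <- correlation_significance(seq(0, 0.99, by = 0.01), 20)
  expect_true(all(diff(flags$sig_05) >= 0))
  expect_true(all(diff(flags$sig_01) >= 0))
})

test_that("correlation tables cover every variable and match the loop oracle", {
  ds <- simulate_npk_dataset(sim_config(n_per_treatment = 8, seed = 6))
  feats <- extract_features(ds$spectra)
  y <- ds$samples$nitrogen
  tab <- correlation_table(feats, y)
  expect_equal(nrow(tab), 24)
  for (i in seq_len(nrow(tab))) {
    expect_equal(tab$r[i], pearson_r(feats[[tab$variable[i]]], y))
  }
  self <- correlation_table(tibble::tibble(v = y), y)
  expect_equal(self$r, 1)

  feats$flat <- 1
  tab2 <- correlation_table(feats, y)
  expect_true(is.na(tab2$r[tab2$variable == "flat"]))
  expect_match(tab2$note[tab2$variable == "flat"], "constant")
})

test_that("a planted detail coefficient is recovered as the top sensitivity coefficient", {
  set.seed(61)
  wl <- seq(400, 1000, length.out = 64)
  spectra <- make_spectra(random_spectra_matrix(16, 64), wl)
  target <- vapply(seq_len(16), function(i) {
    dec <- swt_decompose(spectra[i, ], "db3", levels = 5)
    coefficient_at(dec, "D", 5, 20)
  }, numeric(1))
  y <- 2 * target + 1
  sel <- select_sensitivity_coefficients(spectra, y, levels = 5, k = 3)
  expect_equal(sel$basis[1], "db3")
  expect_equal(sel$level[1], 5)
  expect_equal(sel$band_index[1], 20)
  expect_equal(abs(sel$r[1]), 1, tolerance = 1e-10)
  expect_true(all(diff(abs(sel$r)) <= 1e-12))
})

test_that("selection equals brute-force enumeration over every coefficient", {
  set.seed(62)
  wl <- seq(400, 1000, length.out = 32)
  spectra <- make_spectra(random_spectra_matrix(10, 32), wl)
  y <- rnorm(10)
  bases <- c("db2", "db3")
  # oracle: enumerate every (basis, level, band) with per-spectrum decompose
  oracle <- purrr::map_dfr(bases, function(b) {
    decs <- lapply(seq_len(10), function(i) swt_decompose(spectra[i, ], b, 3))
    purrr::map_dfr(1:3, function(j) {
      purrr::map_dfr(1:32, function(k) {
        vals <- vapply(decs, function(d) d$D[j, k], numeric(1))
        tibble::tibble(
          basis = b, level = j, band_index = k,
          r = if (sd(vals) > 0) cor(vals, y) else NA_real_
        )
      })
    })
  }) |>
    dplyr::filter(!is.na(r)) |>
    dplyr::mutate(basis_rank = match(basis, c("db2", "db3"))) |>
    dplyr::arrange(dplyr::desc(abs(r)), basis_rank, level, band_index)
  sel <- select_sensitivity_coefficients(spectra, y,
    bases = bases, levels = 3, k = 5
  )
  expect_equal(sel$basis, oracle$basis[1:5])
  expect_equal(sel$level, oracle$level[1:5])
  expect_equal(sel$band_index, oracle$band_index[1:5])
  expect_equal(sel$r, oracle$r[1:5], tolerance = 1e-12)
  expect_error(
    select_sensitivity_coefficients(spectra, y, bases = "db2", levels = 2, k = 100),
    "exceeds"
  )
})

test_that("selection is invariant to sample order", {
  set.seed(63)
  wl <- seq(400, 1000, length.out = 48)
  spectra <- make_spectra(random_spectra_matrix(12, 48), wl)
  y <- rnorm(12)
  sel1 <- select_sensitivity_coefficients(spectra, y, bases = "db4", levels = 3)
  perm <- sample(12)
  sel2 <- select_sensitivity_coefficients(spectra[perm, ], y[perm],
    bases = "db4", levels = 3
  )
  expect_equal(sel1$name, sel2$name)
  expect_equal(sel1$r, sel2$r, tolerance = 1e-12)
})

test_that("sensitivity predictors reproduce per-spectrum coefficients", {
  set.seed(64)
  wl <- seq(400, 1000, length.out = 64)
  spectra <- make_spectra(random_spectra_matrix(8, 64), wl)
  y <- rnorm(8)
  sel <- select_sensitivity_coefficients(spectra, y, levels = 4, k = 3)
  preds <- sensitivity_predictors(spectra, sel)
  for (j in seq_len(nrow(sel))) {
    manual <- vapply(seq_len(8), function(i) {
      dec <- swt_decompose(spectra[i, ], sel$basis[j], levels = sel$level[j])
      coefficient_at(dec, "D", sel$level[j], sel$band_index[j])
    }, numeric(1))
    expect_equal(preds[[sel$name[j]]], manual, tolerance = 1e-10)
  }
})
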