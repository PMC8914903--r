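wl20 <- seq(400, 1000, length.out = 20)

test_that("radiometric correction matches the reference formula", {
  set.seed(4)
  white <- make_spectra(matrix(runif(20, 0.8, 1), 1), wl20, "WHITE")
  dark <- make_spectra(matrix(runif(20, 0, 0.05), 1), wl20, "DARK")
  iw <- unlist(white[1, -1]); id <- unlist(dark[1, -1])

  raw_iw <- make_spectra(matrix(iw, 1), wl20, "S1")
  out <- radiometric_correct(raw_iw, white, dark)
  expect_equal(unname(unlist(out[1, -1])), rep(0, 20))

  # a band ratio of 0.1 maps to -1 under the log10 form
  tenth <- make_spectra(matrix(id + 0.1 * (iw - id), 1), wl20, "S1")
  out <- radiometric_correct(tenth, white, dark)
  expect_equal(unname(unlist(out[1, -1])), rep(-1, 20), tolerance = 1e-12)

  # random raw spectra: element-wise re-evaluation oracle, both modes
  raw <- make_spectra(
    matrix(runif(60, 0.1, 0.7), 3) + matrix(id, 3, 20, byrow = TRUE), wl20
  )
  got <- radiometric_correct(raw, white, dark)
  ratio <- sweep(sweep(as.matrix(raw[-1]), 2, id), 2, iw - id, "/")
  expect_equal(unname(as.matrix(got[-1])), unname(log10(ratio)),
    tolerance = 1e-12
  )
  got_ratio <- radiometric_correct(raw, white, dark, mode = "ratio")
  expect_equal(unname(as.matrix(got_ratio[-1])), unname(ratio),
    tolerance = 1e-12
  )

  # ratio-mode correction is invertible back to raw counts
  rec <- sweep(sweep(as.matrix(got_ratio[-1]), 2, iw - id, "*"), 2, id, "+")
  expect_equal(unname(rec), unname(as.matrix(raw[-1])), tolerance = 1e-10)
})

test_that("radiometric correction reports degenerate bands and samples", {
  white <- make_spectra(matrix(rep(1, 20), 1), wl20, "WHITE")
  dark0 <- make_spectra(matrix(rep(0, 20), 1), wl20, "DARK")
  bad_white <- white
  bad_white[[5]] <- 0 # white == dark at the 4th band
  raw <- make_spectra(matrix(rep(0.5, 20), 1), wl20, "S1")
  expect_error(
    radiometric_correct(raw, bad_white, dark0),
    "does not exceed dark reference at band"
  )
  below_dark <- make_spectra(matrix(rep(-0.1, 20), 1), wl20, "S1")
  expect_error(radiometric_correct(below_dark, white, dark0), "log10")
  expect_silent(radiometric_correct(below_dark, white, dark0, mode = "ratio"))
})

test_that("replicate averaging is the band-wise mean", {
  one <- make_spectra(matrix(runif(20), 1), wl20, "L1")
  four <- dplyr::bind_rows(one, one, one, one)
  expect_equal(average_replicates(four), one, ignore_attr = TRUE)

  two <- make_spectra(rbind(rep(0.2, 20), rep(0.4, 20)), wl20, c("L1", "L1"))
  avg <- average_replicates(two)
  expect_equal(unname(unlist(avg[1, -1])), rep(0.3, 20))

  set.seed(9)
  reps <- make_spectra(matrix(runif(80), 4), wl20, rep("L1", 4))
  avg <- average_replicates(reps)
  expect_equal(
    unname(unlist(avg[1, -1])),
    unname(colMeans(as.matrix(reps[-1])))
  )
  expect_equal(attr(avg, "n_replicates")$n_replicates, 4L)

  other_grid <- make_spectra(matrix(runif(20), 1), wl20 + 1, "L1")
  expect_error(average_replicates(list(one, other_grid)), "grids")
})

test_that("outlier screening flags gross outliers and spares clean data", {
  ds <- simulate_npk_dataset(sim_config(n_per_treatment = 8, seed = 3))
  clean <- remove_outliers(ds$spectra, ds$samples)
  expect_equal(nrow(clean$removed), 0)
  expect_equal(clean$spectra, ds$spectra)

  spiked <- ds$spectra
  spiked[5, -1] <- as.list(rep(5, ncol(spiked) - 1)) # 10x out of range
  res <- remove_outliers(spiked, ds$samples)
  expect_true(ds$spectra$sample_id[5] %in% res$removed$sample_id)
  expect_false(ds$spectra$sample_id[5] %in% res$spectra$sample_id)
  expect_equal(nrow(res$spectra), nrow(res$samples))

  res_none <- remove_outliers(spiked, ds$samples, method = "none")
  expect_equal(res_none$spectra, spiked)
  expect_error(remove_outliers(ds$spectra[1:5, ]), "at least 10")
})

test_that("modeling/validation split partitions samples reproducibly", {
  ids <- sprintf("S%02d", 1:72)
  sp <- split_modeling_validation(ids, seed = 21)
  expect_length(sp$modeling_ids, 48)
  expect_length(sp$validation_ids, 24)
  expect_setequal(c(sp$modeling_ids, sp$validation_ids), ids)
  expect_length(intersect(sp$modeling_ids, sp$validation_ids), 0)
  sp2 <- split_modeling_validation(ids, seed = 21)
  expect_identical(sp, sp2)

  tiny <- split_modeling_validation(c("a", "b", "c"), seed = 1)
  expect_length(tiny$modeling_ids, 2)
  expect_length(tiny$validation_ids, 1)

  strat <- split_modeling_validation(ids,
    seed = 5, stratify = rep(c("N0", "N1", "N2"), each = 24)
  )
  expect_length(strat$modeling_ids, 48)
  expect_error(split_modeling_validation(c("a", "b")), "at least 3")
})
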