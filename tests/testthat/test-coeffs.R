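test_that("biased autocorrelation matches direct summation and closed forms", {
  set.seed(4)
  x <- rnorm(500)
  expect_equal(as.numeric(acf_biased(x, 6)), oracle_acf(x, 6), tolerance = 1e-12)
  # constant signal: R(k) = c^2 (N - k) / N without demeaning
  N <- 100; cst <- rep(3, N)
  expect_equal(as.numeric(acf_biased(cst, 4)), 9 * (N - 0:4) / N)
  # alternating signal has negative lag-1 autocorrelation
  alt <- rep(c(1, -1), 50)
  expect_lt(acf_biased(alt, 1)[2], 0)
  # AR(1) with rho = 0.5: lag-1 autocorrelation near rho
  y <- synth_ar(0.5, 1, n = 1e5, seed = 6)
  R <- acf_biased(y, 1, demean = TRUE)
  expect_lt(abs(R[2] / R[1] - 0.5), 0.02)
})

test_that("Levinson-Durbin solves worked systems and flags degeneracy", {
  expect_equal(levinson(c(1, 0.5), 1)$coefficients, 0.5)
  expect_equal(levinson(c(1, 0.5, 0.25), 2)$coefficients, c(0.5, 0))
  expect_equal(levinson(c(2.0, 1.0, 0.8), 2)$coefficients,
               oracle_toeplitz_lp(c(2.0, 1.0, 0.8), 2))
  expect_equal(levinson(c(2.0, 1.0, 0.8), 2)$coefficients, c(0.4, 0.2))
  expect_error(levinson(c(0, 0.5), 1), "degenerate")
  expect_error(levinson(c(1, 1, 1), 2), "degenerate")
})

test_that("Levinson-Durbin agrees with a dense Toeplitz solve on random PSD systems", {
  set.seed(19)
  for (rep in 1:200) {
    p <- sample(1:8, 1)
    # autocorrelations of a genuine random signal are PSD by construction
    x <- rnorm(80 + 5 * p) + 0.5 * sin(seq_len(80 + 5 * p) / 3)
    R <- oracle_acf(x, p)
    expect_lt(max(abs(levinson(R, p)$coefficients - oracle_toeplitz_lp(R, p))),
              1e-9)
  }
})

test_that("lp_fit recovers known AR coefficients from simulated data", {
  x <- synth_ar(0.9, 1, n = 1e5, seed = 5)
  f1 <- lp_fit(x, order = 1, demean = TRUE)
  expect_lt(abs(coef(f1)[["a1"]] - 0.9), 0.02)
  ar2 <- c(1.2, -0.5)
  y <- synth_ar(ar2, 1, n = 1e5, seed = 23)
  f2 <- lp_fit(y, order = 2, demean = TRUE)
  expect_lt(max(abs(coef(f2) - ar2)), 0.02)
  ar4 <- c(0.6, 0.1, 0.05, 0.05)
  z <- synth_ar(ar4, 1, n = 1e5, seed = 29)
  f4 <- lp_fit(z, order = 4, demean = TRUE)
  expect_lt(max(abs(coef(f4) - ar4)), 0.02)
})

test_that("lp_fit on a constant record behaves per the closed form", {
  N <- 2000L
  rec <- ecg_record(rep(50L, N), fs = 100, bits = 8)
  f <- lp_fit(rec, order = 1, demean = FALSE)
  expect_equal(coef(f)[["a1"]], (N - 1) / N)
  expect_error(lp_fit(rec, order = 1, demean = TRUE), "degenerate")
})

test_that("lp_fit methods are mutually consistent", {
  x <- synth_ar(0.8, 2, n = 5000, seed = 44)
  f <- lp_fit(x, order = 2)
  pr <- predict(f)
  expect_true(all(is.na(pr[1:2])) && !anyNA(pr[-(1:2)]))
  r <- residuals(f)
  expect_equal(r[-(1:2)], (x - pr)[-(1:2)])
  a <- coef(f)
  n <- 1000
  expect_equal(pr[n], a[["a1"]] * x[n - 1] + a[["a2"]] * x[n - 2])
})

test_that("averaging pools same-order sets and rejects mixed orders", {
  expect_identical(lp_average(list(c(1, -1), c(3, 1))), c(2, 0))
  expect_identical(lp_average(list(c(1.5, 0.5))), c(1.5, 0.5))
  expect_error(lp_average(list(c(1, 2), c(1, 2, 3))), "mixed")
  expect_error(lp_average(list()), "at least one")
})

test_that("integer rounding reproduces the published rounded coefficient tables", {
  ref <- reference_lp_averages()
  # frozen published rounded values for the three databases, orders 1-4
  expected <- list(
    mitdb = list(`1` = 1L, `2` = c(2L, -1L), `3` = c(2L, -2L, 0L),
                 `4` = c(2L, -1L, 0L, 0L)),
    ptbdb = list(`1` = 1L, `2` = c(2L, -1L), `3` = c(2L, -1L, 0L),
                 `4` = c(2L, -1L, 0L, 0L)),
    edb = list(`1` = 1L, `2` = c(2L, -1L), `3` = c(2L, -2L, 0L),
               `4` = c(2L, -2L, 0L, 0L)))
  for (db in names(expected))
    for (ord in names(expected[[db]]))
      expect_identical(lp_round(ref[[db]][[ord]]), expected[[db]][[ord]],
                       info = paste(db, "order", ord))
})

test_that("order-2 prediction is nearly as good as order-4 on synthetic ECG", {
  rec <- synth_ecg(acquisition_preset("mitdb"), duration_s = 20, seed = 9,
                   noise_sd_mv = 0.02)
  x <- record_lead(rec)
  mae <- vapply(c(2, 4), function(p)
    mean(abs(residuals(lp_fit(x, order = p))), na.rm = TRUE), numeric(1))
  expect_lt(mae[1], 1.05 * mae[2])
})

test_that("dataset-wide coefficient fitting pools, averages and rounds", {
  recs <- lapply(1:4, function(i)
    synth_ecg(acquisition_preset("edb"), duration_s = 8, seed = 100 + i,
              noise_sd_mv = 0.02))
  names(recs) <- paste0("rec", 1:4)
  fc <- fit_dataset_coefficients(recs, order = 2)
  expect_identical(nrow(fc$per_record), 4L)
  expect_equal(fc$average,
               unname(colMeans(as.matrix(fc$per_record[, c("a1", "a2")]))))
  expect_identical(fc$rounded, lp_round(fc$average))
})
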