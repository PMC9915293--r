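test_that("polynomial sequences are exact integers", {
  expect_identical(synth_polynomial(7, 10), rep(7L, 10))
  expect_identical(synth_polynomial(c(0, 1), 5), 0:4)
  expect_identical(synth_polynomial(c(0, 0, 1), 5), c(0L, 1L, 4L, 9L, 16L))
  expect_error(synth_polynomial(c(1, 2, 3, 4, 5), 10), "degree")
  expect_error(synth_polynomial(c(0.5, 1), 10), "integers")
})

test_that("AR generator is seed-deterministic, stable-only, leaves the RNG alone", {
  expect_identical(synth_ar(0.9, 1, 500, seed = 2), synth_ar(0.9, 1, 500, seed = 2))
  expect_false(identical(synth_ar(0.9, 1, 500, seed = 2),
                         synth_ar(0.9, 1, 500, seed = 3)))
  expect_error(synth_ar(1.1, 1, 100, seed = 1), "unstable")
  set.seed(123); before <- runif(1)
  set.seed(123); invisible(synth_ar(0.5, 1, 100, seed = 9)); after <- runif(1)
  expect_identical(before, after)
  # white noise case: negligible lag-1 autocorrelation
  w <- synth_ar(0, 1, n = 1e5, seed = 11)
  R <- oracle_acf(w - mean(w), 1)
  expect_lt(abs(R[2] / R[1]), 0.02)
})

test_that("synthetic ECG has the right sample count, beats and determinism", {
  rec <- synth_ecg(acquisition_preset("mitdb"), duration_s = 10,
                   heart_rate_bpm = 60, seed = 1)
  x <- record_lead(rec)
  expect_identical(length(x), 3600L)
  # count R peaks: local maxima above half the global maximum
  peaks <- which(diff(sign(diff(x))) == -2) + 1L
  peaks <- peaks[x[peaks] > max(x) / 2]
  expect_identical(length(peaks), 10L)
  rec2 <- synth_ecg(acquisition_preset("mitdb"), duration_s = 10,
                    heart_rate_bpm = 60, seed = 1)
  expect_identical(record_lead(rec2), x)
})

test_that("degenerate morphology gives a constant baseline signal", {
  flat <- beat_morphology(amplitudes = c(P = 0, Q = 0, R = 0, S = 0, T = 0))
  rec <- synth_ecg(acquisition_preset("edb"), duration_s = 5, morphology = flat)
  expect_identical(unique(record_lead(rec)), 0L)
})

test_that("generated samples always fit the preset resolution; clipping warns", {
  for (p in c("mitdb", "edb", "ptbdb")) {
    pre <- acquisition_preset(p)
    rec <- synth_ecg(pre, duration_s = 5, noise_sd_mv = 0.05,
                     baseline_wander_mv = 0.5, seed = 14)
    x <- record_lead(rec)
    expect_true(all(x >= -2^(pre$bits - 1) & x <= 2^(pre$bits - 1) - 1))
  }
  big <- beat_morphology(amplitudes = c(P = 0.1, Q = -0.1, R = 40, S = -0.2,
                                        T = 0.3))
  expect_warning(synth_ecg(acquisition_preset("mitdb"), duration_s = 3,
                           morphology = big), "clipped")
})

test_that("higher-resolution acquisition yields larger selected residuals", {
  # same mV morphology: the 16-bit 2000 ADU/mV setup sees larger ADU
  # residual magnitudes than the 11-bit 200 ADU/mV one
  mean_sel_err <- function(preset) {
    rec <- synth_ecg(acquisition_preset(preset), duration_s = 10, seed = 40,
                     noise_sd_mv = 0.005)
    em <- alp_error_matrix(record_lead(rec))
    mean(apply(abs(em), 1, min))
  }
  expect_gt(mean_sel_err("ptbdb"), mean_sel_err("mitdb"))
})

test_that("fixture suite is stable, named, and codec-compatible", {
  fx <- fixture_suite(seed = 2, duration_s = 4)
  expect_identical(length(fx), 9L)
  expect_setequal(names(fx), as.vector(outer(c("mitdb", "edb", "ptbdb"),
                                             c("clean", "noisy", "wandering"),
                                             paste, sep = "_")))
  fx2 <- fixture_suite(seed = 2, duration_s = 4)
  expect_identical(lapply(fx, record_lead), lapply(fx2, record_lead))
  for (nm in c("mitdb_noisy", "ptbdb_wandering")) {
    pk <- ecg_compress(fx[[nm]])
    expect_identical(record_lead(ecg_decompress(pk)), record_lead(fx[[nm]]))
  }
})

test_that("compression degrades gracefully from clean ECG to pure noise", {
  clean <- synth_ecg(acquisition_preset("mitdb"), duration_s = 10, seed = 3)
  expect_gt(compression_report(ecg_compress(clean))$cr, 1.5)
  noise <- random_test_record(3600, bits = 11L, seed = 50)
  expect_lt(compression_report(ecg_compress(noise))$cr, 1.1)
})
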