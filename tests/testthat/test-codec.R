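test_that("a constant lead codes to one bit per sample and round-trips", {
  rec <- ecg_record(rep(7L, 1000), fs = 360, bits = 11)
  pk <- ecg_compress(rec, mode = "causal")
  expect_identical(pk$leads[[1]]$nbits, 996)  # 996 zero-residuals at k = 0
  expect_identical(record_lead(ecg_decompress(pk)), rep(7L, 1000))
})

test_that("both modes round-trip random and structured signals exactly", {
  set.seed(5)
  for (rep in 1:25) {
    bits <- sample(c(8L, 11L, 12L, 16L), 1)
    rec <- random_test_record(sample(5:800, 1), bits = bits, seed = rep)
    for (mode in c("causal", "side_info")) {
      pk <- ecg_compress(rec, mode = mode)
      out <- ecg_decompress(pk)
      expect_identical(record_lead(out), record_lead(rec))
      expect_identical(prd(record_lead(rec), record_lead(out)), 0)
    }
  }
  # structured: clean synthetic ECG in all three presets
  for (p in c("mitdb", "edb", "ptbdb")) {
    rec <- synth_ecg(acquisition_preset(p), duration_s = 5, seed = 12,
                     noise_sd_mv = 0.01)
    for (mode in c("causal", "side_info"))
      expect_identical(record_lead(ecg_decompress(ecg_compress(rec, mode))),
                       record_lead(rec))
  }
})

test_that("the decoder replays the encoder's order and k sequences", {
  rec <- synth_ecg(acquisition_preset("mitdb"), duration_s = 6, seed = 31,
                   noise_sd_mv = 0.02)
  for (mode in c("causal", "side_info")) {
    pk <- ecg_compress(rec, mode = mode, trace = TRUE)
    dec <- alpcodec:::.alp_decode_cpp(pk$leads[[1]]$payload, pk$leads[[1]]$nbits,
                                      pk$n, pk$leads[[1]]$init,
                                      if (mode == "side_info") 1L else 0L,
                                      pk$k_max, TRUE)
    expect_identical(dec$orders, pk$leads[[1]]$orders)
    expect_identical(dec$ks, pk$leads[[1]]$ks)
  }
})

test_that("side-info accounting equals Rice cost plus two order bits per sample", {
  rec <- synth_ecg(acquisition_preset("edb"), duration_s = 6, seed = 8,
                   noise_sd_mv = 0.03)
  pk <- ecg_compress(rec, mode = "side_info", trace = TRUE)
  ld <- pk$leads[[1]]
  m <- rice_map(ld$errors)
  rice_bits <- sum(m %/% 2^ld$ks + 1 + ld$ks)
  expect_identical(ld$nbits, rice_bits + 2 * (pk$n - 4))
  # causal mode: the same identity without the order-bit overhead
  pk2 <- ecg_compress(rec, mode = "causal", trace = TRUE)
  ld2 <- pk2$leads[[1]]
  m2 <- rice_map(ld2$errors)
  expect_identical(ld2$nbits, sum(m2 %/% 2^ld2$ks + 1 + ld2$ks))
})

test_that("multi-lead records compress per lead and round-trip", {
  set.seed(77)
  leads <- list(v1 = sample(-500:500, 400, replace = TRUE),
                v2 = cumsum(sample(-3:3, 400, replace = TRUE)))
  rec <- ecg_record(leads, fs = 250, bits = 12)
  pk <- ecg_compress(rec)
  out <- ecg_decompress(pk)
  expect_identical(out$leads$v1, rec$leads$v1)
  expect_identical(out$leads$v2, rec$leads$v2)
  expect_identical(names(out$leads), c("v1", "v2"))
})

test_that("container serialization is deterministic and exact", {
  rec <- synth_ecg(acquisition_preset("mitdb"), duration_s = 4, seed = 3,
                   noise_sd_mv = 0.01)
  pk <- ecg_compress(rec, mode = "side_info")
  b1 <- alpc_serialize(pk)
  b2 <- alpc_serialize(ecg_compress(rec, mode = "side_info"))
  expect_identical(b1, b2)  # same input + config -> byte-identical
  pk2 <- alpc_deserialize(b1)
  expect_identical(pk2$mode, "side_info")
  expect_identical(pk2$bits, pk$bits)
  expect_identical(pk2$fs, pk$fs)
  expect_identical(record_lead(ecg_decompress(pk2)), record_lead(rec))

  path <- tempfile(fileext = ".alpc")
  write_alpc(pk, path)
  expect_identical(record_lead(ecg_decompress(read_alpc(path))),
                   record_lead(rec))
  unlink(path)
})

test_that("malformed containers are rejected with clear errors", {
  rec <- ecg_record(rep(3L, 50), fs = 100, bits = 8)
  b <- alpc_serialize(ecg_compress(rec))
  bad <- b; bad[1] <- as.raw(0x5A)
  expect_error(alpc_deserialize(bad), "magic")
  badv <- b; badv[5] <- as.raw(9)
  expect_error(alpc_deserialize(badv), "version")
  expect_error(alpc_deserialize(b[1:25]), "truncated")
})

test_that("a header-only packet with four samples decodes to the raw samples", {
  rec <- ecg_record(rep(3L, 50), fs = 100, bits = 8)
  pk <- ecg_compress(rec)
  pk$n <- 4L
  pk$leads[[1]]$payload <- raw(0)
  pk$leads[[1]]$nbits <- 0
  degenerate <- alpc_deserialize(alpc_serialize(pk))
  expect_identical(record_lead(ecg_decompress(degenerate)), rep(3L, 4))
})

test_that("compression ratio and PRD follow their definitions", {
  expect_identical(compression_ratio(11000, 11000), 1)
  expect_equal(compression_ratio(11000, 3125), 3.52)
  expect_identical(compression_ratio(2 * 4321, 4321), 2)
  expect_error(compression_ratio(100, 0), "positive")
  x <- round(100 * sqrt(500) * sin(1:500))
  expect_identical(prd(x, x), 0)
  expect_gt(prd(x, x + 1), 0)
  expect_error(prd(1:5, 1:4), "mismatch")
})

test_that("constant-lead CR approaches the bit resolution in causal mode", {
  n <- 1e5L
  rec <- ecg_record(rep(-100L, n), fs = 360, bits = 11)
  cr <- compression_report(ecg_compress(rec, mode = "causal"))$cr
  expect_lt(abs(cr - 11) / 11, 0.01)
})

test_that("too-short and out-of-range inputs are refused", {
  expect_error(ecg_compress(ecg_record(1:4, fs = 1, bits = 8)), "at least 5")
  expect_error(ecg_record(c(0L, 300L), fs = 1, bits = 8), "range")
})

test_that("dataset evaluation averages per-lead CRs unweighted", {
  recs <- list(a = random_test_record(300, seed = 1),
               b = random_test_record(300, seed = 2))
  ev <- evaluate_dataset(recs, mode = "causal")
  expect_identical(nrow(ev$table), 2L)
  expect_equal(ev$mean_cr, mean(ev$table$cr))
  expect_true(all(ev$table$prd == 0))
  one <- evaluate_dataset(recs[1])
  expect_equal(one$mean_cr, one$table$cr[1])
})
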