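#' Acquisition presets mirroring the standard evaluation databases
#'
#' Three built-in acquisition setups matching the public databases
#' commonly used to benchmark ECG codecs: PTB Diagnostic (1000 Hz, 16-bit,
#' 2000 ADU/mV), European ST-T (250 Hz, 12-bit, 200 ADU/mV) and MIT-BIH
#' Arrhythmia (360 Hz, 11-bit, 200 ADU/mV).
#'
#' @param name `"mitdb"`, `"edb"` or `"ptbdb"`.
#' @return list with `name`, `fs` (Hz), `bits` and `adu_per_mv`, class
#'   `acquisition_preset`.
#' @export
acquisition_preset <- function(name = c("mitdb", "edb", "ptbdb")) {
  name <- match.arg(name)
  p <- switch(name,
    mitdb = list(name = "mitdb", fs = 360, bits = 11L, adu_per_mv = 200),
    edb   = list(name = "edb",   fs = 250, bits = 12L, adu_per_mv = 200),
    ptbdb = list(name = "ptbdb", fs = 1000, bits = 16L, adu_per_mv = 2000))
  structure(p, class = "acquisition_preset")
}

#' @export
print.acquisition_preset <- function(x, ...) {
  cat(sprintf("Acquisition preset '%s': %g Hz, %d-bit, %g ADU/mV\n",
              x$name, x$fs, x$bits, x$adu_per_mv))
  invisible(x)
}

#' Default beat morphology
#'
#' Gaussian-bump parameterization of one heartbeat: per wave (P, Q, R, S,
#' T) an amplitude in mV, a center as a fraction of the beat period, and a
#' width in seconds. The default is a plausible sinus-rhythm lead-II
#' shape with the R wave dominant. A full dynamical ECG model is
#' deliberately out of scope: the codec tests only need realistic
#' alternation of flat and steep regions.
#'
#' @param amplitudes,centers,widths named numeric vectors over
#'   `c("P","Q","R","S","T")`.
#' @return list of per-wave parameters, class `beat_morphology`.
#' @export
beat_morphology <- function(
    amplitudes = c(P = 0.12, Q = -0.10, R = 1.10, S = -0.25, T = 0.30),
    centers = c(P = 0.18, Q = 0.37, R = 0.40, S = 0.43, T = 0.65),
    widths = c(P = 0.025, Q = 0.010, R = 0.012, S = 0.010, T = 0.045)) {
  waves <- c("P", "Q", "R", "S", "T")
  stopifnot(setequal(names(amplitudes), waves), setequal(names(centers), waves),
            setequal(names(widths), waves), all(widths > 0))
  structure(list(amplitudes = amplitudes[waves], centers = centers[waves],
                 widths = widths[waves]), class = "beat_morphology")
}

#' Exact integer polynomial sequences
#'
#' `x(n) = sum_i c[i+1] * n^i` over `n = 0..length-1`, exact integers.
#' These are the canonical fixtures for the binomial predictors: an
#' order-p predictor annihilates any polynomial of degree p-1.
#'
#' @param coeffs integer polynomial coefficients, constant term first;
#'   degree = `length(coeffs) - 1` must be at most 3.
#' @param n sequence length.
#' @return integer vector of length `n`.
#' @examples
#' synth_polynomial(c(0, 0, 1), 5)  # 0 1 4 9 16
#' @export
synth_polynomial <- function(coeffs, n) {
  if (length(coeffs) < 1L || length(coeffs) > 4L)
    stop("degree must be 0..3 (1 to 4 coefficients)")
  if (any(coeffs != floor(coeffs))) stop("coefficients must be integers")
  t <- 0:(n - 1)
  x <- rowSums(outer(t, seq_along(coeffs) - 1, `^`) *
                 matrix(coeffs, n, length(coeffs), byrow = TRUE))
  if (any(abs(x) > .Machine$integer.max)) stop("polynomial values overflow 32-bit range")
  as.integer(x)
}

#' Seedable stationary AR process
#'
#' Simulates a stable AR(p) process with Gaussian innovations, discarding
#' a 1000-sample burn-in, deterministically for a given seed. The global
#' RNG state is left untouched.
#'
#' @param coeffs AR coefficients (prediction convention); all roots of
#'   `1 - sum a_i z^i` must lie outside the unit circle.
#' @param noise_sd innovation standard deviation.
#' @param n output length.
#' @param seed integer seed.
#' @return numeric vector of length `n`.
#' @export
synth_ar <- function(coeffs, noise_sd = 1, n = 1000L, seed = 1L) {
  stopifnot(noise_sd > 0, n >= 1)
  coeffs <- as.numeric(coeffs)
  with_seed(seed, {
    if (length(coeffs) == 0L || all(coeffs == 0)) {
      stats::rnorm(n, sd = noise_sd)
    } else {
      if (any(Mod(polyroot(c(1, -coeffs))) <= 1))
        stop("unstable AR coefficients: roots inside the unit circle")
      as.numeric(stats::arima.sim(model = list(ar = coeffs), n = n,
                                  n.start = 1000L, sd = noise_sd))
    }
  })
}

# run code under a local RNG seed, restoring the caller's stream
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (had) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  force(code)
}

#' Synthetic ECG record
#'
#' Generates an ECG-like integer signal for a given acquisition setup: a
#' Gaussian-bump beat train ([beat_morphology()]) plus sinusoidal baseline
#' wander (0.33 Hz, respiratory band) plus band-limited Gaussian noise,
#' all in mV, scaled by the preset's ADU-per-mV gain, quantized
#' round-to-nearest and clipped to the preset's bit resolution. The noise
#' is AR(1)-correlated (pole 0.9, marginal standard deviation
#' `noise_sd_mv`): acquired ECG noise -- muscle artifact, mains pickup,
#' electrode motion -- is band-limited by the anti-alias chain, not white
#' at Nyquist; quantization roughness still enters through the rounding
#' step. Clipping raises a warning
#' -- silent wraparound would corrupt lossless tests. Deterministic for a
#' given seed.
#'
#' @param preset an [acquisition_preset()] (or preset name).
#' @param duration_s record length in seconds (at least 2 beats).
#' @param heart_rate_bpm beat rate.
#' @param morphology a [beat_morphology()].
#' @param baseline_wander_mv amplitude of the baseline wander, mV.
#' @param noise_sd_mv white-noise standard deviation, mV.
#' @param seed integer seed.
#' @param lead_name name of the generated lead.
#' @return an [ecg_record()].
#' @examples
#' rec <- synth_ecg(acquisition_preset("mitdb"), duration_s = 10, seed = 1)
#' length(rec)  # 3600 samples
#' @export
synth_ecg <- function(preset = acquisition_preset("mitdb"), duration_s = 10,
                      heart_rate_bpm = 60, morphology = beat_morphology(),
                      baseline_wander_mv = 0, noise_sd_mv = 0, seed = 1L,
                      lead_name = "synthetic") {
  if (is.character(preset)) preset <- acquisition_preset(preset)
  stopifnot(inherits(preset, "acquisition_preset"),
            inherits(morphology, "beat_morphology"))
  beat_t <- 60 / heart_rate_bpm
  if (duration_s < 2 * beat_t) stop("duration must cover at least 2 beats")
  n <- round(preset$fs * duration_s)
  t <- (0:(n - 1)) / preset$fs
  phase <- t %% beat_t
  mv <- numeric(n)
  for (w in seq_along(morphology$amplitudes)) {
    ctr <- morphology$centers[w] * beat_t
    # wrap the distance so late waves spill smoothly into the next beat
    d <- phase - ctr
    d <- d - beat_t * round(d / beat_t)
    mv <- mv + morphology$amplitudes[w] * exp(-d^2 / (2 * morphology$widths[w]^2))
  }
  if (baseline_wander_mv != 0)
    mv <- mv + baseline_wander_mv * sin(2 * pi * 0.33 * t)
  if (noise_sd_mv > 0)
    mv <- mv + with_seed(seed, as.numeric(stats::arima.sim(
      list(ar = 0.9), n, n.start = 500L,
      sd = noise_sd_mv * sqrt(1 - 0.9^2))))
  adu <- round(mv * preset$adu_per_mv)
  lo <- -2^(preset$bits - 1); hi <- 2^(preset$bits - 1) - 1
  nclip <- sum(adu < lo | adu > hi)
  if (nclip > 0)
    warning(sprintf("%d sample(s) clipped to the %d-bit range", nclip, preset$bits))
  adu <- pmin(pmax(adu, lo), hi)
  ecg_record(stats::setNames(list(as.integer(adu)), lead_name),
             fs = preset$fs, bits = preset$bits, gain = preset$adu_per_mv)
}

#' Standard synthetic regression corpus
#'
#' Nine named fixtures: the three acquisition presets crossed with
#' \{clean, noisy, wandering\} variants, 30 s each, deterministically
#' derived from one seed. This is the corpus the codec round-trip tests
#' run on.
#'
#' @param seed integer seed; each fixture derives its own sub-seed.
#' @param duration_s per-fixture duration.
#' @return named list of nine [ecg_record()] objects
#'   (`mitdb_clean`, ..., `ptbdb_wandering`).
#' @export
fixture_suite <- function(seed = 1L, duration_s = 30) {
  presets <- c("mitdb", "edb", "ptbdb")
  variants <- list(
    clean = list(noise = 0, wander = 0),
    noisy = list(noise = 0.02, wander = 0),
    wandering = list(noise = 0.01, wander = 0.3))
  out <- list()
  i <- 0L
  for (p in presets) for (v in names(variants)) {
    i <- i + 1L
    out[[paste(p, v, sep = "_")]] <- synth_ecg(
      acquisition_preset(p), duration_s = duration_s,
      heart_rate_bpm = 72, noise_sd_mv = variants[[v]]$noise,
      baseline_wander_mv = variants[[v]]$wander,
      seed = seed * 131L + i, lead_name = paste(p, v, sep = "_"))
  }
  out
}
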