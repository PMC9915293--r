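# Independent hand oracles, kept deliberately naive.

# Rice code of one value, assembled bit by bit from the definition:
# q one-bits, a zero, then k remainder bits MSB-first.
oracle_rice_bits <- function(m, k) {
  q <- m %/% 2^k
  r <- m %% 2^k
  rbits <- integer(0)
  while (k > 0) {
    k <- k - 1
    rbits <- c(rbits, (r %/% 2^k) %% 2)
  }
  as.integer(c(rep(1, q), 0, rbits))
}

# payload raw vector -> 0/1 integer vector, MSB-first within each byte
bits_from_payload <- function(payload, nbits) {
  if (length(payload) == 0L) return(integer(0))
  v <- as.integer(payload)
  bits <- as.vector(vapply(v, function(b) as.integer((b %/% 2^(7:0)) %% 2),
                           integer(8)))
  bits[seq_len(nbits)]
}

# dense Yule-Walker solve: prediction coefficients from R(0)..R(p)
oracle_toeplitz_lp <- function(R, p) {
  as.numeric(solve(toeplitz(R[1:p]), R[2:(p + 1)]))
}

# biased raw autocorrelation by direct summation
oracle_acf <- function(x, lag_max) {
  n <- length(x)
  vapply(0:lag_max, function(k)
    sum(x[(k + 1):n] * x[1:(n - k)]) / n, numeric(1))
}

# direct evaluation of the four binomial predictors at one sample
oracle_predictions <- function(window) {
  c(window[1],
    2 * window[1] - window[2],
    3 * window[1] - 3 * window[2] + window[3],
    4 * window[1] - 6 * window[2] + 4 * window[3] - window[4])
}

random_test_record <- function(n, bits = 11L, seed = 1L, fs = 360) {
  set.seed(seed)
  half <- 2^(bits - 1)
  ecg_record(sample.int(2 * half, n, replace = TRUE) - half - 1L,
             fs = fs, bits = bits)
}
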