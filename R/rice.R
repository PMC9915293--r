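#' Signed-to-unsigned residual mapping for Rice coding
#'
#' Golomb--Rice codes accept non-negative integers, so signed residuals are
#' interleaved first: `e >= 0` maps to `2e` (even) and `e < 0` to
#' `2|e| - 1` (odd). The mapping is a bijection and `rice_unmap()` is its
#' exact inverse.
#'
#' @param e signed integer residual(s).
#' @return non-negative mapped value(s), same length as the input.
#' @examples
#' rice_map(c(0, -1, 1, -3, 4))   # 0 1 2 5 8
#' rice_unmap(rice_map(-1234L))   # -1234
#' @export
rice_map <- function(e) {
  if (any(!is.finite(e)) || any(e != floor(e))) stop("residuals must be integers")
  ifelse(e >= 0, 2 * e, -2 * e - 1)
}

#' @rdname rice_map
#' @param m non-negative mapped value(s).
#' @export
rice_unmap <- function(m) {
  if (any(!is.finite(m)) || any(m != floor(m))) stop("mapped values must be integers")
  if (any(m < 0)) stop("mapped values must be non-negative")
  ifelse(m %% 2 == 0, m / 2, -(m + 1) / 2)
}

#' Adaptive Rice parameter from the residual history
#'
#' The Rice divisor exponent k(n) adapts to the mean absolute error of the
#' three most recently coded residuals. Both sides of the codec evaluate it
#' with identical integer arithmetic: the MAE is the integer-floored
#' three-sum average, and k is `floor(log2(MAE))`, with k = 0 whenever the
#' MAE is 0 or 1 (flat regions get the shortest codes), clamped to
#' `k_max`.
#'
#' @param window the last three absolute residuals
#'   `c(|e(n-1)|, |e(n-2)|, |e(n-3)|)`.
#' @param k_max upper clamp for k; the codec uses `bits + 2`.
#' @return non-negative integer k.
#' @examples
#' rice_k(c(4, 5, 3))  # MAE 4 -> k = 2
#' rice_k(c(0, 0, 0))  # k = 0
#' @export
rice_k <- function(window, k_max = 32L) {
  if (length(window) != 3L || any(!is.finite(window)) ||
      any(window != floor(window)) || any(window < 0))
    stop("window must hold the last 3 absolute residuals")
  mae <- sum(window) %/% 3
  if (mae <= 1) return(0L)
  k <- 0L
  while (mae %/% 2^(k + 1) > 0) k <- k + 1L  # floor(log2(mae)), exactly
  min(k, as.integer(k_max))
}

#' Golomb--Rice code for one value
#'
#' Encodes a non-negative integer M with divisor `2^k` as
#' `q = floor(M / 2^k)` one-bits, a single zero separator, then the
#' remainder `r = M mod 2^k` in exactly k binary bits, most-significant bit
#' first. The code is self-delimiting: total length `q + 1 + k` bits.
#' These scalar functions are the readable reference; bulk streams go
#' through [rice_encode_stream()].
#'
#' @param m non-negative integer value.
#' @param k non-negative Rice parameter.
#' @return `rice_encode()`: integer vector of bits (0/1).
#' @examples
#' rice_encode(9, 2)             # 1 1 0 0 1
#' rice_decode(c(1, 1, 0, 1), 1) # value 5, 4 bits used
#' @export
rice_encode <- function(m, k) {
  stopifnot(length(m) == 1L, m >= 0, m == floor(m),
            length(k) == 1L, k >= 0, k == floor(k))
  q <- m %/% 2^k
  r <- m %% 2^k
  rbits <- if (k > 0) as.integer(intToBits(r))[k:1] else integer(0)
  c(rep(1L, q), 0L, rbits)
}

#' @rdname rice_encode
#' @param bits integer 0/1 vector positioned at a code boundary.
#' @param pos read position within `bits` (1-based).
#' @return `rice_decode()`: list with the decoded `value` and `used`, the
#'   number of bits consumed; errors out on a truncated stream.
#' @export
rice_decode <- function(bits, k, pos = 1L) {
  stopifnot(length(k) == 1L, k >= 0, k == floor(k))
  i <- pos
  q <- 0
  repeat {
    if (i > length(bits)) stop("truncated bitstream: no separator found")
    if (bits[i] == 0L) break
    q <- q + 1
    i <- i + 1L
  }
  i <- i + 1L
  if (k > 0) {
    if (i + k - 1L > length(bits)) stop("truncated bitstream: remainder cut short")
    r <- sum(bits[i:(i + k - 1L)] * 2^((k - 1):0))
    i <- i + as.integer(k)
  } else r <- 0
  list(value = q * 2^k + r, used = i - pos)
}

#' Rice-code a vector of values into a packed bitstream
#'
#' Compiled bulk counterpart of [rice_encode()]/[rice_decode()]: values are
#' concatenated MSB-first into a byte-packed payload. `k` is recycled to
#' one parameter per value (the codec feeds the causally adapted
#' sequence).
#'
#' @param m non-negative integer values.
#' @param k Rice parameter(s), scalar or one per value.
#' @return `rice_encode_stream()`: list with `payload` (raw bytes,
#'   zero-padded to a byte boundary) and `nbits`, the exact bit length.
#' @export
rice_encode_stream <- function(m, k) {
  k <- as.integer(rep_len(k, length(m)))
  if (any(k < 0)) stop("k must be non-negative")
  .rice_encode_stream_cpp(as.numeric(m), k)
}

#' @rdname rice_encode_stream
#' @param payload raw byte vector from `rice_encode_stream()`.
#' @param nbits exact bit length of the stream.
#' @return `rice_decode_stream()`: numeric vector of decoded values, one
#'   per entry of `k`.
#' @export
rice_decode_stream <- function(payload, nbits, k) {
  .rice_decode_stream_cpp(payload, as.numeric(nbits), as.integer(k))
}
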