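#' Fixed binomial-coefficient linear predictors
#'
#' The codec predicts each sample with the four classic fixed-coefficient
#' linear predictors whose weights come from Pascal's triangle:
#' \deqn{\hat x_1(n) = x(n-1)}
#' \deqn{\hat x_2(n) = 2x(n-1) - x(n-2)}
#' \deqn{\hat x_3(n) = 3x(n-1) - 3x(n-2) + x(n-3)}
#' \deqn{\hat x_4(n) = 4x(n-1) - 6x(n-2) + 4x(n-3) - x(n-4)}
#' The order-p residual \eqn{e_p(n) = x(n) - \hat x_p(n)} equals the p-th
#' backward difference of the signal, so an order-p predictor is exact on
#' any polynomial of degree p-1. All arithmetic is exact integer
#' arithmetic; intermediate predictions may exceed the input bit range.
#'
#' @param window the four most recent past samples, newest first:
#'   `c(x(n-1), x(n-2), x(n-3), x(n-4))`.
#' @param order prediction order, 1 to 4.
#' @return `alp_predict()`: the integer prediction \eqn{\hat x_p(n)}.
#' @examples
#' alp_predict(c(4, 3, 2, 1), 2)   # exact on a ramp: 5
#' alp_errors(c(16, 9, 4, 1), 25)  # squares: orders 3 and 4 are exact
#' @seealso [alp_select()], [ecg_compress()]
#' @export
alp_predict <- function(window, order) {
  window <- check_window(window)
  if (!is.numeric(order) || length(order) != 1L || !order %in% 1:4)
    stop("order must be 1, 2, 3 or 4")
  co <- .alp_coef[[order]]
  sum(co * window[seq_along(co)])
}

# binomial predictor weights, orders 1..4 (alternating-sign Pascal rows)
.alp_coef <- list(1, c(2, -1), c(3, -3, 1), c(4, -6, 4, -1))

check_window <- function(window) {
  if (length(window) != 4L || any(!is.finite(window)) ||
      any(window != floor(window)))
    stop("window must hold exactly 4 integer past samples (newest first)")
  as.numeric(window)
}

#' @rdname alp_predict
#' @param x the current sample `x(n)`.
#' @return `alp_errors()`: a list with integer vectors `predictions` and
#'   `errors` (\eqn{e_p(n)}, orders 1--4).
#' @export
alp_errors <- function(window, x) {
  window <- check_window(window)
  pred <- vapply(1:4, function(p) alp_predict(window, p), numeric(1))
  list(predictions = pred, errors = x - pred)
}

#' Minimum-absolute-error order selection
#'
#' Chooses the predictor whose residual has the smallest magnitude,
#' \eqn{e(n) = \min_p |e_p(n)|}, keeping the residual's sign. Ties go to
#' the smallest order (lower orders are cheaper and more stable in flat
#' regions).
#'
#' @param errors the four signed residuals \eqn{e_1(n) \ldots e_4(n)} (or
#'   the list returned by [alp_errors()]).
#' @return list with `order` (1--4) and the signed `error`.
#' @examples
#' alp_select(c(3, 1, -2, 5))  # order 2, error 1
#' alp_select(c(2, -2, 3, 4))  # tie in magnitude -> order 1
#' @export
alp_select <- function(errors) {
  if (is.list(errors)) errors <- errors$errors
  if (length(errors) != 4L || any(!is.finite(errors)))
    stop("need the four order-1..4 residuals")
  p <- which.min(abs(errors))  # which.min takes the first of tied minima
  list(order = as.integer(p), error = errors[[p]])
}

#' @rdname alp_predict
#' @param error the signed residual transmitted for this sample.
#' @return `alp_reconstruct()`: the exact original sample
#'   `alp_predict(window, order) + error`.
#' @export
alp_reconstruct <- function(window, order, error) {
  alp_predict(window, order) + error
}

#' Residuals of all four predictors over a whole signal
#'
#' Vectorized form of [alp_errors()]: for every sample index `n >= 5`
#' returns the four predictor residuals, which equal the backward
#' differences `diff(x, differences = p)`.
#'
#' @param x integer signal, length at least 5.
#' @return an `(length(x) - 4) x 4` matrix; row i holds
#'   \eqn{e_1 \ldots e_4} at sample `i + 4`, columns named `p1`..`p4`.
#' @export
alp_error_matrix <- function(x) {
  n <- length(x)
  if (n < 5L) stop("need at least 5 samples")
  x <- as.numeric(x)
  m <- vapply(1:4, function(p) diff(x, differences = p)[(5 - p):(n - p)],
              numeric(n - 4L))
  if (n == 5L) m <- matrix(m, nrow = 1L)
  colnames(m) <- paste0("p", 1:4)
  m
}
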