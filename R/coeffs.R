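#' Biased autocorrelation estimate
#'
#' Raw (non-demeaned by default) biased autocorrelation
#' \eqn{R(k) = N^{-1} \sum_{n=k+1}^{N} x(n) x(n-k)}. The 1/N normalization
#' makes the Toeplitz system positive semi-definite, so the
#' Levinson--Durbin recursion cannot blow up. Mean removal is off by
#' default: quantized ECG in ADU carries a DC offset, and the fixed
#' binomial predictors the codec uses act on the raw signal.
#'
#' @param x numeric signal.
#' @param lag_max largest lag; needs `length(x) > lag_max >= 1`.
#' @param demean subtract the sample mean first.
#' @return numeric vector `R(0)..R(lag_max)`, with attribute `n` (sample
#'   count used).
#' @export
acf_biased <- function(x, lag_max, demean = FALSE) {
  n <- length(x)
  if (!is.numeric(x) || n <= lag_max || lag_max < 1L)
    stop("need length(x) > lag_max >= 1")
  r <- drop(stats::acf(as.numeric(x), lag.max = lag_max, type = "covariance",
                       demean = demean, plot = FALSE, na.action = stats::na.fail)$acf)
  structure(r, n = n)
}

#' Levinson--Durbin recursion
#'
#' Solves the order-p Yule--Walker equations
#' \eqn{\sum_i a_i R(|k-i|) = R(k)} in O(p^2), returning coefficients in
#' the prediction convention \eqn{\hat x(n) = \sum_i a_i x(n-i)} (so a
#' near-random-walk signal gives \eqn{a_1 \approx +1}).
#'
#' @param R autocorrelation values `R(0)..R(p)` (at least `order + 1`).
#' @param order prediction order p >= 1.
#' @return list with `coefficients` (a_1..a_p), `reflection` (the p partial
#'   correlation coefficients) and `sigma2` (the final prediction-error
#'   variance). Errors out when `R(0) <= 0` or the recursion hits a
#'   zero-variance (degenerate) stage.
#' @examples
#' levinson(c(1, 0.5, 0.25), 2)  # AR(1)-shaped: a = (0.5, 0)
#' @export
levinson <- function(R, order) {
  order <- as.integer(order)
  if (order < 1L) stop("order must be >= 1")
  if (length(R) < order + 1L) stop("need R(0)..R(order)")
  if (!all(is.finite(R))) stop("non-finite autocorrelation values")
  if (R[1] <= 0) stop("degenerate autocorrelation: R(0) <= 0 (zero-variance signal?)")
  a <- numeric(order)
  refl <- numeric(order)
  e <- R[1]
  for (m in seq_len(order)) {
    acc <- R[m + 1]
    if (m > 1L) acc <- acc - sum(a[1:(m - 1)] * R[m:2])
    if (e <= 0) stop(sprintf("degenerate recursion at stage %d: zero prediction-error variance", m))
    kref <- acc / e
    refl[m] <- kref
    a_new <- a
    a_new[m] <- kref
    if (m > 1L) a_new[1:(m - 1)] <- a[1:(m - 1)] - kref * a[(m - 1):1]
    a <- a_new
    e <- e * (1 - kref^2)
  }
  list(coefficients = a, reflection = refl, sigma2 = e)
}

#' Fit linear-prediction coefficients to a signal
#'
#' The autocorrelation method: biased autocorrelation of the full signal
#' (see [acf_biased()]) followed by the Levinson--Durbin solve of the
#' Yule--Walker system. This is the analysis companion to the codec: the
#' fitted real coefficients tell you how adequate the fixed integer
#' predictors are for a given acquisition setup, but they never enter the
#' compression path.
#'
#' @param x numeric signal, or an [ecg_record()] (its `lead` is used).
#' @param order prediction order, 1--4 for the codec comparison (higher
#'   orders are allowed for general LP analysis).
#' @param demean remove the sample mean before autocorrelation (off by
#'   default; see [acf_biased()]).
#' @param lead lead selector when `x` is a record.
#' @return an object of class `lp_fit` with `print()`, `coef()`,
#'   `predict()`, `residuals()` and `summary()` methods.
#' @examples
#' set.seed(2)
#' x <- synth_ar(0.9, noise_sd = 1, n = 5000, seed = 2)
#' fit <- lp_fit(x, order = 1)
#' coef(fit)  # close to 0.9
#' @export
lp_fit <- function(x, order = 2L, demean = FALSE, lead = 1L) {
  cl <- match.call()
  if (inherits(x, "ecg_record")) x <- record_lead(x, lead)
  x <- as.numeric(x)
  order <- as.integer(order)
  R <- acf_biased(x, lag_max = order, demean = demean)
  ld <- levinson(R, order)
  structure(list(coefficients = ld$coefficients, order = order,
                 sigma2 = ld$sigma2, reflection = ld$reflection,
                 R = as.numeric(R), n = length(x), demean = demean,
                 series = x, call = cl),
            class = "lp_fit")
}

#' @export
print.lp_fit <- function(x, digits = 4, ...) {
  cat(sprintf("Linear prediction fit (autocorrelation method), order %d, n = %d\n",
              x$order, x$n))
  co <- round(x$coefficients, digits)
  cat("  coefficients:", paste0("a", seq_along(co), " = ", co, collapse = ", "), "\n")
  cat(sprintf("  prediction-error variance: %.6g\n", x$sigma2))
  invisible(x)
}

#' @export
coef.lp_fit <- function(object, ...) {
  stats::setNames(object$coefficients, paste0("a", seq_len(object$order)))
}

#' @rdname lp_fit
#' @param object an `lp_fit`.
#' @param newdata optional signal to predict; defaults to the fitting
#'   series.
#' @param ... unused.
#' @return `predict.lp_fit()`: one-step-ahead predictions for samples
#'   `order+1 .. N` of the series (leading `order` entries are `NA`).
#' @export
predict.lp_fit <- function(object, newdata = NULL, ...) {
  x <- if (is.null(newdata)) object$series else as.numeric(newdata)
  p <- object$order
  if (length(x) <= p) stop("series shorter than the prediction order")
  out <- rep(NA_real_, length(x))
  for (i in seq_len(p))
    out[(p + 1):length(x)] <- if (i == 1L)
      object$coefficients[1] * x[p:(length(x) - 1)]
    else out[(p + 1):length(x)] + object$coefficients[i] * x[(p + 1 - i):(length(x) - i)]
  out
}

#' @export
residuals.lp_fit <- function(object, newdata = NULL, ...) {
  x <- if (is.null(newdata)) object$series else as.numeric(newdata)
  x - predict(object, newdata = x)
}

#' @export
summary.lp_fit <- function(object, ...) {
  r <- residuals(object)
  cat(sprintf("LP fit: order %d, n = %d, demean %s\n", object$order,
              object$n, if (object$demean) "on" else "off"))
  cat("  coefficients: ", paste(sprintf("%.4f", object$coefficients),
                                collapse = ", "), "\n")
  cat("  reflection:   ", paste(sprintf("%.4f", object$reflection),
                                collapse = ", "), "\n")
  cat(sprintf("  residual MAE %.4f, RMS %.4f (one-step, in ADU)\n",
              mean(abs(r), na.rm = TRUE), sqrt(mean(r^2, na.rm = TRUE))))
  invisible(object)
}

#' Average and round coefficient sets
#'
#' `lp_average()` takes the element-wise unweighted mean of same-order
#' coefficient sets (vectors or `lp_fit` objects) -- how per-record
#' estimates are pooled across a database. `lp_round()` rounds a real
#' coefficient set to the nearest integers for use with integer-only
#' codec arithmetic; exact halves follow round-half-to-even.
#'
#' @param sets list of numeric coefficient vectors or `lp_fit` objects,
#'   all the same order.
#' @return `lp_average()`: the mean coefficient vector.
#' @examples
#' lp_average(list(c(1, -1), c(3, 1)))  # (2, 0)
#' lp_round(c(1.85, -0.86))             # (2, -1)
#' @export
lp_average <- function(sets) {
  if (length(sets) == 0L) stop("need at least one coefficient set")
  co <- lapply(sets, function(s) if (inherits(s, "lp_fit")) s$coefficients else as.numeric(s))
  p <- unique(lengths(co))
  if (length(p) != 1L) stop("coefficient sets have mixed orders")
  colMeans(do.call(rbind, co))
}

#' @rdname lp_average
#' @param coefficients a real coefficient vector.
#' @return `lp_round()`: integer vector of the same length.
#' @export
lp_round <- function(coefficients) {
  if (inherits(coefficients, "lp_fit")) coefficients <- coefficients$coefficients
  as.integer(round(as.numeric(coefficients)))
}

#' Per-record coefficient determination over a dataset
#'
#' Fits order-p coefficients to the designated lead of every record,
#' then pools them: per-record estimates, their unweighted average and
#' the integer-rounded average, mirroring how database-wide LP
#' coefficients are tabulated.
#'
#' @param records list of [ecg_record()] objects.
#' @param order prediction order 1--4.
#' @param demean,lead passed to [lp_fit()].
#' @return list with `per_record` (data.frame of a_1..a_p per record),
#'   `average` and `rounded`.
#' @export
fit_dataset_coefficients <- function(records, order = 2L, demean = FALSE,
                                     lead = 1L) {
  if (length(records) == 0L) stop("need at least one record")
  ids <- names(records)
  if (is.null(ids)) ids <- paste0("record", seq_along(records))
  fits <- lapply(records, lp_fit, order = order, demean = demean, lead = lead)
  tab <- do.call(rbind, lapply(fits, function(f)
    as.data.frame(as.list(coef(f)))))
  tab <- cbind(record = ids, tab, stringsAsFactors = FALSE)
  rownames(tab) <- NULL
  avg <- lp_average(fits)
  list(per_record = tab, average = avg, rounded = lp_round(avg))
}

#' Literature-reported average LP coefficients for the three standard
#' databases
#'
#' Published database-wide averages of autocorrelation-method LP
#' coefficients for the MIT-BIH Arrhythmia (MITDB), PTB Diagnostic
#' (PTBDB) and European ST-T (EDB) databases, orders 1--4. Useful as
#' reference input for rounding and comparison studies without
#' downloading the databases.
#'
#' @return nested list: `$mitdb`, `$ptbdb`, `$edb`, each with elements
#'   `"1"`..`"4"` holding the average coefficient vector of that order.
#' @export
reference_lp_averages <- function() {
  list(
    mitdb = list(`1` = 0.99, `2` = c(1.85, -0.86),
                 `3` = c(2.18, -1.57, -0.38), `4` = c(2.10, -1.25, -0.06, 0.20)),
    ptbdb = list(`1` = 0.99, `2` = c(1.59, -0.60),
                 `3` = c(1.54, -0.51, -0.04), `4` = c(1.53, -0.66, 0.40, -0.28)),
    edb = list(`1` = 0.99, `2` = c(1.74, -0.75),
               `3` = c(2.13, -1.63, 0.50), `4` = c(2.14, -1.63, 0.46, 0.02)))
}
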