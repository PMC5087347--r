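# Zero-phase Butterworth band-pass filtering.
#
# Coefficients come from signal::butter; the forward-backward application is
# implemented here so that whole multi-channel trials can be filtered in one
# column-parallel pass (stats::filter runs at C speed on matrices). Edges are
# handled by odd reflection padding of length 3 * (n_coef - 1), which bounds
# the startup transient of both passes.

#' Band-pass filter coefficients
#'
#' 4th-order Butterworth band-pass design for a canonical EEG band.
#'
#' @param low,high Band edges in Hz.
#' @param sampling_rate Sampling rate in Hz.
#' @param order Filter order (default 4).
#' @return List with components `b` (moving-average) and `a` (autoregressive)
#'   coefficients.
#' @export
bandpass_coefficients <- function(low, high, sampling_rate, order = 4L) {
  stopifnot_scalar_number(low, "low", 0, sampling_rate / 2)
  stopifnot_scalar_number(high, "high", 0, sampling_rate / 2)
  if (low >= high) stop("`low` must be below `high`", call. = FALSE)
  bf <- signal::butter(order, c(low, high) / (sampling_rate / 2), type = "pass")
  list(b = bf$b, a = bf$a)
}

# Direct-form IIR filter y = filter(b, a, x) with zero initial state,
# column-wise over a matrix (compiled kernel). Equivalent to
# signal::filter(b, a, x) per column.
ba_filter <- function(b, a, x) {
  vec <- is.null(dim(x))
  if (vec) x <- matrix(x, ncol = 1L)
  y <- .iir_filter(as.numeric(b), as.numeric(a), x)
  if (vec) drop(y) else y
}

#' Zero-phase band-pass filter
#'
#' Applies a Butterworth band-pass filter forward and backward (zero phase,
#' squared magnitude response) with odd-reflection edge padding. Operates
#' column-wise when given a matrix (time x channels).
#'
#' @param x Numeric vector, or matrix with time along rows.
#' @param coefs Coefficients from [bandpass_coefficients()].
#' @return Filtered vector or matrix, same shape as `x`.
#' @export
zerophase_filter <- function(x, coefs) {
  b <- coefs$b
  a <- coefs$a
  vec <- is.null(dim(x))
  if (vec) x <- matrix(x, ncol = 1L)
  n <- nrow(x)
  npad <- 3L * (max(length(a), length(b)) - 1L)
  if (n <= npad) {
    stop(sprintf("signal too short for zero-phase filtering (need > %d samples)",
                 npad), call. = FALSE)
  }
  pre <- 2 * x[rep(1L, npad), , drop = FALSE] - x[(npad + 1L):2L, , drop = FALSE]
  post <- 2 * x[rep(n, npad), , drop = FALSE] - x[(n - 1L):(n - npad), , drop = FALSE]
  xx <- rbind(pre, x, post)
  y <- ba_filter(b, a, xx)
  y <- ba_filter(b, a, y[nrow(y):1L, , drop = FALSE])
  y <- y[nrow(y):1L, , drop = FALSE]
  y <- y[(npad + 1L):(npad + n), , drop = FALSE]
  if (vec) drop(y) else y
}
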