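#' Binary time series
#'
#' A binary time series of length `L` is stored sparsely as the sorted times
#' of its "1" signals on the 1-based integer time axis `t = 1..L`. This is
#' the natural representation for the time-circle construction, where only
#' the "1" signals carry information.
#'
#' @param length Positive integer, the number of time steps `L`.
#' @param times Integer vector of signal times, strictly increasing, all in
#'   `[1, length]`. Unsorted input is sorted; duplicates are an error.
#'
#' @return An object of class `"bls_series"`: a list with elements `length`
#'   and `times`.
#' @examples
#' q <- bls_series(10, c(2, 5, 9))
#' n_signals(q)
#' as_binary_vector(q)
#' @export
bls_series <- function(length, times) {
  length <- as.integer(length)
  if (is.na(length) || length < 1L)
    stop("series length must be a positive integer")
  if (is.null(times)) times <- integer(0)
  if (any(times != floor(times)))
    stop("signal times must be integers")
  times <- as.integer(times)
  if (anyNA(times)) stop("signal times contain NA")
  if (anyDuplicated(times)) stop("signal times must be unique")
  if (any(times < 1L | times > length))
    stop("signal times must lie in [1, length]")
  structure(list(length = length, times = sort(times)),
            class = "bls_series")
}

#' @export
print.bls_series <- function(x, ...) {
  cat(sprintf("Binary time series: L = %d, %d signal(s)\n",
              x$length, length(x$times)))
  if (length(x$times)) {
    shown <- utils::head(x$times, 10L)
    cat("  times:", paste(shown, collapse = " "),
        if (length(x$times) > 10L) "..." else "", "\n")
  }
  invisible(x)
}

#' Number of "1" signals in a series
#'
#' @param series A [bls_series] object.
#' @return Integer count of signals.
#' @export
n_signals <- function(series) {
  stopifnot(inherits(series, "bls_series"))
  length(series$times)
}

#' Dense 0/1 representation of a series
#'
#' @param series A [bls_series] object.
#' @return Integer vector of length `series$length` with 1 at signal times.
#' @export
as_binary_vector <- function(series) {
  stopifnot(inherits(series, "bls_series"))
  v <- integer(series$length)
  v[series$times] <- 1L
  v
}

#' Cyclic shift of a binary time series
#'
#' Shifts every signal time by `k` steps along the time circle, wrapping
#' modulo the series length. Used throughout to express the rotation
#' invariance of the time-circle construction.
#'
#' @param series A [bls_series] object.
#' @param k Integer shift (may be negative).
#' @return The shifted [bls_series].
#' @export
shift_series <- function(series, k) {
  stopifnot(inherits(series, "bls_series"))
  k <- as.integer(k)
  tt <- ((series$times - 1L + k) %% series$length) + 1L
  bls_series(series$length, tt)
}

#' Time reversal of a binary time series
#'
#' Maps every signal time `t` to `L + 1 - t`. Circular distance multisets
#' are preserved under this reflection, so the entropy profile of the
#' reversed series is the reversed profile.
#'
#' @param series A [bls_series] object.
#' @return The reflected [bls_series].
#' @export
reverse_series <- function(series) {
  stopifnot(inherits(series, "bls_series"))
  bls_series(series$length, series$length + 1L - series$times)
}
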